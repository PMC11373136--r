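# Seeded synthetic generators standing in for the undeposited hepatotoxicity
# dataset. Two levels: an abstract planted-signal fingerprint generator
# (fast, bit-level, known informative indices) for quantitative tests of
# selection/ensembling, and a concrete rule-labeled SMILES generator (real
# chemistry objects, nitro-group toxicity rule) exercising curation and
# featurization end to end. The default class balance 0.625 mirrors the
# 1618/970 positive/negative imbalance of the assembled literature dataset.

#' Generate planted-signal fingerprint data
#'
#' Binary fingerprint-like matrices with a known structure-label signal:
#' `n_informative` bits fire with rate `p_active_pos` in positives and
#' `p_active_neg` in negatives; all remaining bits are background noise with
#' rate `p_background` in both classes.
#'
#' @param n_samples number of compounds (default 600).
#' @param n_features fingerprint length (default 2048).
#' @param n_informative number of signal-carrying bits (default 40).
#' @param p_active_pos,p_active_neg Bernoulli rates of informative bits in
#'   the positive / negative class (defaults 0.7 / 0.3).
#' @param p_background rate of all other bits (default 0.1).
#' @param class_balance positive fraction (default 0.625).
#' @param seed integer seed; same spec + seed gives identical output.
#' @return list with `x` (binary `feature_matrix` of kind
#'   circular_fingerprints), `y` (0/1 labels), `informative` (column indices
#'   of the planted bits).
#' @export
planted_fingerprints <- function(n_samples = 600, n_features = 2048,
                                 n_informative = 40, p_active_pos = 0.7,
                                 p_active_neg = 0.3, p_background = 0.1,
                                 class_balance = 0.625, seed = 1) {
  rates <- c(p_active_pos, p_active_neg, p_background, class_balance)
  if (any(rates < 0) || any(rates > 1)) abort("rates must lie in [0,1]", "spec_error")
  if (n_informative > n_features)
    abort("n_informative exceeds n_features", "spec_error")
  with_seed(seed, {
    y <- stats::rbinom(n_samples, 1, class_balance)
    x <- matrix(stats::rbinom(n_samples * n_features, 1, p_background),
                n_samples, n_features)
    info <- sort(sample.int(n_features, n_informative))
    n_pos <- sum(y == 1); n_neg <- sum(y == 0)
    x[y == 1, info] <- stats::rbinom(n_pos * n_informative, 1, p_active_pos)
    x[y == 0, info] <- stats::rbinom(n_neg * n_informative, 1, p_active_neg)
  })
  colnames(x) <- sprintf("bit%04d", seq_len(n_features))
  list(x = feature_matrix(x, "circular_fingerprints"), y = y,
       informative = info)
}

# scaffold templates ({R1}/{R2} = substitution points) and substituent pools;
# all combinations yield valid single-fragment organic SMILES
.scaffolds <- c(
  benzene   = "c1cc({R2})ccc1{R1}",
  pyridine  = "c1cc({R2})cnc1{R1}",
  phenol    = "Oc1ccc({R1})cc1{R2}",
  toluene   = "Cc1ccc({R1})cc1{R2}",
  butyl     = "CCCC({R2}){R1}",
  propyl    = "CCC({R2}){R1}",
  cyclohex  = "C1CCC({R2})CC1{R1}"
)
.substituents <- c("[H]", "C", "CC", "CCC", "O", "N", "Cl", "F", "C(=O)O",
                   "OC", "C#N", "C(C)C", "CO", "C=C")
.nitro <- "[N+](=O)[O-]"

.instantiate_scaffold <- function(scaffold, r1, r2) {
  s <- sub("{R1}", r1, scaffold, fixed = TRUE)
  s <- sub("{R2}", r2, s, fixed = TRUE)
  # "[H]" marks "no substituent": drop it together with an enclosing branch
  s <- gsub("([H])", "", s, fixed = TRUE)
  s <- gsub("[H]", "", s, fixed = TRUE)
  s <- gsub("()", "", s, fixed = TRUE)
  s
}

#' Generate rule-labeled SMILES rows
#'
#' Enumerates small organic molecules by decorating scaffold templates
#' (benzene, pyridine, phenol, toluene, alkyl chains, cyclohexane) with
#' substituent pairs, one of which may be a nitro group. The toxicity label
#' is 1 iff the molecule matches the nitro SMARTS pattern, then flipped with
#' probability `label_noise`. Duplicates are allowed (sampling with
#' replacement) so curation has work to do.
#'
#' @param n_molecules rows to emit (default 500).
#' @param label_noise label flip probability (default 0).
#' @param seed integer seed.
#' @return data.frame `smiles`, `label`, `source_id` (raw rows for
#'   [curate_compounds()]), with attribute `label_prenoise`.
#' @export
rule_labeled_smiles <- function(n_molecules = 500, label_noise = 0, seed = 1) {
  if (label_noise < 0 || label_noise > 1) abort("label_noise in [0,1]", "spec_error")
  n_space <- length(.scaffolds) * (length(.substituents) + 1) * length(.substituents)
  if (n_molecules > 20 * n_space)
    abort("n_molecules far exceeds the enumerable space", "spec_error")
  # nitro only at R1 (drawn with probability ~0.45 so classes stay roughly
  # balanced); R2 varies the molecular background
  with_seed(seed, {
    sc <- sample(names(.scaffolds), n_molecules, replace = TRUE)
    use_nitro <- stats::rbinom(n_molecules, 1, 0.45)
    r1 <- ifelse(use_nitro == 1, .nitro,
                 sample(.substituents, n_molecules, replace = TRUE))
    r2 <- sample(.substituents, n_molecules, replace = TRUE)
    flip <- stats::rbinom(n_molecules, 1, label_noise)
  })
  smiles <- vapply(seq_len(n_molecules), function(i)
    .instantiate_scaffold(.scaffolds[[sc[i]]], r1[i], r2[i]),
    character(1))
  has_nitro <- smarts_matches(smiles, "[NX3+](=O)[O-]")
  label <- as.integer(xor(has_nitro, flip == 1))
  out <- data.frame(smiles = smiles, label = label,
                    source_id = paste0("synth", seq_len(n_molecules)),
                    stringsAsFactors = FALSE)
  attr(out, "label_prenoise") <- as.integer(has_nitro)
  out
}

#' Count SMARTS pattern matches per molecule
#'
#' @param smiles character vector of SMILES.
#' @param smarts a SMARTS pattern.
#' @return logical vector: does each molecule contain the pattern?
#' @export
smarts_matches <- function(smiles, smarts) {
  uniq <- unique(smiles)
  hit <- vapply(uniq, function(s) {
    sdf <- .smiles_to_sdf(s)
    if (is.null(sdf)) return(NA)
    n <- tryCatch(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE),
                  error = function(e) NA_integer_)
    isTRUE(as.numeric(n)[1] > 0)
  }, logical(1))
  unname(hit[match(smiles, uniq)])
}
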