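# Molecular featurization: physicochemical descriptors, an extended 2D
# descriptor block, and circular (Morgan-type / ECFP) fingerprints, plus
# matrix cleaning and [0,1] min-max scaling with a train-fitted scaler.

#' Construct a feature matrix
#'
#' A feature matrix is a plain numeric matrix with unique column names plus
#' `kind` and `scaled` attributes. Fingerprint matrices are 0/1-valued.
#'
#' @param values numeric matrix with column names.
#' @param kind one of "physchem_descriptors", "extended_descriptors",
#'   "circular_fingerprints", "combined_descriptors".
#' @param scaled logical; whether min-max scaling has been applied.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, kind, scaled = FALSE) {
  kinds <- c("physchem_descriptors", "extended_descriptors",
             "circular_fingerprints", "combined_descriptors")
  if (!kind %in% kinds) abort("unknown feature kind", "config_error")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    abort("feature names must be present and unique", "schema_error")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(values, kind = kind, scaled = scaled,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s%s]: %d compounds x %d features\n",
              attr(x, "kind"), if (isTRUE(attr(x, "scaled"))) ", scaled" else "",
              nrow(x), ncol(x)))
  invisible(x)
}

# keep feature_matrix attributes through subsetting
#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, kind = attr(x, "kind"), scaled = attr(x, "scaled"),
                     class = c("feature_matrix", "matrix", "array"))
  out
}

.dataset_smiles <- function(dataset) {
  if (inherits(dataset, "curated_dataset")) dataset$records$smiles
  else as.character(dataset)
}

# parse one canonical SMILES into an SDF object (NULL on failure)
.smiles_to_sdf <- function(s) {
  tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "m")))
    if (length(sdf) == 0) NULL else sdf
  }, error = function(e) NULL)
}

#' Compute molecular descriptors
#'
#' `physchem_descriptors`: a fixed physicochemical panel (molecular weight,
#' logP, TPSA, molar refractivity, H-bond donor/acceptor counts, rotatable
#' bonds, heteroatom/element counts, ring statistics, functional group
#' counts). `extended_descriptors`: the physchem panel plus classical 2D
#' topological graph indices (Wiener, Zagreb, Randic, Balaban J, kappa shape,
#' eccentricity-based and related indices) computed from the heavy-atom
#' connectivity matrix. Both are pure functions of the canonical SMILES; no
#' 3D/conformer-dependent quantities are included.
#'
#' @param dataset a `curated_dataset` or character vector of SMILES.
#' @param kind "physchem_descriptors" or "extended_descriptors".
#' @return a `feature_matrix`, one row per compound in input order. Compounds
#'   for which generation fails are dropped with a warning; the surviving row
#'   indices are in attribute `row_index`.
#' @export
compute_descriptors <- function(dataset, kind = c("physchem_descriptors",
                                                  "extended_descriptors")) {
  kind <- match.arg(kind)
  smiles <- .dataset_smiles(dataset)
  if (length(smiles) == 0) abort("empty dataset", "empty_dataset")
  uniq <- unique(smiles)
  rows_u <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    rows_u[i] <- list(tryCatch(.descriptor_row(uniq[i], extended = kind == "extended_descriptors"),
                               error = function(e) NULL))
  }
  names(rows_u) <- uniq
  rows <- rows_u[match(smiles, uniq)]
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) abort("descriptor generation failed for every compound", "featurization_error")
  if (any(!ok))
    warning(sprintf("descriptor generation failed for %d compound(s); rows dropped", sum(!ok)))
  m <- do.call(rbind, rows[ok])
  m <- m[, order(colnames(m)), drop = FALSE]   # fixed alphabetical order
  out <- feature_matrix(m, kind)
  attr(out, "row_index") <- which(ok)
  out
}

# one descriptor row for a single canonical SMILES
.descriptor_row <- function(smiles, extended = FALSE) {
  sdf <- .smiles_to_sdf(smiles)
  if (is.null(sdf)) abort(sprintf("cannot featurize '%s'", smiles), "featurization_error")
  props <- ChemmineR::propOB(sdf)
  ab <- ChemmineR::atomblock(sdf)[[1]]
  bb <- ChemmineR::bondblock(sdf)[[1]]
  elements <- gsub("_.*", "", rownames(ab))
  counts <- function(el) sum(elements == el)
  n_heavy <- sum(elements != "H")
  bond_orders <- if (nrow(bb) > 0) bb[, 3] else numeric(0)
  ringinfo <- tryCatch(ChemmineR::rings(sdf, type = "count", upper = 12, arom = TRUE),
                       error = function(e) list(RINGS = 0, AROMATIC = 0))
  grp <- tryCatch(ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA"),
                  error = function(e) NULL)
  out <- c(
    MW = props$MW, LogP = props$logP, TPSA = props$TPSA, MR = props$MR,
    HBA = props$HBA1, HBA_lipinski = props$HBA2, HBD = props$HBD,
    nF_ob = props$nF,
    nAtomsHeavy = n_heavy,
    nC = counts("C"), nN = counts("N"), nO = counts("O"), nS = counts("S"),
    nP = counts("P"), nHal = counts("F") + counts("Cl") + counts("Br") + counts("I"),
    nBonds = nrow(bb),
    nBondsDouble = sum(bond_orders == 2), nBondsTriple = sum(bond_orders == 3),
    nRings = as.numeric(ringinfo[["RINGS"]]),
    nRingsAromatic = as.numeric(ringinfo[["AROMATIC"]]),
    FracHetero = if (n_heavy > 0) (n_heavy - counts("C")) / n_heavy else 0
  )
  if (!is.null(grp)) {
    g <- as.numeric(grp[1, ])
    names(g) <- paste0("grp", gsub("[^A-Za-z0-9]", "", colnames(grp)))
    out <- c(out, g)
  }
  if (extended) out <- c(out, .topological_indices(sdf))
  out
}

#' Compute circular (Morgan-type) fingerprints
#'
#' Hashed circular atom-environment fingerprints (the ECFP family; ECFP with
#' diameter 2*radius corresponds to a Morgan fingerprint of that radius),
#' folded to `n_bits` by OR-folding. Deterministic per molecule.
#'
#' @param dataset a `curated_dataset` or character vector of SMILES.
#' @param radius circular environment radius (default 2, i.e. ECFP4).
#' @param n_bits fingerprint length after folding (default 2048).
#' @return a binary `feature_matrix` of kind "circular_fingerprints" with
#'   columns `bit0001...`.
#' @export
morgan_fingerprints <- function(dataset, radius = 2, n_bits = 2048) {
  if (n_bits < 8) abort("n_bits must be >= 8", "config_error")
  if (radius < 0 || radius > 5) abort("radius must be in 0..5", "config_error")
  smiles <- .dataset_smiles(dataset)
  if (length(smiles) == 0) abort("empty dataset", "empty_dataset")
  fpname <- paste0("ECFP", 2 * radius)
  uniq <- unique(smiles)
  mols <- ChemmineOB::forEachMol("SMILES", paste(uniq, collapse = "\n"), identity)
  if (length(mols) != length(uniq))
    abort("fingerprint generation failed for some compounds", "featurization_error")
  raw <- ChemmineOB::fingerprint_OB(mols, fpname)   # n_uniq x 4096
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)   # single unique molecule
  raw <- raw[match(smiles, uniq), , drop = FALSE]
  m <- matrix(0, nrow(raw), n_bits)
  for (block in seq_len(ceiling(ncol(raw) / n_bits))) {
    cols <- ((block - 1) * n_bits + 1):min(block * n_bits, ncol(raw))
    seg <- raw[, cols, drop = FALSE]
    if (ncol(seg) < n_bits) seg <- cbind(seg, matrix(0, nrow(seg), n_bits - ncol(seg)))
    m <- pmax(m, seg)
  }
  colnames(m) <- sprintf("bit%04d", seq_len(n_bits))
  feature_matrix(m, "circular_fingerprints")
}

#' Drop defective feature columns
#'
#' Removes every column containing at least one missing or non-finite value,
#' preserving the order of the remaining columns. Dropped names are attached
#' as attribute `dropped`.
#'
#' @param m a `feature_matrix` (or numeric matrix).
#' @return the cleaned `feature_matrix`.
#' @export
clean_features <- function(m) {
  kind <- attr(m, "kind") %||% "physchem_descriptors"
  scaled <- isTRUE(attr(m, "scaled"))
  vals <- unclass(as.matrix(m))
  bad <- apply(vals, 2, function(col) any(!is.finite(col)))
  if (all(bad)) abort("cleaning removed every feature column", "featurization_error")
  out <- feature_matrix(vals[, !bad, drop = FALSE], kind, scaled)
  attr(out, "dropped") <- colnames(vals)[bad]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a min-max scaler on training rows
#'
#' @param train a `feature_matrix` of training rows (finite values).
#' @return a `minmax_scaler`: per-feature min and max.
#' @export
fit_minmax <- function(train) {
  vals <- unclass(as.matrix(train))
  if (any(!is.finite(vals))) abort("scale input must be finite; clean first", "featurization_error")
  structure(list(min = apply(vals, 2, min), max = apply(vals, 2, max),
                 feature_names = colnames(vals)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps x to (x - min)/(max - min) per feature. Constant training columns map
#' to 0; values outside the training range are clipped to [0,1].
#'
#' @param state a `minmax_scaler` from [fit_minmax()].
#' @param m a `feature_matrix` with the same feature names.
#' @return the scaled `feature_matrix`.
#' @export
apply_minmax <- function(state, m) {
  stopifnot(inherits(state, "minmax_scaler"))
  vals <- unclass(as.matrix(m))
  if (!identical(colnames(vals), state$feature_names))
    abort("feature names do not match the fitted scaler", "schema_error")
  rng <- state$max - state$min
  out <- sweep(vals, 2, state$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  feature_matrix(out, attr(m, "kind") %||% "physchem_descriptors", scaled = TRUE)
}

#' Column-wise concatenation of descriptor matrices
#'
#' Joins two cleaned feature matrices on the same compounds with
#' kind-prefixed column names (used for runs combining both descriptor sets).
#'
#' @param a,b `feature_matrix` objects with equal row counts.
#' @return a `feature_matrix` of kind "combined_descriptors".
#' @export
combine_features <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("row counts differ", "schema_error")
  va <- unclass(as.matrix(a)); vb <- unclass(as.matrix(b))
  colnames(va) <- paste0(substr(attr(a, "kind") %||% "a", 1, 4), ".", colnames(va))
  colnames(vb) <- paste0(substr(attr(b, "kind") %||% "b", 1, 4), ".", colnames(vb))
  feature_matrix(cbind(va, vb), "combined_descriptors",
                 isTRUE(attr(a, "scaled")) && isTRUE(attr(b, "scaled")))
}
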