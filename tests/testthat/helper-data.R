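# Shared fixtures, built in code at test time.

# the 8-row curation fixture exercising every exclusion rule
curation_fixture <- function() {
  data.frame(
    smiles = c("CCO", "CCO", "c1ccccc1O", "c1ccccc1O", "[Na+].[Cl-]",
               "O=S(=O)(O)O", "CCN", "C("),
    label = c(1, 1, 1, 0, 0, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}

# a small labeled matrix with one perfect predictor column among noise
perfect_predictor_matrix <- function(n = 60, n_noise = 50, seed = 7) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * n_noise), n, n_noise)
    x <- cbind(x, signal = y)
    colnames(x) <- c(sprintf("noise%02d", seq_len(n_noise)), "signal")
    list(x = x, y = y)
  })
}

# brute-force AUC oracle: all-pairs concordance with ties counted 1/2
auc_bruteforce <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  total <- 0
  for (i in pos) for (j in neg)
    total <- total + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  total / (length(pos) * length(neg))
}

# element-by-element confusion tally oracle
confusion_bruteforce <- function(y, p) {
  out <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) out["TP"] <- out["TP"] + 1L
    if (y[i] == 0 && p[i] == 0) out["TN"] <- out["TN"] + 1L
    if (y[i] == 0 && p[i] == 1) out["FP"] <- out["FP"] + 1L
    if (y[i] == 1 && p[i] == 0) out["FN"] <- out["FN"] + 1L
  }
  out
}

# small planted-signal problem for fast model checks
small_planted <- function(seed = 1, n = 240, bits = 256, informative = 20) {
  planted_fingerprints(n_samples = n, n_features = bits,
                       n_informative = informative, seed = seed)
}
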