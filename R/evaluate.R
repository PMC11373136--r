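# Performance evaluation: confusion counts, threshold metrics (accuracy,
# sensitivity, specificity, precision, F1, balanced accuracy), rank-based
# ROC/AUC, stratified k-fold cross-validation, repeated holdouts, and
# one-way ANOVA for comparing metric groups.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred lengths differ", "schema_error")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    abort("labels must be 0/1", "schema_error")
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy Q = (TP+TN)/total, sensitivity SE = TP/(TP+FN),
#' specificity SP = TN/(TN+FP), precision PRE = TP/(TP+FP), F1 =
#' TP/(TP + (FP+FN)/2), balanced accuracy BA = (SE+SP)/2, and AUC when
#' probability scores are supplied. All metrics are fractions in [0,1]; any
#' 0/0 metric is reported as NA (undefined), never silently 0.
#'
#' @param counts output of [confusion_counts()] (or a list with TP/TN/FP/FN).
#' @param scores optional probability scores (with `y_true`) for AUC.
#' @param y_true optional true labels matching `scores`.
#' @return list of metrics: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `balanced_accuracy`, `auc`.
#' @export
classification_metrics <- function(counts, scores = NULL, y_true = NULL) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) abort("no evaluated samples", "schema_error")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- safe_div(TP, TP + FN)
  sp <- safe_div(TN, TN + FP)
  out <- list(
    accuracy = (TP + TN) / total,
    sensitivity = se,
    specificity = sp,
    precision = safe_div(TP, TP + FP),
    f1 = safe_div(TP, TP + 0.5 * (FP + FN)),
    balanced_accuracy = if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2,
    auc = NA_real_
  )
  if (!is.null(scores) && !is.null(y_true) && length(unique(y_true)) == 2)
    out$auc <- roc_auc(y_true, scores)
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted one half.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores numeric scores (higher = more positive).
#' @return AUC in [0,1].
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    abort("labels and scores lengths differ", "schema_error")
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present", "degenerate_labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores.
#' @return data.frame with `threshold`, `fpr`, `tpr` over all score cutoffs.
#' @export
roc_curve <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(which(diff(s) != 0), length(s))
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / N),
             tpr = c(0, tp[keep] / P))
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one
.stratified_folds <- function(labels, k, seed) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k))
    abort(sprintf("each class needs >= k=%d members", k), "stratification_error")
  fold <- integer(length(labels))
  with_seed(seed, {
    # deal the two classes in opposite fold orders so their remainders land
    # on different folds and total fold sizes differ by at most one
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      slots <- if (cls == 0L) seq_len(k) else rev(seq_len(k))
      fold[idx] <- rep_len(slots, length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' Re-runs the entire pipeline (scaler fit, optional feature selection, model
#' fitting) inside each training fold and evaluates on the held-out fold, so
#' no preprocessing leaks across folds.
#'
#' @param spec a [pipeline_spec()] describing the pipeline.
#' @param x a `feature_matrix` (unscaled is fine; scaling happens per fold).
#' @param y 0/1 labels.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and per-fold fits.
#' @return list with `k`, `seed`, `fold_assignment`, `per_fold` (data.frame of
#'   metrics per fold) and `summary` (mean and sd per metric).
#' @export
cross_validate <- function(spec, x, y, k = 10, seed = 1) {
  if (k < 2) abort("k must be >= 2", "config_error")
  y <- as.integer(y)
  fold <- .stratified_folds(y, k, seed)
  per <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- .fit_pipeline(spec, x[tr, , drop = FALSE], y[tr],
                         seed = child_seed(seed, f))
    p <- .predict_pipeline(fit, x[te, , drop = FALSE])
    cm <- confusion_counts(y[te], predict_label(p))
    met <- classification_metrics(cm, scores = p, y_true = y[te])
    per[[f]] <- as.data.frame(met)
  }
  per_fold <- do.call(rbind, per)
  per_fold$fold <- seq_len(k)
  metric_cols <- setdiff(names(per_fold), "fold")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  list(k = k, seed = seed, fold_assignment = fold, per_fold = per_fold,
       summary = summary)
}

#' Repeated stratified-holdout evaluation
#'
#' Re-runs the pipeline with a fresh stratified train/test split per repeat
#' (one master seed per repeat drives both the split and the model fits) and
#' summarises each metric as mean and SD across repeats.
#'
#' @param spec a [pipeline_spec()].
#' @param x feature matrix; `y` 0/1 labels.
#' @param y 0/1 labels.
#' @param n_repeats number of repeats (default 5).
#' @param test_fraction held-out proportion (default 0.2).
#' @param seeds integer vector of per-repeat seeds (default derived 1..n).
#' @return list with `per_repeat` (metrics data.frame) and `summary`
#'   (mean/sd per metric).
#' @export
repeated_holdout <- function(spec, x, y, n_repeats = 5, test_fraction = 0.2,
                             seeds = NULL) {
  if (n_repeats < 2) abort("n_repeats must be >= 2", "config_error")
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  if (length(seeds) != n_repeats) abort("need one seed per repeat", "config_error")
  y <- as.integer(y)
  per <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(y, test_fraction, seed = seeds[r])
    fit <- .fit_pipeline(spec, x[sp$train_idx, , drop = FALSE], y[sp$train_idx],
                         seed = seeds[r])
    p <- .predict_pipeline(fit, x[sp$test_idx, , drop = FALSE])
    cm <- confusion_counts(y[sp$test_idx], predict_label(p))
    per[[r]] <- as.data.frame(classification_metrics(cm, scores = p,
                                                     y_true = y[sp$test_idx]))
  }
  per_repeat <- do.call(rbind, per)
  per_repeat$seed <- seeds
  metric_cols <- setdiff(names(per_repeat), "seed")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_repeat[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_repeat[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  list(per_repeat = per_repeat, summary = summary)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio with its F-distribution tail
#' probability, for comparing metric values across model groups. Degenerate
#' inputs are resolved explicitly: zero within-group variance with equal
#' means gives F = 0, p = 1; zero within-group variance with unequal means
#' gives an infinite F and a p-value at the smallest positive double.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `F`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    abort("need at least two groups", "config_error")
  if (any(vapply(groups, length, integer(1)) < 2))
    abort("each group needs at least two values", "config_error")
  all_v <- unlist(groups)
  n <- length(all_v); g <- length(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- g - 1; df_w <- n - g
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p_value = 1, df_between = df_b, df_within = df_w))
    return(list(F = Inf, p_value = .Machine$double.xmin,
                df_between = df_b, df_within = df_w))
  }
  f_stat <- (ssb / df_b) / (ssw / df_w)
  list(F = f_stat, p_value = stats::pf(f_stat, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}
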