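# Feature ranking and sequential elimination scored by the AUC-contribution
# statistic: contribution = (AUC_w - AUC_i) / AUC_w, where AUC_w is the
# validation AUC with the whole current feature set and AUC_i the AUC after
# a removal. Positive contribution means the removed block was informative.

#' AUC contribution of a removed feature block
#'
#' @param auc_w AUC of the model with the whole feature set (in (0,1]).
#' @param auc_i AUC of the model refitted without the block (in [0,1]).
#' @return (auc_w - auc_i) / auc_w. Positive: removal hurt (the removed
#'   content was informative); negative: removal helped.
#' @export
contribution_score <- function(auc_w, auc_i) {
  if (any(auc_w <= 0)) abort("auc_w must be positive", "domain_error")
  if (any(auc_w > 1) || any(auc_i < 0) || any(auc_i > 1))
    abort("AUC values must lie in [0,1]", "domain_error")
  (auc_w - auc_i) / auc_w
}

#' Rank features by importance
#'
#' `embedded_forest` ranks by impurity-based importances of a seeded random
#' forest; `univariate_auc` ranks each feature by |per-feature AUC - 0.5|
#' (how far the single feature, used as a score, is from chance). Ties are
#' broken lexicographically by feature name so rankings are deterministic.
#'
#' @param x feature matrix with named columns.
#' @param y 0/1 labels (both classes present).
#' @param ranker "embedded_forest" (default) or "univariate_auc".
#' @param seed integer seed (forest ranker).
#' @param num_trees trees for the forest ranker (default 500).
#' @return a `feature_ranking`: data.frame `feature`, `score`, ordered most
#'   to least important, with attribute `ranker_id`.
#' @export
rank_features <- function(x, y, ranker = c("embedded_forest", "univariate_auc"),
                          seed = 1, num_trees = 500) {
  ranker <- match.arg(ranker)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("need both classes in y", "degenerate_labels")
  xm <- .as_plain_matrix(x)
  if (nrow(xm) != length(y)) abort("row count != label count", "schema_error")
  score <- if (ranker == "embedded_forest") {
    fit <- ranger::ranger(x = xm, y = factor(y, levels = c(0, 1)),
                          num.trees = num_trees, importance = "impurity",
                          seed = seed, num.threads = 1)
    imp <- fit$variable.importance
    imp[colnames(xm)]
  } else {
    vapply(seq_len(ncol(xm)), function(j) {
      v <- xm[, j]
      if (stats::sd(v) == 0) 0 else abs(roc_auc(y, v) - 0.5)
    }, numeric(1))
  }
  score[!is.finite(score)] <- 0
  ord <- order(-score, colnames(xm))        # descending score, name tie-break
  out <- data.frame(feature = colnames(xm)[ord], score = as.numeric(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "ranker_id") <- ranker
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Sequential feature elimination
#'
#' Starting from the full feature set, repeatedly removes the `step_size`
#' least-important remaining features (per the supplied ranking), refits the
#' evaluator on an internal stratified 80/20 split of the training rows, and
#' records the validation AUC and the contribution score of each step
#' against the all-features baseline. Stops once `step_size` or fewer
#' features remain (a step removing every feature is taken only when
#' `step_size` covers the whole set; its AUC is defined as chance, 0.5).
#'
#' @param x training feature matrix; `y` 0/1 labels.
#' @param y 0/1 labels.
#' @param ranking a `feature_ranking` covering the columns of `x`.
#' @param step_size features removed per step (default 5% of features, >= 1).
#' @param evaluator a `base_model_config` refitted at each step (default a
#'   500-tree random forest).
#' @param seed seed for the internal validation split.
#' @return an `elimination_trace`: data.frame with `step`, `n_retained`,
#'   `auc`, `contribution`, plus attributes `auc_w` (baseline AUC),
#'   `feature_sets` (list of retained names per step) and `step_size`.
#' @export
sequential_elimination <- function(x, y, ranking = NULL, step_size = NULL,
                                   evaluator = base_model("rf", seed = seed),
                                   seed = 1) {
  y <- as.integer(y)
  xm <- .as_plain_matrix(x)
  if (is.null(ranking)) ranking <- rank_features(x, y, seed = seed)
  if (!all(colnames(xm) %in% ranking$feature))
    abort("ranking does not cover the feature matrix", "schema_error")
  nf <- ncol(xm)
  if (is.null(step_size)) step_size <- max(1L, floor(0.05 * nf))
  if (step_size < 1) abort("step_size must be >= 1", "config_error")

  sp <- stratified_split(y, 0.2, seed = seed)
  tr <- sp$train_idx; va <- sp$test_idx
  eval_auc <- function(feats) {
    if (length(feats) == 0) return(0.5)
    fit <- tryCatch(
      fit_base_model(evaluator, xm[tr, feats, drop = FALSE], y[tr]),
      error = function(e) abort(sprintf("evaluator failed: %s",
                                        conditionMessage(e)), "member_fit_error"))
    roc_auc(y[va], predict(fit, xm[va, feats, drop = FALSE]))
  }

  ordered <- ranking$feature[ranking$feature %in% colnames(xm)]
  retained <- ordered
  auc_w <- eval_auc(retained)
  steps <- list(list(step = 0L, n_retained = nf, auc = auc_w, contribution = 0))
  sets <- list(retained)
  step_i <- 0L
  while (length(retained) > step_size || (step_i == 0L && step_size >= nf)) {
    step_i <- step_i + 1L
    drop_n <- min(step_size, length(retained))
    retained <- retained[seq_len(length(retained) - drop_n)]
    auc_i <- eval_auc(retained)
    steps[[length(steps) + 1]] <- list(step = step_i,
                                       n_retained = length(retained),
                                       auc = auc_i,
                                       contribution = contribution_score(auc_w, auc_i))
    sets[[length(sets) + 1]] <- retained
    if (length(retained) <= step_size) break
  }
  trace <- do.call(rbind, lapply(steps, as.data.frame))
  attr(trace, "auc_w") <- auc_w
  attr(trace, "feature_sets") <- sets
  attr(trace, "step_size") <- step_size
  class(trace) <- c("elimination_trace", "data.frame")
  trace
}

#' Pick the optimal feature subset from an elimination trace
#'
#' Returns the retained-feature set of the step (including the all-features
#' baseline) with the highest validation AUC; exact ties go to the smaller
#' set.
#'
#' @param trace an `elimination_trace`.
#' @return character vector of selected feature names.
#' @export
select_optimal_subset <- function(trace) {
  if (!inherits(trace, "elimination_trace") || nrow(trace) == 0)
    abort("empty elimination trace", "config_error")
  sets <- attr(trace, "feature_sets")
  best_auc <- max(trace$auc)
  cand <- which(trace$auc == best_auc)
  sizes <- trace$n_retained[cand]
  sets[[cand[which.min(sizes)]]]
}

#' Export an elimination trace
#'
#' @param trace an `elimination_trace`.
#' @param csv_path,json_path optional output files.
#' @return invisibly, the trace.
#' @export
write_trace <- function(trace, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(trace)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(auc_w = attr(trace, "auc_w"),
                              step_size = attr(trace, "step_size"),
                              steps = df), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(trace)
}
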