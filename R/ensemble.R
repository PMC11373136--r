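# Heterogeneous ensembles over the base learners: voting (soft/hard),
# bagging (bootstrap-per-member resampling), and stacking (logistic
# meta-learner on out-of-fold member probabilities). `tox_ensemble()` is the
# package's central fitting function; the returned object carries the fitted
# members and supports predict/print/summary.

#' Default five-member ensemble configuration
#'
#' The heterogeneous member set used throughout: KNN, SVC, RF, ET and the
#' LSTM recurrent net (`include_mlp` adds or substitutes the MLP, giving the
#' variants with MLP instead of, or alongside, the recurrent member).
#'
#' @param seed master seed; member seeds are derived from it.
#' @param include_rnn,include_mlp which neural members to include.
#' @param ... hyperparameter overrides applied to matching members, e.g.
#'   `rnn = list(epochs = 5)`.
#' @return list of `base_model_config`.
#' @export
default_members <- function(seed = 1, include_rnn = TRUE, include_mlp = FALSE,
                            ...) {
  overrides <- list(...)
  algos <- c("knn", "svc", "rf", "et",
             if (include_rnn) "rnn", if (include_mlp) "mlp")
  lapply(seq_along(algos), function(i) {
    a <- algos[i]
    args <- c(list(algorithm = a, seed = child_seed(seed, i)),
              overrides[[a]] %||% list())
    do.call(base_model, args)
  })
}

#' Soft vote: mean of member probabilities
#'
#' @param member_probs numeric vector (one sample) or matrix (rows = samples,
#'   columns = members) of probabilities in [0,1].
#' @return combined probability per sample (equal-weight arithmetic mean).
#' @export
soft_vote <- function(member_probs) {
  if (is.null(member_probs) || length(member_probs) == 0)
    abort("no member probabilities", "config_error")
  if (is.matrix(member_probs)) rowMeans(member_probs) else mean(member_probs)
}

#' Hard vote: majority label
#'
#' Exact ties go to class 1 (the toxic class), favouring sensitivity in a
#' screening setting.
#'
#' @param member_labels 0/1 vector (one sample) or matrix (rows = samples).
#' @return majority label per sample.
#' @export
hard_vote <- function(member_labels) {
  if (is.null(member_labels) || length(member_labels) == 0)
    abort("no member labels", "config_error")
  frac <- if (is.matrix(member_labels)) rowMeans(member_labels) else mean(member_labels)
  as.integer(frac >= 0.5)
}

#' Fit a heterogeneous classifier ensemble
#'
#' Fits the member base models on `x`/`y` and combines them by the chosen
#' strategy. Voting averages member probabilities (soft, default) or takes
#' the majority of member labels (hard). Bagging refits every member
#' `n_bootstrap` times on bootstrap resamples of the training rows and
#' soft-votes over all member-by-replicate probabilities. Stacking builds
#' out-of-fold member probabilities on the training rows (stratified
#' `k_oof`-fold), fits a logistic meta-learner on them, and at predict time
#' feeds full-fit member probabilities to the meta-learner.
#'
#' @param x feature matrix (rows = compounds, named columns).
#' @param y 0/1 labels.
#' @param strategy "voting", "bagging" or "stacking".
#' @param members list of `base_model_config` (default [default_members()]).
#' @param voting_mode "soft" or "hard" (voting strategy only).
#' @param n_bootstrap bootstrap replicates per member (bagging; default 5).
#' @param k_oof folds for out-of-fold meta features (stacking; default 5).
#' @param seed master seed for resampling/fold assignment.
#' @param resample set FALSE to disable bootstrap resampling (then bagging
#'   with `n_bootstrap = 1` reduces exactly to voting).
#' @return a fitted `tox_ensemble`.
#' @export
tox_ensemble <- function(x, y, strategy = c("voting", "bagging", "stacking"),
                         members = default_members(seed), voting_mode = c("soft", "hard"),
                         n_bootstrap = 5, k_oof = 5, seed = 1, resample = TRUE) {
  strategy <- match.arg(strategy)
  voting_mode <- match.arg(voting_mode)
  if (length(members) == 0) abort("members must be non-empty", "config_error")
  y <- as.integer(y)
  fitted <- switch(strategy,
    voting = .fit_members(members, x, y),
    bagging = .fit_bagged(members, x, y, n_bootstrap, seed, resample),
    stacking = NULL)
  meta <- NULL; oof <- NULL
  if (strategy == "stacking") {
    if (k_oof < 2) abort("k_oof must be >= 2", "config_error")
    oof <- .oof_probabilities(members, x, y, k_oof, seed)
    # separable meta-problems are routine on strong members; the warning
    # glm emits then is expected and harmless
    meta <- suppressWarnings(
      stats::glm.fit(cbind(1, oof), y, family = stats::binomial())$coefficients)
    meta[is.na(meta)] <- 0     # aliased (collinear member) coefficients
    fitted <- .fit_members(members, x, y)
  }
  structure(list(strategy = strategy, members = members, fitted = fitted,
                 voting_mode = voting_mode, n_bootstrap = n_bootstrap,
                 k_oof = k_oof, seed = seed, meta = meta,
                 oof_features = oof, n_train = nrow(x),
                 feature_names = colnames(x)),
            class = "tox_ensemble")
}

.fit_members <- function(members, x, y) {
  lapply(seq_along(members), function(i) {
    tryCatch(fit_base_model(members[[i]], x, y), error = function(e) {
      abort(sprintf("member %d (%s) failed to fit: %s", i,
                    members[[i]]$algorithm, conditionMessage(e)),
            "member_fit_error")
    })
  })
}

.fit_bagged <- function(members, x, y, n_bootstrap, seed, resample) {
  if (n_bootstrap < 1) abort("n_bootstrap must be >= 1", "config_error")
  n <- nrow(x)
  fits <- list()
  for (i in seq_along(members)) {
    for (b in seq_len(n_bootstrap)) {
      idx <- if (resample)
        with_seed(child_seed(seed, i * 1000 + b), sample.int(n, n, replace = TRUE))
      else seq_len(n)
      # reseed later replicates so they differ; replicate 1 keeps the member
      # seed, making bagging with n_bootstrap = 1 and resampling disabled
      # coincide exactly with voting
      cfg <- members[[i]]
      if (b > 1) cfg$seed <- child_seed(cfg$seed, b)
      fit <- tryCatch(fit_base_model(cfg, x[idx, , drop = FALSE], y[idx]),
                      error = function(e)
                        abort(sprintf("member %d (%s) replicate %d failed: %s",
                                      i, members[[i]]$algorithm, b,
                                      conditionMessage(e)), "member_fit_error"))
      fits[[length(fits) + 1]] <- fit
    }
  }
  fits
}

# out-of-fold member probabilities: every training row is predicted by models
# fitted without it
.oof_probabilities <- function(members, x, y, k_oof, seed) {
  fold <- .stratified_folds(y, k_oof, seed)
  oof <- matrix(NA_real_, nrow(x), length(members))
  for (f in seq_len(k_oof)) {
    tr <- which(fold != f); te <- which(fold == f)
    fits <- .fit_members(members, x[tr, , drop = FALSE], y[tr])
    for (j in seq_along(fits))
      oof[te, j] <- predict(fits[[j]], x[te, , drop = FALSE])
  }
  colnames(oof) <- vapply(members, function(m) m$algorithm, character(1))
  oof
}

#' Predict with a fitted ensemble
#'
#' @param object a `tox_ensemble`.
#' @param newdata feature matrix with the training schema.
#' @param type "prob" (combined probability), "label", or "members" (matrix
#'   of per-member probabilities).
#' @param threshold decision threshold for labels (default 0.5).
#' @param ... unused.
#' @return probabilities, labels, or the member probability matrix.
#' @export
predict.tox_ensemble <- function(object, newdata, type = c("prob", "label", "members"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  probs <- vapply(object$fitted, function(f) predict(f, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1) probs <- matrix(probs, nrow = 1)
  if (type == "members") {
    colnames(probs) <- vapply(object$fitted,
                              function(f) f$config$algorithm, character(1))
    return(probs)
  }
  p <- switch(object$strategy,
    voting = if (object$voting_mode == "hard")
      hard_vote(matrix(as.integer(probs >= threshold), nrow(probs))) * 1.0
    else soft_vote(probs),
    bagging = soft_vote(probs),
    stacking = {
      eta <- cbind(1, probs) %*% object$meta
      as.numeric(1 / (1 + exp(-eta)))
    })
  if (type == "label") predict_label(p, threshold) else p
}

#' @export
print.tox_ensemble <- function(x, ...) {
  algos <- vapply(x$members, function(m) m$algorithm, character(1))
  cat(sprintf("Hepatotoxicity %s ensemble (%s): members %s; trained on %d compounds x %d features\n",
              x$strategy,
              if (x$strategy == "voting") x$voting_mode else
                if (x$strategy == "bagging") sprintf("%d bootstraps/member", x$n_bootstrap)
                else sprintf("%d-fold OOF meta", x$k_oof),
              paste(algos, collapse = "+"), x$n_train, length(x$feature_names)))
  invisible(x)
}

#' Summarise a fitted ensemble on evaluation data
#'
#' @param object a `tox_ensemble`.
#' @param x,y optional evaluation data; when supplied, per-member and
#'   combined metrics are reported.
#' @param ... unused.
#' @return invisibly, a data.frame of metrics (when data supplied).
#' @export
summary.tox_ensemble <- function(object, x = NULL, y = NULL, ...) {
  print(object)
  if (is.null(x) || is.null(y)) return(invisible(NULL))
  y <- as.integer(y)
  probs <- predict(object, x, type = "members")
  rows <- lapply(seq_len(ncol(probs)), function(j) {
    p <- probs[, j]
    met <- classification_metrics(confusion_counts(y, predict_label(p)),
                                  scores = p, y_true = y)
    data.frame(model = colnames(probs)[j], as.data.frame(met))
  })
  pc <- predict(object, x)
  met <- classification_metrics(confusion_counts(y, predict_label(pc)),
                                scores = pc, y_true = y)
  out <- rbind(do.call(rbind, rows),
               data.frame(model = "ensemble", as.data.frame(met)))
  print(out, digits = 4, row.names = FALSE)
  invisible(out)
}
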