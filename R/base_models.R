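# The six base learners behind the ensembles, under one fit /
# predict-probability contract: four shallow members (KNN, SVC with Platt
# probabilities, random forest, extremely randomized trees) wrap installed
# implementations; the two neural members (LSTM recurrent net, MLP) are
# implemented in this package (src/lstm.cpp and R/mlp.R).

.algorithms <- c("knn", "svc", "rf", "et", "rnn", "mlp")

.default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    knn = list(k = 5),
    svc = list(kernel = "radial", cost = 1),
    rf  = list(n_estimators = 500),
    et  = list(n_estimators = 500),
    rnn = list(units = 64, layers = 2, dropout = 0.2, learning_rate = 0.001,
               epochs = 10, batch_size = 128, seq_len = 32),
    mlp = list(hidden_sizes = c(100, 50), max_iter = 500, learning_rate = 0.001)
  )
}

#' Declare a base-model configuration
#'
#' Defaults follow the reference setup: KNN with k = 5; forests with 500
#' trees (the grid 100/300/500/700 is available through `n_estimators` as a
#' vector, resolved by internal validation AUC); RBF-kernel SVC with Platt
#' probability calibration; a 2-layer LSTM of 64 units with dropout 0.2,
#' learning rate 0.001, 10 epochs, batch size 128; an MLP with hidden layers
#' 100 and 50 and at most 500 iterations.
#'
#' @param algorithm one of "knn", "svc", "rf", "et", "rnn", "mlp".
#' @param ... hyperparameter overrides (see defaults above). For "rnn",
#'   `seq_len` sets how the feature vector is folded into a sequence
#'   (timesteps; the remaining features become channels per step).
#' @param seed integer seed used by the fit.
#' @return a `base_model_config`.
#' @export
base_model <- function(algorithm, ..., seed = 1) {
  if (!algorithm %in% .algorithms)
    abort(sprintf("unknown algorithm '%s'", algorithm), "config_error")
  hp <- .default_hyperparameters(algorithm)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown) > 0)
    abort(sprintf("unknown hyperparameters for %s: %s", algorithm,
                  paste(unknown, collapse = ", ")), "config_error")
  hp[names(dots)] <- dots
  .validate_hyperparameters(algorithm, hp)
  structure(list(algorithm = algorithm, hyperparameters = hp, seed = seed),
            class = "base_model_config")
}

.validate_hyperparameters <- function(algorithm, hp) {
  bad <- switch(algorithm,
    knn = hp$k < 1,
    svc = hp$cost <= 0,
    rf  = any(hp$n_estimators < 1),
    et  = any(hp$n_estimators < 1),
    rnn = hp$units < 1 || hp$layers < 1 || hp$dropout < 0 || hp$dropout >= 1 ||
          hp$learning_rate <= 0 || hp$epochs < 1 || hp$batch_size < 1 ||
          hp$seq_len < 1,
    mlp = any(hp$hidden_sizes < 1) || hp$max_iter < 1 || hp$learning_rate <= 0
  )
  if (isTRUE(bad)) abort(sprintf("invalid hyperparameters for %s", algorithm),
                         "config_error")
  invisible(TRUE)
}

#' @export
print.base_model_config <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v) paste(v, collapse = "/"),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("Base model config: %s (%s), seed %d\n", x$algorithm, hp, x$seed))
  invisible(x)
}

.as_plain_matrix <- function(x) {
  m <- unclass(as.matrix(x))
  attr(m, "kind") <- NULL; attr(m, "scaled") <- NULL; attr(m, "row_index") <- NULL
  storage.mode(m) <- "double"
  m
}

#' Fit a base model
#'
#' @param config a `base_model_config` from [base_model()].
#' @param x feature matrix (rows = compounds) with column names.
#' @param y 0/1 labels.
#' @return a `fitted_base_model`; use `predict(fit, x)` for probabilities of
#'   class 1 and `predict(fit, x, type = "label")` for thresholded labels.
#' @export
fit_base_model <- function(config, x, y) {
  stopifnot(inherits(config, "base_model_config"))
  x <- .as_plain_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("need both classes in y", "degenerate_labels")
  if (ncol(x) < 1) abort("need at least one feature", "config_error")
  if (nrow(x) != length(y)) abort("row count != label count", "schema_error")
  hp <- config$hyperparameters
  seed <- config$seed
  state <- switch(config$algorithm,
    knn = {
      if (hp$k > nrow(x))
        abort(sprintf("k = %d exceeds the %d training rows", hp$k, nrow(x)),
              "config_error")
      list(x = x, y = y, k = hp$k)
    },
    svc = with_seed(seed, e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), kernel = hp$kernel,
      cost = hp$cost, probability = TRUE, scale = FALSE)),
    rf  = .fit_forest(x, y, hp$n_estimators, seed, extratrees = FALSE),
    et  = .fit_forest(x, y, hp$n_estimators, seed, extratrees = TRUE),
    rnn = .lstm_fit_wrapper(x, y, hp, seed),
    mlp = .mlp_fit(x, y, hidden = hp$hidden_sizes, max_iter = hp$max_iter,
                   lr = hp$learning_rate, seed = seed)
  )
  log <- switch(config$algorithm,
    rnn = data.frame(epoch = seq_along(state$loss), loss = state$loss),
    mlp = data.frame(epoch = seq_along(state$loss), loss = state$loss),
    data.frame(epoch = integer(0), loss = numeric(0)))
  structure(list(config = config, feature_names = colnames(x),
                 state = state, training_log = log),
            class = "fitted_base_model")
}

# forest fit via ranger; n_estimators may be a grid, resolved by internal
# stratified 80/20 validation AUC
.fit_forest <- function(x, y, n_estimators, seed, extratrees) {
  fit_one <- function(xx, yy, ntree, sd) {
    args <- list(x = xx, y = factor(yy, levels = c(0, 1)), num.trees = ntree,
                 probability = TRUE, seed = sd, num.threads = 1)
    if (extratrees) {
      args$splitrule <- "extratrees"; args$num.random.splits <- 1
      args$replace <- FALSE; args$sample.fraction <- 1
    }
    do.call(ranger::ranger, args)
  }
  if (length(n_estimators) > 1) {
    sp <- stratified_split(y, 0.2, seed = seed)
    aucs <- vapply(n_estimators, function(nt) {
      f <- fit_one(x[sp$train_idx, , drop = FALSE], y[sp$train_idx], nt, seed)
      p <- predict(f, x[sp$test_idx, , drop = FALSE])$predictions[, "1"]
      roc_auc(y[sp$test_idx], p)
    }, numeric(1))
    n_estimators <- n_estimators[which.max(aucs)]
  }
  fit_one(x, y, n_estimators, seed)
}

#' Predict with a fitted base model
#'
#' @param object a `fitted_base_model`.
#' @param newdata feature matrix with the training schema (same column names).
#' @param type "prob" for probability of class 1, "label" for 0/1 labels.
#' @param threshold decision threshold for `type = "label"` (default 0.5).
#' @param ... unused.
#' @return numeric probabilities or integer labels, one per row.
#' @export
predict.fitted_base_model <- function(object, newdata, type = c("prob", "label"),
                                      threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- .as_plain_matrix(newdata)
  if (!identical(colnames(x), object$feature_names))
    abort("feature names do not match the training schema", "schema_error")
  hp <- object$config$hyperparameters
  p <- switch(object$config$algorithm,
    knn = {
      st <- object$state
      pred <- class::knn(st$x, x, factor(st$y, levels = c(0, 1)),
                         k = st$k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    svc = {
      pr <- attr(predict(object$state, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    rf = predict(object$state, x, num.threads = 1)$predictions[, "1"],
    et = predict(object$state, x, num.threads = 1)$predictions[, "1"],
    rnn = .lstm_predict_wrapper(object$state, x),
    mlp = .mlp_predict(object$state, x)
  )
  p <- as.numeric(p)
  p[p < 0] <- 0; p[p > 1] <- 1
  if (type == "label") predict_label(p, threshold) else p
}

#' Threshold probabilities into labels
#'
#' @param probabilities numeric vector in [0,1].
#' @param threshold decision threshold in (0,1); label is 1 iff probability
#'   >= threshold.
#' @return integer 0/1 vector.
#' @export
predict_label <- function(probabilities, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    abort("threshold must lie in (0,1)", "config_error")
  as.integer(probabilities >= threshold)
}

#' @export
print.fitted_base_model <- function(x, ...) {
  cat(sprintf("Fitted %s base model on %d features\n",
              x$config$algorithm, length(x$feature_names)))
  invisible(x)
}
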