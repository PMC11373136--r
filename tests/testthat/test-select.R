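test_that("contribution score matches its closed form and sign convention", {
  expect_equal(contribution_score(0.8, 0.8), 0)
  expect_equal(contribution_score(0.8, 0.72), 0.1)
  expect_equal(contribution_score(0.8, 0.84), -0.05)
  expect_error(contribution_score(0, 0.5), class = "domain_error")
})

test_that("contribution score is zero iff AUCs agree and strictly decreasing in auc_i", {
  withr::with_seed(11, {
    a <- runif(50, 0.01, 1)
    expect_equal(contribution_score(a, a), rep(0, 50))
    for (w in runif(10, 0.3, 1)) {
      ai <- sort(runif(20, 0, 1))
      sc <- contribution_score(w, ai)
      expect_true(all(diff(sc) < 0))
    }
  })
})

test_that("both rankers put a perfect predictor first", {
  pp <- perfect_predictor_matrix()
  for (r in c("embedded_forest", "univariate_auc")) {
    rk <- rank_features(pp$x, pp$y, ranker = r, seed = 2)
    expect_equal(rk$feature[1], "signal")
    expect_true(all(is.finite(rk$score)))
    expect_true(all(diff(rk$score) <= 0))
  }
})

test_that("all-constant features tie and break lexicographically", {
  x <- matrix(1, 20, 4, dimnames = list(NULL, c("delta", "alpha", "charlie", "bravo")))
  y <- rep(c(0, 1), 10)
  rk <- rank_features(x, y, ranker = "univariate_auc")
  expect_equal(rk$feature, c("alpha", "bravo", "charlie", "delta"))
  expect_equal(length(unique(rk$score)), 1)
})

test_that("ranking is deterministic given a seed", {
  d <- small_planted(seed = 3)
  r1 <- rank_features(d$x, d$y, seed = 9)
  r2 <- rank_features(d$x, d$y, seed = 9)
  expect_identical(r1$feature, r2$feature)
})

test_that("elimination stopping rules: step 5 of 10 features; step covering all", {
  pp <- perfect_predictor_matrix(n = 80, n_noise = 9)
  ev <- base_model("rf", n_estimators = 50, seed = 1)
  tr <- sequential_elimination(pp$x, pp$y, step_size = 5, evaluator = ev, seed = 1)
  expect_equal(nrow(tr), 2)                       # baseline + one removal step
  expect_equal(tr$n_retained, c(10, 5))
  # a step removing everything is taken only when step_size spans the set
  tr_all <- sequential_elimination(pp$x, pp$y, step_size = 10, evaluator = ev, seed = 1)
  expect_equal(nrow(tr_all), 2)
  expect_equal(tr_all$n_retained[2], 0)
  expect_equal(tr_all$auc[2], 0.5)                # empty model scores chance
})

test_that("removing trailing pure-noise features barely moves the AUC", {
  d <- small_planted(seed = 4, n = 300)
  rk <- rank_features(d$x, d$y, seed = 4)
  tr <- sequential_elimination(d$x, d$y, rk, step_size = 5,
                               evaluator = base_model("rf", n_estimators = 100, seed = 4),
                               seed = 4)
  expect_lte(abs(tr$contribution[2]), 0.02)
})

test_that("elimination trace sets are strictly nested and AUCs bounded", {
  d <- small_planted(seed = 6, n = 200, bits = 64, informative = 10)
  tr <- sequential_elimination(d$x, d$y, step_size = 16,
                               evaluator = base_model("rf", n_estimators = 100, seed = 6),
                               seed = 6)
  sets <- attr(tr, "feature_sets")
  expect_true(all(diff(tr$n_retained) < 0))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  expect_true(all(tr$auc >= 0 & tr$auc <= 1))
})

test_that("optimal subset is the argmax step with ties toward fewer features", {
  fake <- function(aucs, sizes) {
    tr <- data.frame(step = seq_along(aucs) - 1, n_retained = sizes, auc = aucs,
                     contribution = 0)
    attr(tr, "feature_sets") <- lapply(sizes, function(k) paste0("f", seq_len(k)))
    attr(tr, "auc_w") <- aucs[1]
    class(tr) <- c("elimination_trace", "data.frame")
    tr
  }
  sel <- select_optimal_subset(fake(c(0.80, 0.82, 0.79), c(10, 6, 3)))
  expect_length(sel, 6)
  sel2 <- select_optimal_subset(fake(c(0.80, 0.80), c(10, 5)))
  expect_length(sel2, 5)
})

test_that("selection induces no optimism when labels are independent of features", {
  withr::with_seed(31, {
    n <- 200
    x <- matrix(rbinom(n * 64, 1, 0.3), n, 64,
                dimnames = list(NULL, sprintf("b%02d", 1:64)))
    y <- rbinom(n, 1, 0.5)
  })
  holdout <- stratified_split(y, 0.25, seed = 31)
  xtr <- x[holdout$train_idx, ]; ytr <- y[holdout$train_idx]
  tr <- sequential_elimination(xtr, ytr, step_size = 16,
                               evaluator = base_model("rf", n_estimators = 100, seed = 31),
                               seed = 31)
  sel <- select_optimal_subset(tr)
  if (length(sel) > 0) {
    fit <- fit_base_model(base_model("rf", n_estimators = 100, seed = 31),
                          xtr[, sel, drop = FALSE], ytr)
    auc <- roc_auc(y[holdout$test_idx],
                   predict(fit, x[holdout$test_idx, sel, drop = FALSE]))
    expect_lt(abs(auc - 0.5), 0.2)
  }
})

test_that("trace export round-trips through CSV", {
  d <- small_planted(seed = 8, n = 120, bits = 32, informative = 8)
  tr <- sequential_elimination(d$x, d$y, step_size = 8,
                               evaluator = base_model("rf", n_estimators = 50, seed = 8),
                               seed = 8)
  csv <- tempfile(fileext = ".csv")
  write_trace(tr, csv_path = csv)
  back <- read.csv(csv)
  expect_equal(back$auc, tr$auc)
  expect_equal(back$n_retained, tr$n_retained)
})
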