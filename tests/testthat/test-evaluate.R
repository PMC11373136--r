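test_that("confusion counts follow the four definitions", {
  cm <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cm, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  y <- c(1, 0, 1, 1, 0)
  expect_equal(confusion_counts(y, y)[c("FP", "FN")], list(FP = 0L, FN = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), class = "schema_error")
})

test_that("confusion counts agree with an element-by-element tally on random vectors", {
  withr::with_seed(33, {
    for (rep in 1:200) {
      y <- rbinom(50, 1, runif(1, 0.2, 0.8))
      p <- rbinom(50, 1, runif(1, 0.2, 0.8))
      cm <- confusion_counts(y, p)
      oracle <- confusion_bruteforce(y, p)
      expect_equal(unlist(cm), oracle[names(unlist(cm))])
    }
  })
})

test_that("metrics match hand arithmetic on the worked confusion example", {
  met <- classification_metrics(list(TP = 3, TN = 2, FP = 1, FN = 0))
  expect_equal(met$accuracy, 5 / 6)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$precision, 0.75)
  expect_equal(met$f1, 3 / 3.5)
  expect_equal(met$specificity, 2 / 3)
  expect_equal(met$balanced_accuracy, (1 + 2 / 3) / 2)
})

test_that("perfect prediction scores 1 everywhere; 0/0 metrics surface as NA", {
  met <- classification_metrics(confusion_counts(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unlist(met[c("accuracy", "sensitivity", "specificity",
                            "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1, f1 = 1))
  none_pos <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$precision))
  expect_true(is.na(none_pos$balanced_accuracy))
})

test_that("accuracy decomposes as the class-weighted mean of SE and SP", {
  withr::with_seed(34, {
    for (rep in 1:50) {
      y <- rbinom(40, 1, 0.5); p <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      cm <- confusion_counts(y, p)
      met <- classification_metrics(cm)
      P <- cm$TP + cm$FN; N <- cm$TN + cm$FP
      expect_equal(met$accuracy,
                   (met$sensitivity * P + met$specificity * N) / (P + N))
    }
  })
})

test_that("AUC matches exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  withr::with_seed(35, {
    for (rep in 1:100) {
      n <- sample(10:100, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- sample(round(runif(n), 2))        # rounded scores force ties
      expect_lt(abs(roc_auc(y, s) - auc_bruteforce(y, s)), 1e-9)
    }
  })
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), class = "degenerate_labels")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(36, {
    y <- rbinom(60, 1, 0.5); s <- runif(60)
    a <- roc_auc(y, s)
    expect_equal(roc_auc(y, 10 * s - 3), a)
    expect_equal(roc_auc(y, exp(s)), a)
    expect_equal(roc_auc(y, rank(s)), a)
  })
})

test_that("ROC curve starts at (0,0), ends at (1,1), and is monotone", {
  withr::with_seed(37, {
    y <- rbinom(80, 1, 0.6); s <- runif(80)
  })
  rc <- roc_curve(y, s)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("cross-validation folds partition the data with near-equal sizes", {
  d <- small_planted(seed = 38, n = 25, bits = 16, informative = 6)
  spc <- pipeline_spec(base_model("rf", n_estimators = 50, seed = 1), scale = FALSE)
  cv <- cross_validate(spc, d$x, d$y, k = 5, seed = 2)
  sizes <- table(cv$fold_assignment)
  expect_equal(sum(sizes), 25)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(cv$summary$mean >= vapply(cv$summary$metric, function(m)
    min(cv$per_fold[[m]], na.rm = TRUE), numeric(1))))
  expect_true(all(cv$summary$mean <= vapply(cv$summary$metric, function(m)
    max(cv$per_fold[[m]], na.rm = TRUE), numeric(1))))
  # same seed reproduces the folds bit for bit
  cv2 <- cross_validate(spc, d$x, d$y, k = 5, seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$per_fold, cv2$per_fold)
  expect_error(cross_validate(spc, d$x, d$y, k = 200, seed = 1),
               class = "stratification_error")
})

test_that("repeated holdout with identical seeds collapses to zero SD", {
  d <- small_planted(seed = 39, n = 100, bits = 32, informative = 8)
  spc <- pipeline_spec(base_model("rf", n_estimators = 50, seed = 1), scale = FALSE)
  rh <- repeated_holdout(spc, d$x, d$y, n_repeats = 3, seeds = c(7, 7, 7))
  expect_true(all(rh$summary$sd == 0, na.rm = TRUE))
  # summary means equal the mean of the per-repeat reports
  rh2 <- repeated_holdout(spc, d$x, d$y, n_repeats = 3, seeds = c(1, 2, 3))
  expect_equal(rh2$summary$mean[rh2$summary$metric == "auc"],
               mean(rh2$per_repeat$auc))
})

test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  a <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(a$F, 8)                      # SSB = 4 (df 1), SSW = 1 (df 2)
  expect_equal(a$p_value, stats::pf(8, 1, 2, lower.tail = FALSE))
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0); expect_equal(same$p_value, 1)
  degen <- one_way_anova(list(c(2, 2), c(5, 5)))
  expect_equal(degen$F, Inf)
  expect_lte(degen$p_value, .Machine$double.xmin)
  expect_error(one_way_anova(list(1:3)), class = "config_error")
  expect_error(one_way_anova(list(1, 1:3)), class = "config_error")
})

test_that("ANOVA agrees with the classical reference implementation", {
  withr::with_seed(40, {
    for (rep in 1:20) {
      g <- lapply(1:3, function(i) rnorm(sample(3:8, 1), mean = runif(1, 0, 2)))
      ours <- one_way_anova(g)
      ref <- stats::oneway.test(
        v ~ grp, data = data.frame(v = unlist(g),
                                   grp = factor(rep(seq_along(g), lengths(g)))),
        var.equal = TRUE)
      expect_equal(ours$F, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value)
    }
  })
})
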