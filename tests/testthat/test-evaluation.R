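# Grouped folds, feature selection, nested CV, aggregation, variants

test_that("grouped folds keep patients together and balance counts", {
  pts <- rep(sprintf("P%02d", 1:10), times = sample(2:6, 10, replace = TRUE))
  f <- grouped_folds(pts, 5, seed = 1)
  tab <- table(pts, f)
  expect_true(all(rowSums(tab > 0) == 1))  # each patient in exactly one fold
  per_fold <- table(vapply(split(f, pts), `[`, numeric(1), 1))
  expect_true(max(per_fold) - min(per_fold) <= 1)
  expect_identical(f, grouped_folds(pts, 5, seed = 1))
  expect_error(grouped_folds(rep("P1", 10), 2), "distinct patients")
})

test_that("L1-SVM selection keeps informative columns and falls back gracefully", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 400; p <- 51
    y <- runif(n) < 0.5
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + 2 * y
    keep <- feature_select_l1svm(scale(x), y, C = 0.05)
    if (1 %in% keep) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  set.seed(11)
  x <- matrix(rnorm(200), 100, 2)
  y <- runif(100) < 0.5
  expect_warning(keep <- feature_select_l1svm(x, y, C = 1e-9), "no features")
  expect_equal(keep, 1:2)
  expect_error(feature_select_l1svm(x, rep(TRUE, 100)), "both classes")

  # duplicated informative column: at least one of the pair retained
  set.seed(12)
  x <- matrix(rnorm(400 * 20), 400, 20)
  y <- runif(400) < 0.5
  x[, 1] <- x[, 1] + 2 * y
  x[, 2] <- x[, 1]
  keep <- feature_select_l1svm(scale(x), y, C = 0.05)
  expect_true(any(c(1, 2) %in% keep))
})

test_that("epoch aggregation is an exact quantile with interpolation", {
  expect_equal(unname(aggregate_epoch_predictions(c(0.2, 0.8, 0.4), rep("a", 3), 0.5)),
               0.4)
  expect_equal(unname(aggregate_epoch_predictions(0.7, "a", 0.3)), 0.7)
  expect_equal(unname(aggregate_epoch_predictions(seq(0.1, 1, 0.1), rep("a", 10), 0.9)),
               0.91)
  expect_error(aggregate_epoch_predictions(0.5, "a", 0.95), "0.1, 0.9")
  set.seed(1)
  sc <- runif(30); id <- rep(c("a", "b", "c"), 10)
  agg <- aggregate_epoch_predictions(sc, id, 0.3)
  expect_equal(unname(agg["b"]), unname(quantile(sc[id == "b"], 0.3)))
})

test_that("nested CV recovers an injected effect and respects grouping", {
  fm <- make_sim_fm(n_pat = 50, d = 1.5, seed = 21)
  sp <- model_spec("glm_logistic_l1l2", grid = data.frame(alpha = 1, C = 1),
                   select_c = 0.1)
  cv <- nested_cv_evaluate(fm, sp, seed = 2)
  expect_gt(cv$result$auc, 0.8)
  expect_true(cv$result$ci_low <= cv$result$auc && cv$result$auc <= cv$result$ci_high)
  # fold manifest: every patient in exactly one fold
  expect_false(any(duplicated(cv$fold_manifest$patient_id)))
  # determinism
  cv2 <- nested_cv_evaluate(fm, sp, seed = 2)
  expect_equal(cv$result$auc, cv2$result$auc)
})

test_that("two-step rule overrides flagged EEGs only", {
  sc <- c(0.1, 0.6, 0.3)
  expect_equal(two_step_classify(c(TRUE, FALSE, FALSE), sc), c(1.0, 0.6, 0.3))
  expect_equal(two_step_classify(c(FALSE, FALSE, FALSE), sc), sc)
  # flags predicting a case subset + informative model: combined beats flags alone
  set.seed(5)
  n <- 200
  y <- runif(n) < 0.4
  flag <- y & runif(n) < 0.5
  model <- plogis(qlogis(0.3) + 1.5 * y + rnorm(n))
  comb <- two_step_classify(flag, model)
  expect_gte(auc_mw(comb, y), auc_mw(as.numeric(flag), y))
})

test_that("age interactions double the feature count and use training stats", {
  fm <- make_sim_fm(n_pat = 10, n_ep = 2, p = 7)
  age <- rep(seq(20, 65, length.out = 10), each = 2)
  out <- add_age_interactions(fm, age)
  expect_equal(ncol(out$x), 2 * 7 + 1)
  stats <- attr(out, "age_stats")
  held <- add_age_interactions(fm, age, train_stats = c(40, 10))
  expect_equal(unname(held$x[1, "age_scaled"]), (age[1] - 40) / 10)
  # a row at the training mean has zero interactions
  at_mean <- add_age_interactions(fm, rep(stats[1], 20), train_stats = stats)
  expect_true(all(abs(at_mean$x[, grep("^ageX", colnames(at_mean$x))]) < 1e-12))
  expect_error(add_age_interactions(fm, c(NA, age[-1])), "eeg_id")
})

test_that("holdout evaluation blocks patient leakage and reports binary metrics", {
  fm_tr <- make_sim_fm(n_pat = 30, d = 1.5, seed = 31)
  fm_te <- make_sim_fm(n_pat = 20, d = 1.5, seed = 32)
  fm_te$patient_id <- sub("P", "Q", fm_te$patient_id)
  fm_te$eeg_id <- sub("E", "F", fm_te$eeg_id)
  sp <- model_spec("glm_logistic_l1l2", grid = data.frame(alpha = 1, C = 1),
                   select_c = 0.1)
  res <- holdout_evaluate(fm_tr, fm_te, sp, seed = 3)
  expect_gt(res$result$auc, 0.7)
  expect_identical(res$result$ci_method, "delong")
  expect_setequal(res$metrics$metric, c("sensitivity", "specificity", "ppv", "npv"))
  leaky <- fm_te
  leaky$patient_id[1:3] <- fm_tr$patient_id[1]
  expect_error(holdout_evaluate(fm_tr, leaky, sp), "both splits")
})
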