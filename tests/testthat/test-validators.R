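test_that("stratified folds balance stages exactly on the default cohort", {
  cohort <- simulate_cohort(500, seed = 51)
  fold <- stratified_folds(cohort, 5, seed = 52)
  expect_equal(unname(table(fold)), rep(100L, 5), ignore_attr = TRUE)
  tab <- table(fold, cohort$stage)
  expect_true(all(tab == matrix(rep(c(16, 21, 63), each = 5), 5)))
})

test_that("fold partitions are disjoint, exhaustive and near-balanced per stage", {
  withr::with_seed(53, {
    for (i in 1:20) {
      n <- sample(60:400, 1)
      k <- sample(2:7, 1)
      cohort <- simulate_cohort(n)
      fold <- suppressWarnings(stratified_folds(cohort, k))
      expect_identical(length(fold), n)
      expect_true(all(fold %in% 1:k))
      tab <- table(factor(fold, levels = 1:k), cohort$stage)
      expect_true(all(apply(tab, 2, function(col) diff(range(col)) <= 1)))
    }
  })
})

test_that("fold edge cases behave: leave-one-out, determinism, bad k", {
  cohort <- simulate_cohort(20, seed = 54)
  loo <- suppressWarnings(stratified_folds(cohort, 20, seed = 1))
  expect_identical(sort(loo), 1:20)
  expect_identical(suppressWarnings(stratified_folds(cohort, 4, seed = 9)),
                   suppressWarnings(stratified_folds(cohort, 4, seed = 9)))
  expect_error(stratified_folds(cohort, 21), class = "valsim_invalid_argument")
  expect_error(stratified_folds(cohort, 1), class = "valsim_invalid_argument")
  expect_warning(stratified_folds(cohort, 15, seed = 2), "fewer than k")
})

test_that("stratified split reproduces the 400/100 holdout design", {
  cohort <- simulate_cohort(500, seed = 55)
  parts <- stratified_split(cohort, 0.2, seed = 56)
  expect_identical(nrow(parts$holdout), 100L)
  expect_identical(nrow(parts$train), 400L)
  expect_equal(unname(table(parts$holdout$stage)), c(16L, 21L, 63L),
               ignore_attr = TRUE)
  expect_error(stratified_split(cohort, 1.2), class = "valsim_invalid_argument")
})

test_that("cross-validation covers the cohort once per repeat", {
  cohort <- simulate_labeled_cohort(500, seed = 57)
  folds <- cross_validate(cohort, k = 5, repeats = 2, seed = 58)
  expect_identical(nrow(folds), 10L)
  sizes <- dplyr::summarise(dplyr::group_by(folds, cv_repeat),
                            total = sum(n_test))
  expect_true(all(sizes$total == 500))
  expect_true(all(is.finite(folds$auc)))
  expect_true(all(folds$auc >= 0 & folds$auc <= 1))
  expect_true(all(folds$n_events <= folds$n_test))
})

test_that("holdout validation refits on the training part only", {
  cohort <- simulate_labeled_cohort(500, seed = 59)
  hv <- holdout_validate(cohort, seed = 60)
  expect_identical(hv$holdout$n_test, 100L)
  expect_identical(nrow(hv$cv), 5L)
  expect_true(is.finite(hv$holdout$auc))
  skipped <- holdout_validate(cohort, cv_repeats = 0, seed = 60)
  expect_identical(nrow(skipped$cv), 0L)
  expect_identical(skipped$holdout, hv$holdout)
})

test_that("bootstrap optimism vanishes when resampling is the identity", {
  cohort <- simulate_labeled_cohort(300, seed = 61)
  res <- bootstrap_validate(cohort, n_boot = 3, seed = 62,
                            sampler = function(n) seq_len(n))
  expect_equal(res$optimism_auc, 0, tolerance = 1e-12)
  expect_equal(res$auc, res$apparent_auc)
  expect_equal(res$calibration_slope, res$apparent_slope, tolerance = 1e-6)
  # apparent slope of an ML fit on its own data is 1 by construction
  expect_equal(res$apparent_slope, 1, tolerance = 1e-6)
})

test_that("bootstrap correction removes optimism from the apparent AUC", {
  cohort <- simulate_labeled_cohort(300, seed = 63)
  res <- bootstrap_validate(cohort, n_boot = 25, seed = 64)
  expect_gt(res$optimism_auc, 0)
  expect_lt(res$auc, res$apparent_auc)
  expect_identical(res$n_redrawn, 0L)
})

test_that("external validation on the training cohort equals apparent performance", {
  train <- simulate_labeled_cohort(400, seed = 65)
  ev <- external_validate(train, train)
  fit <- fit_logistic(train)
  expect_equal(ev$external$auc,
               roc_auc(predict_probability(fit, train), train$outcome))
  expect_equal(ev$external$calibration_slope, 1, tolerance = 1e-6)

  test <- simulate_labeled_cohort(500, seed = 66)
  ev2 <- external_validate(train, test, cv_repeats = 1, seed = 67)
  expect_identical(nrow(ev2$cv), 5L)
  expect_identical(ev2$external$n_test, 500L)
  expect_s3_class(ev2$model, "risk_model")
})

test_that("degenerate folds are recorded as failures, not dropped", {
  cohort <- simulate_labeled_cohort(60, seed = 68)
  cohort$outcome[cohort$stage == 2] <- 1L # tiny folds may go single-class
  folds <- cross_validate(cohort, k = 5, repeats = 1, seed = 69)
  expect_identical(nrow(folds), 5L)
  expect_true(all(!is.na(folds$error) | is.finite(folds$auc)))
})
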