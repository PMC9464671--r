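test_that("published model matches its frozen coefficient values", {
  model <- published_coefficients()
  beta <- model$coefficients
  expect_equal(unname(beta["(Intercept)"]), -6.532)
  expect_equal(unname(beta["age_gt60"]), 0.773)
  expect_identical(published_coefficients()$coefficients, beta)
})

test_that("linear predictor reproduces hand arithmetic", {
  patient <- tibble::tibble(log_mtv = 12.0, log_suvpeak = 2.78,
                            log_dmax = 5.4, age_gt60 = 0, who_gt1 = 0)
  lp <- linear_predictor(published_coefficients(), patient)
  expect_equal(lp, -6.532 + 0.533 * 12 - 1.395 * 2.78 + 0.257 * 5.4)
  expect_equal(lp, -2.6263, tolerance = 1e-6)
  expect_equal(predict_probability(published_coefficients(), patient),
               1 / (1 + exp(2.6263)), tolerance = 1e-4)

  zero <- dplyr::mutate(patient, log_mtv = 0, log_suvpeak = 0, log_dmax = 0)
  expect_equal(linear_predictor(published_coefficients(), zero), -6.532)

  aged <- dplyr::mutate(patient, age_gt60 = 1)
  expect_equal(linear_predictor(published_coefficients(), aged) - lp, 0.773)
})

test_that("probability is the elementwise logistic map of the linear predictor", {
  cohort <- simulate_cohort(500, seed = 21)
  lp <- linear_predictor(published_coefficients(), cohort)
  p <- predict_probability(published_coefficients(), cohort)
  expect_identical(p, plogis(lp))
  expect_true(all(p > 0 & p < 1))
  # risk strictly increasing in MTV
  bumped <- dplyr::mutate(cohort, log_mtv = log_mtv + 0.5)
  expect_true(all(predict_probability(published_coefficients(), bumped) > p))
})

test_that("ML refit recovers the generating coefficients within 3 SE", {
  cohort <- bernoulli_cohort(2e4, seed = 41)
  fit <- fit_logistic(cohort)
  truth <- published_coefficients()$coefficients
  expect_true(all(abs(fit$coefficients - truth) < 3 * fit$std_error))
  # score equations vanish at the optimum
  x <- cbind(1, as.matrix(as.data.frame(cohort)[, c("log_mtv", "log_suvpeak",
                                                    "log_dmax", "age_gt60",
                                                    "who_gt1")]))
  score <- t(x) %*% (cohort$outcome - predict_probability(fit, cohort))
  expect_lt(max(abs(score)), 1e-6)
})

test_that("refit is invariant to duplicating every row", {
  cohort <- simulate_labeled_cohort(300, seed = 43)
  single <- fit_logistic(cohort)
  doubled <- fit_logistic(dplyr::bind_rows(cohort, cohort))
  expect_equal(single$coefficients, doubled$coefficients, tolerance = 1e-7)
})

test_that("refit deviance never exceeds the published model's deviance", {
  cohort <- simulate_labeled_cohort(80, seed = 47)
  fit <- fit_logistic(cohort)
  expect_lte(model_deviance(fit, cohort),
             model_deviance(published_coefficients(), cohort) + 1e-8)
  expect_equal(fit$deviance, model_deviance(fit, cohort), tolerance = 1e-8)
})

test_that("degenerate outcomes and separation are flagged errors", {
  cohort <- simulate_labeled_cohort(60, seed = 3)
  cohort$outcome <- 1L
  expect_error(fit_logistic(cohort), class = "valsim_degenerate_data")

  sep <- simulate_cohort(60, seed = 13)
  sep$log_mtv <- rep(c(9, 15), each = 30) + stats::runif(60)
  sep$outcome <- as.integer(sep$log_mtv > 12)
  expect_error(fit_logistic(sep), class = "valsim_nonconvergence")
})

test_that("tidiers expose terms and fit metadata", {
  fit <- fit_logistic(simulate_labeled_cohort(400, seed = 8))
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n, 400L)
  expect_true(gl$converged)
  expect_identical(nrow(tidy(published_coefficients())), 6L)
})

test_that("coefficients round-trip through JSON at full precision", {
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(published_coefficients(), path)
  back <- read_coefficients(path)
  expect_identical(back$coefficients, published_coefficients()$coefficients)
})
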