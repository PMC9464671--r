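test_that("simulated log-PET metrics match their stage profile", {
  n <- 2e4
  cohort <- simulate_cohort(n, single_stage_profiles(4), seed = 11)
  p <- single_stage_profiles(4)
  for (col in c("log_suvpeak", "log_mtv", "log_dmax")) {
    mu <- p[[paste0("mu_", col)]]
    sd_true <- p[[paste0("sd_", col)]]
    expect_lt(abs(mean(cohort[[col]]) - mu), 4 * sd_true / sqrt(n))
    expect_lt(abs(sd(cohort[[col]]) - sd_true), 4 * sd_true / sqrt(2 * n))
  }
})

test_that("binary flags realize exact per-stage counts in exact mode", {
  cohort <- simulate_cohort(100, single_stage_profiles(2), seed = 5)
  expect_identical(sum(cohort$age_gt60), 30L)
  expect_identical(sum(cohort$who_gt1), 23L)
  # bernoulli mode is stochastic but unbiased: loose 4-SE band
  big <- simulate_cohort(1e4, single_stage_profiles(2), seed = 6,
                         flag_mode = "bernoulli")
  expect_lt(abs(mean(big$age_gt60) - 0.30), 4 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("cohort simulation is bitwise reproducible under a seed", {
  a <- simulate_cohort(250, seed = 123)
  b <- simulate_cohort(250, seed = 123)
  expect_identical(a, b)
  expect_error(simulate_cohort(0), class = "valsim_invalid_argument")
})

test_that("outcome relabeling follows the exact-count algebra", {
  cfg <- outcome_config(fpr = 0.45, fnr = 0.15)
  cohort <- assign_outcomes(toy_risk_cohort(200, 300), cfg, seed = 2)
  expect_identical(sum(cohort$outcome), (200L - 90L) + 45L)

  withr::with_seed(17, {
    for (i in 1:100) {
      n_high <- sample(0:150, 1)
      n_low <- sample(0:150, 1)
      if (n_high + n_low == 0) n_low <- 1
      fpr <- stats::runif(1)
      fnr <- stats::runif(1)
      out <- assign_outcomes(toy_risk_cohort(n_high, n_low),
                             outcome_config(fpr = fpr, fnr = fnr))
      expected <- (n_high - round(fpr * n_high)) + round(fnr * n_low)
      expect_identical(sum(out$outcome), as.integer(expected))
    }
  })
})

test_that("degenerate relabel fractions reduce to threshold logic", {
  cohort <- add_risk_probability(simulate_cohort(200, seed = 4))
  clean <- assign_outcomes(cohort, outcome_config(fpr = 0, fnr = 0))
  expect_identical(clean$outcome, as.integer(clean$true_p >= 0.375))
  flipped <- assign_outcomes(cohort, outcome_config(fpr = 1, fnr = 1))
  expect_identical(flipped$outcome, 1L - clean$outcome)
})

test_that("assign_outcomes demands a true risk probability", {
  expect_error(assign_outcomes(simulate_cohort(10, seed = 1)),
               class = "valsim_state_error")
})

test_that("EARL2 transforms shift metrics but never labels", {
  cohort <- simulate_labeled_cohort(300, seed = 9)
  identity <- apply_earl2(cohort, earl2_transform())
  expect_identical(identity, cohort)

  shifted <- apply_earl2(cohort, earl2_transform(offset_log_suvpeak = 0.1))
  expect_equal(shifted$log_suvpeak, cohort$log_suvpeak + 0.1)
  expect_identical(shifted$outcome, cohort$outcome)

  scaled <- apply_earl2(cohort, earl2_transform(scale_log_mtv = 1.07,
                                                offset_log_mtv = -0.2))
  expect_equal(scaled$log_mtv, 1.07 * cohort$log_mtv - 0.2)
  expect_identical(sum(scaled$outcome), sum(cohort$outcome))

  expect_error(earl2_transform(scale_log_mtv = 0),
               class = "valsim_invalid_argument")
  unlabeled <- simulate_cohort(10, seed = 2)
  expect_error(apply_earl2(unlabeled, earl2_transform()),
               class = "valsim_state_error")
})

test_that("the one-call generator reproduces the chained pipeline", {
  direct <- simulate_labeled_cohort(200, seed = 31)
  chained <- withr::with_seed(31, {
    assign_outcomes(add_risk_probability(simulate_cohort(200)))
  })
  expect_identical(direct, chained)
})
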