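# O(n^2) pairwise-concordance oracle for the rank-based AUC implementation
pairwise_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# minimal labeled cohort with directly controlled true risk probabilities:
# n_high patients above the 0.375 cutoff, n_low below
toy_risk_cohort <- function(n_high, n_low, p_high = 0.9, p_low = 0.1) {
  tibble::tibble(true_p = rep(c(p_high, p_low), c(n_high, n_low)))
}

# covariates drawn from the default generator, labels drawn as Bernoulli
# draws from a known model: ground truth for ML recovery checks
bernoulli_cohort <- function(n, model = published_coefficients(), seed = 1) {
  withr::with_seed(seed, {
    cohort <- simulate_cohort(n)
    cohort$outcome <- stats::rbinom(n, 1, predict_probability(model, cohort))
    cohort
  })
}
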