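#' Simulate a stage-stratified synthetic DLBCL cohort
#'
#' Draws a cohort of `n` patients from stage-specific profiles. Stage sizes
#' are fixed deterministically by [stage_counts()]. Within each stage the
#' three log-scale PET metrics are independent normal draws with the
#' stage's mean/SD, mirroring how the study population was sampled with
#' `rnorm` on log-transformed PET parameters. The two binary clinical
#' flags realize their stage prevalence either as an exact rounded count
#' randomly permuted across the stage's patients (`flag_mode = "exact"`,
#' the default, reflecting that fixed clinically observed percentages were
#' used) or as independent Bernoulli draws (`flag_mode = "bernoulli"`).
#'
#' @param n Cohort size (positive integer).
#' @param profiles Stage profile table; defaults to [dlbcl_stage_profiles()].
#' @param seed Optional integer seed; when supplied the draw is fully
#'   reproducible and the ambient RNG state is restored afterwards.
#' @param flag_mode `"exact"` or `"bernoulli"` (see Details).
#' @return A tibble with columns `patient_id`, `stage`, `log_suvpeak`,
#'   `log_mtv`, `log_dmax`, `age_gt60`, `who_gt1`.
#' @examples
#' cohort <- simulate_cohort(500, seed = 1)
#' dplyr::count(cohort, stage)
#' @export
simulate_cohort <- function(n, profiles = dlbcl_stage_profiles(), seed = NULL,
                            flag_mode = c("exact", "bernoulli")) {
  flag_mode <- match.arg(flag_mode)
  profiles <- validate_profiles(profiles)
  if (length(n) != 1 || !is.finite(n) || n <= 0 || n != floor(n)) {
    stop_invalid("n must be a single positive integer")
  }
  counts <- stage_counts(profiles, n)
  profiles <- profiles[match(counts$stage, profiles$stage), ]

  with_seed_if(seed, {
    rows <- purrr::map(seq_len(nrow(profiles)), function(i) {
      m <- counts$count[i]
      if (m == 0) return(NULL)
      p <- profiles[i, ]
      tibble(
        stage       = rep(p$stage, m),
        log_suvpeak = rnorm(m, p$mu_log_suvpeak, p$sd_log_suvpeak),
        log_mtv     = rnorm(m, p$mu_log_mtv, p$sd_log_mtv),
        log_dmax    = rnorm(m, p$mu_log_dmax, p$sd_log_dmax),
        age_gt60    = draw_flags(m, p$p_age_gt60, flag_mode),
        who_gt1     = draw_flags(m, p$p_who_gt1, flag_mode)
      )
    })
    out <- bind_rows(rows)
    out$patient_id <- seq_len(nrow(out))
    out[, c("patient_id", setdiff(names(out), "patient_id"))]
  })
}

draw_flags <- function(m, p, flag_mode) {
  if (flag_mode == "bernoulli") return(rbinom(m, 1L, p))
  n1 <- as.integer(round(p * m))
  permute(rep(c(1L, 0L), c(n1, m - n1)))
}

#' Outcome-generation configuration
#'
#' Parameters of the threshold-plus-misclassification outcome mechanism:
#' patients with true risk probability at or above `cutoff` are provisional
#' events ("high risk"); then a fixed fraction `fpr` of the high-risk
#' patients is relabeled as non-events and a fixed fraction `fnr` of the
#' low-risk patients as events. Note `fpr`/`fnr` are the study's label-noise
#' fractions, not classical confusion-matrix rates. Defaults (0.375, 0.45,
#' 0.15) match the noise levels observed clinically for the published model.
#'
#' @param cutoff Probability threshold in (0, 1) for the high-risk group.
#' @param fpr Fraction of high-risk patients relabeled as non-events.
#' @param fnr Fraction of low-risk patients relabeled as events.
#' @return An object of class `outcome_config`.
#' @examples
#' outcome_config(cutoff = 0.10)
#' @export
outcome_config <- function(cutoff = 0.375, fpr = 0.45, fnr = 0.15) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1) {
    stop_invalid("cutoff must lie strictly in (0, 1)")
  }
  if (!is.finite(fpr) || fpr < 0 || fpr > 1) stop_invalid("fpr must lie in [0, 1]")
  if (!is.finite(fnr) || fnr < 0 || fnr > 1) stop_invalid("fnr must lie in [0, 1]")
  structure(list(cutoff = cutoff, fpr = fpr, fnr = fnr),
            class = "outcome_config")
}

#' @export
print.outcome_config <- function(x, ...) {
  cat(sprintf(
    "<outcome_config> cutoff = %g, relabel high->0: %g%%, low->1: %g%%\n",
    x$cutoff, 100 * x$fpr, 100 * x$fnr
  ))
  invisible(x)
}

#' Attach the true risk probability to a cohort
#'
#' Adds (or overwrites) the `true_p` column: the risk probability of each
#' patient under `model`, by default the published logistic risk model.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param model A [risk_model] object or named coefficient vector; defaults
#'   to [published_coefficients()].
#' @return The cohort with a `true_p` column.
#' @export
add_risk_probability <- function(cohort, model = published_coefficients()) {
  cohort$true_p <- predict_probability(model, cohort)
  cohort
}

#' Assign noisy outcome labels to a cohort
#'
#' Implements the threshold-plus-relabeling outcome mechanism. Provisional
#' labels are `true_p >= cutoff`; then exactly `round(fpr * H)` of the `H`
#' high-risk patients (chosen uniformly without replacement) are flipped to
#' non-events, and exactly `round(fnr * L)` of the `L` low-risk patients to
#' events. The exact-count rule makes the resulting event count the
#' deterministic identity `(H - round(fpr * H)) + round(fnr * L)`.
#'
#' @param cohort A cohort tibble containing `true_p` (see
#'   [add_risk_probability()]).
#' @param config An [outcome_config()].
#' @param seed Optional integer seed.
#' @return The cohort with an integer `outcome` column (0/1).
#' @examples
#' simulate_cohort(100, seed = 1) |>
#'   add_risk_probability() |>
#'   assign_outcomes(seed = 2)
#' @export
assign_outcomes <- function(cohort, config = outcome_config(), seed = NULL) {
  if (!inherits(config, "outcome_config")) {
    stop_invalid("config must be an outcome_config()")
  }
  if (!"true_p" %in% names(cohort) || anyNA(cohort$true_p)) {
    stop_state("cohort must carry a complete true_p column; see add_risk_probability()")
  }
  with_seed_if(seed, {
    y <- as.integer(cohort$true_p >= config$cutoff)
    high <- which(y == 1L)
    low <- which(y == 0L)
    y[draw(high, round(config$fpr * length(high)))] <- 0L
    y[draw(low, round(config$fnr * length(low)))] <- 1L
    cohort$outcome <- y
    cohort
  })
}

#' EARL2-style PET reconstruction perturbation
#'
#' Affine transform of the log-scale PET metrics, emulating the shift
#' between EARL1- and EARL2-compliant reconstructions of the same scans:
#' each configured metric `x` becomes `scale * x + offset` on the log
#' scale. No default offset/scale values are claimed; they must be supplied
#' from reconstruction-comparison data.
#'
#' @param offset_log_suvpeak,offset_log_mtv,offset_log_dmax Additive shifts
#'   on the log scale.
#' @param scale_log_suvpeak,scale_log_mtv,scale_log_dmax Multiplicative
#'   factors (must be > 0).
#' @return An object of class `earl2_transform`.
#' @examples
#' earl2_transform(offset_log_suvpeak = 0.1, scale_log_mtv = 1.05)
#' @export
earl2_transform <- function(offset_log_suvpeak = 0, scale_log_suvpeak = 1,
                            offset_log_mtv = 0, scale_log_mtv = 1,
                            offset_log_dmax = 0, scale_log_dmax = 1) {
  offsets <- c(log_suvpeak = offset_log_suvpeak,
               log_mtv = offset_log_mtv,
               log_dmax = offset_log_dmax)
  scales <- c(log_suvpeak = scale_log_suvpeak,
              log_mtv = scale_log_mtv,
              log_dmax = scale_log_dmax)
  if (any(!is.finite(offsets))) stop_invalid("offsets must be finite")
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop_invalid("scales must be finite and > 0")
  }
  structure(list(offsets = offsets, scales = scales),
            class = "earl2_transform")
}

#' Apply an EARL2 perturbation to a labeled cohort
#'
#' Rescales the cohort's PET metrics with an [earl2_transform()]. The
#' transform mimics re-reconstruction of the same scans, so it is applied
#' after outcome labels exist and leaves outcomes, flags and `true_p`
#' (the label-generating probability) untouched.
#'
#' @param cohort A labeled cohort (must contain `outcome`).
#' @param transform An [earl2_transform()].
#' @return The cohort with transformed `log_suvpeak`, `log_mtv`, `log_dmax`.
#' @export
apply_earl2 <- function(cohort, transform) {
  if (!inherits(transform, "earl2_transform")) {
    stop_invalid("transform must be an earl2_transform()")
  }
  if (!"outcome" %in% names(cohort)) {
    stop_state("apply_earl2 expects a cohort with outcomes already assigned")
  }
  for (metric in names(transform$offsets)) {
    cohort[[metric]] <- transform$scales[[metric]] * cohort[[metric]] +
      transform$offsets[[metric]]
  }
  cohort
}

#' Simulate a fully labeled cohort in one call
#'
#' Chains [simulate_cohort()], [add_risk_probability()],
#' [assign_outcomes()] and (optionally) [apply_earl2()] under a single
#' seed. This is the generator the validators and scenario runners use.
#'
#' @inheritParams simulate_cohort
#' @param model Risk model used to compute `true_p`; defaults to
#'   [published_coefficients()].
#' @param config An [outcome_config()].
#' @param earl2 Optional [earl2_transform()] applied after labeling.
#' @return A labeled cohort tibble.
#' @examples
#' simulate_labeled_cohort(500, seed = 42)
#' @export
simulate_labeled_cohort <- function(n, profiles = dlbcl_stage_profiles(),
                                    model = published_coefficients(),
                                    config = outcome_config(),
                                    seed = NULL,
                                    flag_mode = c("exact", "bernoulli"),
                                    earl2 = NULL) {
  flag_mode <- match.arg(flag_mode)
  with_seed_if(seed, {
    cohort <- simulate_cohort(n, profiles, flag_mode = flag_mode)
    cohort <- add_risk_probability(cohort, model)
    cohort <- assign_outcomes(cohort, config)
    if (!is.null(earl2)) cohort <- apply_earl2(cohort, earl2)
    cohort
  })
}
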