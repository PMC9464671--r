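#' Stage-specific simulation profiles for DLBCL cohorts
#'
#' Per-stage generative parameters for synthetic diffuse large B-cell
#' lymphoma cohorts: the cohort fraction in each Ann Arbor stage, the mean
#' and SD of three natural-log PET metrics (SUVpeak, metabolic tumor volume
#' MTV, and the bulk dissemination distance Dmax), and the prevalence of the
#' two binary clinical flags (age > 60 years, WHO performance status > 1).
#'
#' `dlbcl_stage_profiles()` returns the default profile set observed
#' clinically in a 296-patient DLBCL trial population: stages 2/3/4 at
#' 16/21/63 percent, log SUVpeak 2.78/2.78/2.84 (SD 0.50), log MTV
#' 12.0/12.0/13.0 (SD 1.5), log Dmax 4.74/5.4/5.8 (SD 0.6), age > 60 at 30
#' percent in every stage and WHO > 1 at 23/16/6 percent.
#'
#' @return A tibble with one row per stage and columns `stage`,
#'   `prevalence`, `mu_log_suvpeak`, `sd_log_suvpeak`, `mu_log_mtv`,
#'   `sd_log_mtv`, `mu_log_dmax`, `sd_log_dmax`, `p_age_gt60`, `p_who_gt1`.
#' @seealso [simulate_cohort()], [single_stage_profiles()],
#'   [set_stage_prevalence()]
#' @examples
#' dlbcl_stage_profiles()
#' @export
dlbcl_stage_profiles <- function() {
  tibble(
    stage          = c(2L, 3L, 4L),
    prevalence     = c(0.16, 0.21, 0.63),
    mu_log_suvpeak = c(2.78, 2.78, 2.84),
    sd_log_suvpeak = c(0.50, 0.50, 0.50),
    mu_log_mtv     = c(12.0, 12.0, 13.0),
    sd_log_mtv     = c(1.5, 1.5, 1.5),
    mu_log_dmax    = c(4.74, 5.4, 5.8),
    sd_log_dmax    = c(0.6, 0.6, 0.6),
    p_age_gt60     = c(0.30, 0.30, 0.30),
    p_who_gt1      = c(0.23, 0.16, 0.06)
  )
}

profile_columns <- c(
  "stage", "prevalence",
  "mu_log_suvpeak", "sd_log_suvpeak",
  "mu_log_mtv", "sd_log_mtv",
  "mu_log_dmax", "sd_log_dmax",
  "p_age_gt60", "p_who_gt1"
)

#' Validate a stage-profile table
#'
#' Checks that a profile table has the required columns, strictly positive
#' SDs, probabilities in \[0, 1\], unique stage labels, and prevalences that
#' sum to 1 within `1e-9`.
#'
#' @param profiles A data frame shaped like [dlbcl_stage_profiles()].
#' @return The validated profiles as a tibble, invisibly usable in a pipe.
#' @export
validate_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  missing_cols <- setdiff(profile_columns, names(profiles))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0(
      "profiles is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(profiles) == 0) stop_invalid("profiles must have at least one stage")
  if (anyDuplicated(profiles$stage)) stop_invalid("stage labels must be unique")
  sds <- c(profiles$sd_log_suvpeak, profiles$sd_log_mtv, profiles$sd_log_dmax)
  if (any(!is.finite(sds)) || any(sds <= 0)) stop_invalid("all SDs must be finite and > 0")
  probs <- c(profiles$prevalence, profiles$p_age_gt60, profiles$p_who_gt1)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_invalid("prevalences and flag probabilities must lie in [0, 1]")
  }
  if (abs(sum(profiles$prevalence) - 1) > 1e-9) {
    stop_invalid("stage prevalences must sum to 1 (within 1e-9)")
  }
  profiles
}

#' Restrict the default profiles to a single stage
#'
#' Convenience constructor for external-validation scenarios in which the
#' test population consists of one Ann Arbor stage only (prevalence set
#' to 1, per-stage PET and flag parameters unchanged).
#'
#' @param stage One of the stage labels present in `profiles`.
#' @param profiles Profile table to restrict; defaults to
#'   [dlbcl_stage_profiles()].
#' @return A one-row profile tibble.
#' @examples
#' single_stage_profiles(4)
#' @export
single_stage_profiles <- function(stage, profiles = dlbcl_stage_profiles()) {
  profiles <- validate_profiles(profiles)
  out <- profiles[profiles$stage == stage, ]
  if (nrow(out) != 1) stop_invalid(paste0("no profile for stage ", stage))
  out$prevalence <- 1
  out
}

#' Replace the stage prevalences of a profile table
#'
#' @param profiles Profile table; defaults to [dlbcl_stage_profiles()].
#' @param prevalence Numeric vector of new prevalences, one per row of
#'   `profiles`, summing to 1.
#' @return The modified, validated profile tibble.
#' @examples
#' set_stage_prevalence(prevalence = c(0.33, 0.33, 0.34))
#' @export
set_stage_prevalence <- function(profiles = dlbcl_stage_profiles(), prevalence) {
  if (length(prevalence) != nrow(profiles)) {
    stop_invalid("prevalence must have one entry per profile row")
  }
  profiles$prevalence <- prevalence
  validate_profiles(profiles)
}

# Largest-remainder apportionment of `total` into integer counts
# proportional to `weights`; ties in the remainders are broken by
# `tie_order` (ascending), so the rule is fully deterministic.
largest_remainder <- function(weights, total, tie_order = seq_along(weights)) {
  quota <- weights / sum(weights) * total
  # guard against floating-point quotas like 104.99999999999999 for exact cases
  quota <- round(quota, 9)
  counts <- floor(quota)
  shortfall <- total - sum(counts)
  if (shortfall > 0) {
    rem <- quota - counts
    top_up <- order(-rem, tie_order)[seq_len(shortfall)]
    counts[top_up] <- counts[top_up] + 1
  }
  as.integer(counts)
}

#' Deterministic per-stage patient counts
#'
#' Allocates a cohort of size `n` across the stages of a profile table in
#' proportion to the stage prevalences, using largest-remainder rounding so
#' the counts always sum to exactly `n`. Remainder ties are broken in favour
#' of the lower stage label.
#'
#' @param profiles Profile table (see [dlbcl_stage_profiles()]).
#' @param n Non-negative cohort size.
#' @return A tibble with columns `stage` and `count`.
#' @examples
#' stage_counts(dlbcl_stage_profiles(), 500)
#' @export
stage_counts <- function(profiles, n) {
  profiles <- validate_profiles(profiles)
  if (length(n) != 1 || !is.finite(n) || n < 0 || n != floor(n)) {
    stop_invalid("n must be a single non-negative integer")
  }
  ord <- order(profiles$stage)
  profiles <- profiles[ord, ]
  tibble(
    stage = profiles$stage,
    count = largest_remainder(profiles$prevalence, n, tie_order = profiles$stage)
  )
}
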