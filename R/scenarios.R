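#' Derive a per-repeat seed from a master seed
#'
#' Deterministic splitting rule used by the scenario runners: repeat `i`
#' of the stream salted with `salt` uses
#' `seed = (master * 48271 + salt * 30269 + i * 69621) mod (2^31 - 87) + 1`.
#' All arithmetic stays below 2^53, so the rule is exact in doubles and
#' the result always fits a 32-bit integer.
#'
#' @param master_seed Integer master seed.
#' @param index Repeat index (>= 1).
#' @param salt Integer stream salt (e.g. from a scenario id).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, index, salt = 0) {
  m <- 2147483560
  s <- (as.numeric(master_seed) %% m) * 48271 +
    (as.numeric(salt) %% m) * 30269 + as.numeric(index) * 69621
  as.integer(s %% m + 1)
}

id_salt <- function(id) {
  codes <- utf8ToInt(id)
  sum(codes * seq_along(codes)) %% 29989
}

#' Define a validation scenario
#'
#' A scenario bundles one validation approach with the generative
#' conditions of its cohorts. Overrides (`test_profiles`, `test_outcome`,
#' `earl2`) apply only to the external test cohort; the training side
#' always uses the default study conditions unless `profiles`/`outcome`
#' are set explicitly.
#'
#' @param id Stable string identifier (e.g. `"ext_stage4_only"`).
#' @param validator One of `"cv"`, `"holdout"`, `"bootstrap"`, `"external"`.
#' @param n Cohort size for internal validators, or training-cohort size
#'   for the external validator.
#' @param test_n External test-cohort size (external validator only).
#' @param profiles,outcome Generative conditions of the (training) cohort;
#'   `NULL` means the defaults [dlbcl_stage_profiles()] / [outcome_config()].
#' @param test_profiles,test_outcome Overrides for the external cohort;
#'   `NULL` inherits the training-side conditions.
#' @param earl2 Optional [earl2_transform()] applied to the external
#'   cohort after labeling.
#' @param k Folds for cross-validation (default 5).
#' @param cv_repeats Inner CV repeats per outer repeat (default 1 for the
#'   cv validator; training-side CV of holdout/external runs is reporting
#'   only and defaults off there).
#' @param holdout_fraction Holdout fraction (holdout validator).
#' @param n_boot Bootstrap resamples (bootstrap validator).
#' @param outer_repeats Independent replications, each with freshly
#'   simulated cohorts (default 100).
#' @param paper_label Free-text label recorded in summaries.
#' @param skip Mark the scenario as skipped (used for the EARL2 row when
#'   no transform values are supplied).
#' @return An object of class `scenario_spec`.
#' @seealso [run_scenario()], [default_scenarios()]
#' @export
scenario_spec <- function(id,
                          validator = c("cv", "holdout", "bootstrap", "external"),
                          n = 500, test_n = 500,
                          profiles = NULL, outcome = NULL,
                          test_profiles = NULL, test_outcome = NULL,
                          earl2 = NULL, k = 5,
                          cv_repeats = if (match.arg(validator) == "cv") 1 else 0,
                          holdout_fraction = 0.2, n_boot = 500,
                          outer_repeats = 100, paper_label = id,
                          skip = FALSE) {
  validator <- match.arg(validator)
  if (n <= 0 || test_n <= 0) stop_invalid("cohort sizes must be positive")
  if (outer_repeats < 1) stop_invalid("outer_repeats must be >= 1")
  structure(
    list(id = id, validator = validator, n = n, test_n = test_n,
         profiles = profiles, outcome = outcome,
         test_profiles = test_profiles, test_outcome = test_outcome,
         earl2 = earl2, k = k, cv_repeats = cv_repeats,
         holdout_fraction = holdout_fraction, n_boot = n_boot,
         outer_repeats = outer_repeats, paper_label = paper_label,
         skip = skip),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %s> validator = %s, n = %d%s, repeats = %d%s\n",
              x$id, x$validator, x$n,
              if (x$validator == "external") paste0(", test_n = ", x$test_n) else "",
              x$outer_repeats, if (x$skip) " [skipped]" else ""))
  invisible(x)
}

#' The default scenario battery
#'
#' The full comparison: three internal approaches on 500-patient cohorts
#' (repeated five-fold CV, 20% holdout, 500-resample bootstrap), external
#' test sets of 100/200/500 patients under identical conditions, an EARL2
#' reconstruction shift (skipped unless transform values are supplied),
#' four external case-mix shifts (equal stage prevalences and single-stage
#' populations), three positivity-cutoff shifts (0.10/0.66/0.90) and three
#' symmetric label-noise levels (12%/45%/25%). Training cohorts for all
#' external rows hold 400 patients under default conditions.
#'
#' @param outer_repeats Replications per scenario (default 100; 25 is the
#'   fast profile used in the package's own checks).
#' @param earl2 Optional [earl2_transform()] enabling the EARL2 row.
#' @return A named list of [scenario_spec()] objects (17 rows).
#' @examples
#' names(default_scenarios())
#' @export
default_scenarios <- function(outer_repeats = 100, earl2 = NULL) {
  ext <- function(id, paper_label, ...) {
    scenario_spec(id, "external", n = 400,
                  outer_repeats = outer_repeats, paper_label = paper_label, ...)
  }
  specs <- list(
    scenario_spec("cv", "cv", n = 500, outer_repeats = outer_repeats,
                  paper_label = "1: five-fold CV"),
    scenario_spec("holdout", "holdout", n = 500, outer_repeats = outer_repeats,
                  paper_label = "2: 20% holdout"),
    scenario_spec("bootstrap", "bootstrap", n = 500,
                  outer_repeats = outer_repeats,
                  paper_label = "3: bootstrap (Harrell)"),
    ext("ext_n100", "4: external n=100", test_n = 100),
    ext("ext_n200", "4: external n=200", test_n = 200),
    ext("ext_n500", "4: external n=500"),
    ext("ext_earl2", "5: EARL2 reconstruction", earl2 = earl2,
        skip = is.null(earl2)),
    ext("ext_stage_equal", "6: stage mix 33/33/34",
        test_profiles = set_stage_prevalence(prevalence = c(0.33, 0.33, 0.34))),
    ext("ext_stage2_only", "6: 100% stage 2",
        test_profiles = single_stage_profiles(2)),
    ext("ext_stage3_only", "6: 100% stage 3",
        test_profiles = single_stage_profiles(3)),
    ext("ext_stage4_only", "6: 100% stage 4",
        test_profiles = single_stage_profiles(4)),
    ext("ext_cutoff_010", "7: positivity rate 0.10",
        test_outcome = outcome_config(cutoff = 0.10)),
    ext("ext_cutoff_066", "7: positivity rate 0.66",
        test_outcome = outcome_config(cutoff = 0.66)),
    ext("ext_cutoff_090", "7: positivity rate 0.90",
        test_outcome = outcome_config(cutoff = 0.90)),
    ext("ext_fprfnr_12", "8: FPR/FNR 12%/12%",
        test_outcome = outcome_config(fpr = 0.12, fnr = 0.12)),
    ext("ext_fprfnr_45", "8: FPR/FNR 45%/45%",
        test_outcome = outcome_config(fpr = 0.45, fnr = 0.45)),
    ext("ext_fprfnr_25", "8: FPR/FNR 25%/25%",
        test_outcome = outcome_config(fpr = 0.25, fnr = 0.25))
  )
  names(specs) <- vapply(specs, function(s) s$id, character(1))
  specs
}

#' Run one validation scenario
#'
#' Executes `outer_repeats` independent replications of a scenario. Every
#' replication re-simulates its cohorts from scratch under a repeat seed
#' derived from `master_seed` (see [derive_seed()]; the scenario id salts
#' the stream so scenarios sharing a master seed stay independent),
#' dispatches to the scenario's validator, and collects the evaluation
#' records. Fold/repeat records with failed fits or undefined metrics are
#' kept with their error message and excluded from the summaries, which
#' report mean, SD and 95% percentile interval via [summarize_metric()].
#'
#' @param spec A [scenario_spec()].
#' @param master_seed Integer master seed (default 1).
#' @param model Risk model generating `true_p`; defaults to
#'   [published_coefficients()].
#' @return An object of class `scenario_result`: a list with `id`, `spec`,
#'   `results` (one row per evaluation record), `auc` and
#'   `calibration_slope` summaries, and `n_failed`.
#' @examples
#' spec <- scenario_spec("cv", "cv", outer_repeats = 3)
#' res <- run_scenario(spec, master_seed = 42)
#' tidy(res)
#' @export
run_scenario <- function(spec, master_seed = 1,
                         model = published_coefficients()) {
  if (!inherits(spec, "scenario_spec")) stop_invalid("spec must be a scenario_spec")
  if (spec$skip) {
    stop_state(paste0("scenario ", spec$id,
                      " is marked skipped (missing configuration)"))
  }
  profiles <- spec$profiles %||% dlbcl_stage_profiles()
  outcome <- spec$outcome %||% outcome_config()
  test_profiles <- spec$test_profiles %||% profiles
  test_outcome <- spec$test_outcome %||% outcome
  salt <- id_salt(spec$id)

  one_repeat <- function(r) {
    withr::with_seed(derive_seed(master_seed, r, salt), {
      rows <- switch(
        spec$validator,
        cv = {
          cohort <- simulate_labeled_cohort(spec$n, profiles, model, outcome)
          cross_validate(cohort, k = spec$k, repeats = max(1, spec$cv_repeats))
        },
        holdout = {
          cohort <- simulate_labeled_cohort(spec$n, profiles, model, outcome)
          holdout_validate(cohort, holdout_fraction = spec$holdout_fraction,
                           k = spec$k, cv_repeats = spec$cv_repeats)$holdout
        },
        bootstrap = {
          cohort <- simulate_labeled_cohort(spec$n, profiles, model, outcome)
          bootstrap_validate(cohort, n_boot = spec$n_boot)
        },
        external = {
          train <- simulate_labeled_cohort(spec$n, profiles, model, outcome)
          test <- simulate_labeled_cohort(spec$test_n, test_profiles, model,
                                          test_outcome, earl2 = spec$earl2)
          external_validate(train, test, k = spec$k,
                            cv_repeats = spec$cv_repeats)$external
        }
      )
      mutate(rows, repeat_id = r, .before = 1)
    })
  }

  results <- purrr::map_dfr(seq_len(spec$outer_repeats), function(r) {
    tryCatch(one_repeat(r), error = function(e) {
      tibble(repeat_id = r, n_test = NA_integer_, n_events = NA_integer_,
             auc = NA_real_, calibration_slope = NA_real_,
             error = conditionMessage(e))
    })
  })
  ok <- is.finite(results$auc)
  if (!any(ok)) stop_degenerate(paste0("all repeats of ", spec$id, " failed"))
  n_failed <- sum(!is.na(results$error))
  if (n_failed > 0) {
    message(sprintf("scenario %s: %d record(s) carried failures", spec$id,
                    n_failed))
  }
  structure(
    list(id = spec$id, spec = spec, results = results,
         auc = summarize_metric(results$auc),
         calibration_slope = summarize_metric(results$calibration_slope),
         n_failed = n_failed),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s> %d records (%d failed)\n",
              x$id, nrow(x$results), x$n_failed))
  cat(sprintf("  AUC   %.3f +/- %.3f (%.3f-%.3f)\n", x$auc$mean, x$auc$sd,
              x$auc$ci_low, x$auc$ci_high))
  s <- x$calibration_slope
  cat(sprintf("  slope %.3f +/- %.3f (%.3f-%.3f)\n", s$mean, s$sd,
              s$ci_low, s$ci_high))
  invisible(x)
}

#' @rdname run_scenario
#' @param x,object A `scenario_result`.
#' @param ... Unused.
#' @export
tidy.scenario_result <- function(x, ...) {
  bind_rows(
    mutate(x$auc, metric = "auc", .before = 1),
    mutate(x$calibration_slope, metric = "calibration_slope", .before = 1)
  )
}

#' @rdname run_scenario
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(
    id = x$id, paper_label = x$spec$paper_label, validator = x$spec$validator,
    outer_repeats = x$spec$outer_repeats, n_records = nrow(x$results),
    mean_auc = x$auc$mean, sd_auc = x$auc$sd,
    auc_ci_low = x$auc$ci_low, auc_ci_high = x$auc$ci_high,
    mean_slope = x$calibration_slope$mean, sd_slope = x$calibration_slope$sd,
    slope_ci_low = x$calibration_slope$ci_low,
    slope_ci_high = x$calibration_slope$ci_high,
    n_failed = x$n_failed, skipped = FALSE
  )
}

skipped_row <- function(spec) {
  tibble(
    id = spec$id, paper_label = spec$paper_label, validator = spec$validator,
    outer_repeats = spec$outer_repeats, n_records = 0L,
    mean_auc = NA_real_, sd_auc = NA_real_,
    auc_ci_low = NA_real_, auc_ci_high = NA_real_,
    mean_slope = NA_real_, sd_slope = NA_real_,
    slope_ci_low = NA_real_, slope_ci_high = NA_real_,
    n_failed = 0L, skipped = TRUE
  )
}

#' Run a battery of scenarios
#'
#' Runs every (non-skipped) scenario in a list under one master seed and
#' assembles a summary table in the layout of the study's results table.
#' Optionally writes `summary.csv` plus one `folds_<id>.csv` of evaluation
#' records per scenario to `out_dir`.
#'
#' @param scenarios Named list of [scenario_spec()]s; defaults to
#'   [default_scenarios()].
#' @param master_seed Integer master seed.
#' @param model Risk model generating `true_p`.
#' @param out_dir Optional output directory for CSV export.
#' @return An object of class `scenario_battery`: list with `results`
#'   (scenario_result objects) and `summary` (one row per scenario;
#'   skipped scenarios appear with `skipped = TRUE` and NA metrics).
#' @examples
#' \donttest{
#' battery <- run_all(default_scenarios(outer_repeats = 2), master_seed = 1)
#' battery$summary
#' }
#' @export
run_all <- function(scenarios = default_scenarios(), master_seed = 1,
                    model = published_coefficients(), out_dir = NULL) {
  results <- list()
  summary_rows <- list()
  for (spec in scenarios) {
    if (spec$skip) {
      message(sprintf("scenario %s skipped (no configuration supplied)", spec$id))
      summary_rows[[spec$id]] <- skipped_row(spec)
      next
    }
    res <- run_scenario(spec, master_seed = master_seed, model = model)
    results[[spec$id]] <- res
    summary_rows[[spec$id]] <- glance(res)
  }
  summary <- bind_rows(summary_rows)
  out <- structure(list(results = results, summary = summary,
                        master_seed = master_seed),
                   class = "scenario_battery")
  if (!is.null(out_dir)) write_battery(out, out_dir)
  out
}

#' @export
print.scenario_battery <- function(x, ...) {
  cat(sprintf("<scenario_battery> %d scenarios, master seed %s\n",
              nrow(x$summary), format(x$master_seed)))
  print(x$summary)
  invisible(x)
}

#' Large-sample expected AUC of the generating mechanism
#'
#' Simulates one large cohort and computes the ROC AUC of the true risk
#' probabilities against the noisy outcome labels: the discrimination
#' ceiling that the label-noise mechanism leaves to any model. With no
#' label noise this is exactly 1 (labels are a threshold of the scores);
#' with 50%/50% relabeling the labels carry no signal and the AUC is 0.5.
#'
#' @inheritParams simulate_labeled_cohort
#' @param n_large Cohort size (>= 1e4 recommended; default 1e5).
#' @return The AUC as a single number.
#' @examples
#' expected_auc_oracle(n_large = 2e4, seed = 1)
#' @export
expected_auc_oracle <- function(profiles = dlbcl_stage_profiles(),
                                model = published_coefficients(),
                                config = outcome_config(),
                                n_large = 1e5, seed = NULL) {
  cohort <- simulate_labeled_cohort(n_large, profiles, model, config,
                                    seed = seed)
  roc_auc(cohort$true_p, cohort$outcome)
}
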