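cohort_csv_cols <- function() {
  readr::cols(
    patient_id = readr::col_integer(),
    stage = readr::col_integer(),
    log_suvpeak = readr::col_double(),
    log_mtv = readr::col_double(),
    log_dmax = readr::col_double(),
    age_gt60 = readr::col_integer(),
    who_gt1 = readr::col_integer(),
    true_p = readr::col_double(),
    outcome = readr::col_integer()
  )
}

#' Read and write cohorts as CSV
#'
#' Cohorts round-trip through plain CSV with the canonical column set
#' `patient_id, stage, log_suvpeak, log_mtv, log_dmax, age_gt60, who_gt1,
#' true_p, outcome` (the last two optional).
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- cohort_csv_cols()
  first <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec$cols <- spec$cols[intersect(names(spec$cols), first)]
  readr::read_csv(path, col_types = spec, show_col_types = FALSE)
}

#' Read a run configuration file
#'
#' Parses a YAML or JSON configuration describing a simulation run. All
#' sections are optional; missing ones fall back to the package defaults.
#' Recognized top-level keys:
#' \describe{
#'   \item{profiles}{list of per-stage records with the columns of
#'     [dlbcl_stage_profiles()]}
#'   \item{coefficients}{named logistic coefficients
#'     (`intercept`, `log_mtv`, `log_suvpeak`, `log_dmax`, `age_gt60`,
#'     `who_gt1`)}
#'   \item{outcome}{`cutoff`, `fpr`, `fnr`}
#'   \item{earl2}{offsets/scales accepted by [earl2_transform()]}
#'   \item{outer_repeats, master_seed}{run controls}
#'   \item{scenarios}{character vector of scenario ids to keep from
#'     [default_scenarios()]}
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `profiles`, `model`, `outcome`, `earl2`,
#'   `outer_repeats`, `master_seed` and `scenarios` (the assembled
#'   [scenario_spec()] list).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  profiles <- if (!is.null(raw$profiles)) {
    validate_profiles(bind_rows(lapply(raw$profiles, as_tibble)))
  } else {
    dlbcl_stage_profiles()
  }
  model <- if (!is.null(raw$coefficients)) {
    beta <- unlist(raw$coefficients)
    names(beta)[names(beta) == "intercept"] <- "(Intercept)"
    new_risk_model(beta, source = "config")
  } else {
    published_coefficients()
  }
  outcome <- if (!is.null(raw$outcome)) {
    do.call(outcome_config, raw$outcome)
  } else {
    outcome_config()
  }
  earl2 <- if (!is.null(raw$earl2)) do.call(earl2_transform, raw$earl2) else NULL
  outer_repeats <- raw$outer_repeats %||% 100
  master_seed <- raw$master_seed %||% 1
  scenarios <- default_scenarios(outer_repeats = outer_repeats, earl2 = earl2)
  if (!is.null(raw$scenarios)) {
    unknown <- setdiff(raw$scenarios, names(scenarios))
    if (length(unknown) > 0) {
      stop_invalid(paste0("unknown scenario id(s): ",
                          paste(unknown, collapse = ", ")))
    }
    scenarios <- scenarios[raw$scenarios]
  }
  list(profiles = profiles, model = model, outcome = outcome, earl2 = earl2,
       outer_repeats = outer_repeats, master_seed = master_seed,
       scenarios = scenarios)
}

#' Write a scenario battery to CSV files
#'
#' Writes `summary.csv` (one row per scenario) and `folds_<id>.csv` (one
#' row per evaluation record) into `out_dir`, creating it if needed.
#'
#' @param battery A `scenario_battery` from [run_all()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_battery <- function(battery, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(battery$summary, file.path(out_dir, "summary.csv"))
  for (res in battery$results) {
    readr::write_csv(res$results,
                     file.path(out_dir, paste0("folds_", res$id, ".csv")))
  }
  invisible(out_dir)
}
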