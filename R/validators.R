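#' Stage-stratified fold assignment
#'
#' Partitions a cohort into `k` folds, stratified by Ann Arbor stage: the
#' patients of each stage are randomly permuted and dealt round-robin into
#' the folds, so per-stage counts across folds differ by at most one.
#'
#' @param cohort Cohort tibble with a `stage` column.
#' @param k Number of folds (>= 2, <= number of patients).
#' @param seed Optional integer seed.
#' @return Integer vector of fold labels in `1:k`, one per patient.
#' @examples
#' cohort <- simulate_cohort(500, seed = 1)
#' table(stratified_folds(cohort, 5, seed = 2), cohort$stage)
#' @export
stratified_folds <- function(cohort, k, seed = NULL) {
  n <- nrow(cohort)
  if (length(k) != 1 || !is.finite(k) || k < 2 || k != floor(k)) {
    stop_invalid("k must be a single integer >= 2")
  }
  if (k > n) stop_invalid("k must not exceed the number of patients")
  stages <- sort(unique(cohort$stage))
  small <- stages[tabulate(factor(cohort$stage, levels = stages)) < k]
  if (length(small) > 0) {
    warn(paste0("stage(s) ", paste(small, collapse = ", "),
                " have fewer than k patients; folds will be uneven"))
  }
  with_seed_if(seed, {
    fold <- integer(n)
    dealt <- 0L
    for (s in stages) {
      idx <- permute(which(cohort$stage == s))
      # continue the round-robin counter across stages so overall fold
      # sizes stay even and k = n yields a leave-one-out partition
      fold[idx] <- as.integer(((seq_along(idx) + dealt - 1L) %% k) + 1L)
      dealt <- dealt + length(idx)
    }
    fold
  })
}

#' Stage-stratified train/holdout split
#'
#' Splits a cohort into a training part and a holdout part of (rounded)
#' fraction `holdout_fraction`, allocating the holdout across stages by
#' largest-remainder apportionment so its stage mix matches the cohort's
#' within rounding.
#'
#' @param cohort Cohort tibble with a `stage` column.
#' @param holdout_fraction Fraction in (0, 1) reserved for the holdout.
#' @param seed Optional integer seed.
#' @return A list with tibbles `train` and `holdout`.
#' @export
stratified_split <- function(cohort, holdout_fraction, seed = NULL) {
  if (!is.finite(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1) {
    stop_invalid("holdout_fraction must lie strictly in (0, 1)")
  }
  n <- nrow(cohort)
  stages <- sort(unique(cohort$stage))
  sizes <- vapply(stages, function(s) sum(cohort$stage == s), integer(1))
  target <- as.integer(round(holdout_fraction * n))
  if (target < 1 || target >= n) {
    stop_invalid("holdout_fraction leaves an empty train or holdout part")
  }
  counts <- largest_remainder(sizes, target, tie_order = stages)
  with_seed_if(seed, {
    hold_idx <- unlist(purrr::map(seq_along(stages), function(i) {
      draw(which(cohort$stage == stages[i]), counts[i])
    }))
    list(train = cohort[-hold_idx, ], holdout = cohort[hold_idx, ])
  })
}

# Evaluate a fitted (or fixed) risk model on a test set; never throws --
# undefined metrics become NA with the failure recorded in `error`.
evaluate_model <- function(model, test) {
  n_test <- nrow(test)
  n_events <- sum(test$outcome)
  auc <- NA_real_
  slope <- NA_real_
  msgs <- character(0)
  lp <- linear_predictor(model, test)
  tryCatch(
    auc <- roc_auc(plogis(lp), test$outcome),
    error = function(e) msgs <<- c(msgs, paste0("auc: ", conditionMessage(e)))
  )
  tryCatch(
    slope <- calibration_slope(lp, test$outcome),
    error = function(e) msgs <<- c(msgs, paste0("slope: ", conditionMessage(e)))
  )
  tibble(
    n_test = n_test, n_events = n_events, auc = auc,
    calibration_slope = slope,
    error = if (length(msgs)) paste(msgs, collapse = "; ") else NA_character_
  )
}

fold_failure_row <- function(n_test, n_events, msg) {
  tibble(n_test = n_test, n_events = n_events, auc = NA_real_,
         calibration_slope = NA_real_, error = msg)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, draws a fresh stage-stratified partition; for each
#' fold, refits the fixed-form logistic model on the other `k - 1` folds
#' and evaluates ROC AUC (of predicted probabilities) and calibration
#' slope (of the training model's linear predictor) on the held-out fold.
#' Folds whose fit or metrics are undefined are recorded with a failure
#' message, not dropped silently.
#'
#' @param cohort Labeled cohort tibble.
#' @param k Number of folds (default 5).
#' @param repeats Number of independent reshuffles (default 1).
#' @param seed Optional integer seed.
#' @return A tibble of fold results with columns `cv_repeat`, `fold_id`,
#'   `n_test`, `n_events`, `auc`, `calibration_slope`, `error`.
#' @examples
#' cohort <- simulate_labeled_cohort(500, seed = 1)
#' folds <- cross_validate(cohort, k = 5, repeats = 2, seed = 2)
#' summarize_metric(folds$auc)
#' @export
cross_validate <- function(cohort, k = 5, repeats = 1, seed = NULL) {
  if (!"outcome" %in% names(cohort)) stop_state("cohort must carry outcomes")
  if (repeats < 1) stop_invalid("repeats must be >= 1")
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- stratified_folds(cohort, k)
      purrr::map_dfr(seq_len(k), function(f) {
        test <- cohort[fold == f, ]
        train <- cohort[fold != f, ]
        row <- tryCatch({
          fit <- fit_logistic(train)
          evaluate_model(fit, test)
        }, error = function(e) {
          fold_failure_row(nrow(test), sum(test$outcome),
                           paste0("fit: ", conditionMessage(e)))
        })
        mutate(row, cv_repeat = r, fold_id = f, .before = 1)
      })
    })
  })
}

#' Holdout validation with cross-validated training
#'
#' Stage-stratified split into a training part and a holdout of fraction
#' `holdout_fraction`; runs [cross_validate()] on the training part (for
#' reporting, skipped when `cv_repeats = 0`), then refits the model on the
#' entire training part and evaluates it once on the holdout.
#'
#' @inheritParams cross_validate
#' @param holdout_fraction Fraction held out (default 0.2).
#' @param cv_repeats CV repeats on the training part (default 1; 0 skips).
#' @return A list with `cv` (fold-result tibble, possibly empty) and
#'   `holdout` (one-row evaluation tibble).
#' @examples
#' cohort <- simulate_labeled_cohort(500, seed = 1)
#' holdout_validate(cohort, seed = 2)$holdout
#' @export
holdout_validate <- function(cohort, holdout_fraction = 0.2, k = 5,
                             cv_repeats = 1, seed = NULL) {
  if (!"outcome" %in% names(cohort)) stop_state("cohort must carry outcomes")
  with_seed_if(seed, {
    parts <- stratified_split(cohort, holdout_fraction)
    cv <- if (cv_repeats > 0) {
      cross_validate(parts$train, k = k, repeats = cv_repeats)
    } else {
      tibble()
    }
    holdout <- tryCatch({
      fit <- fit_logistic(parts$train)
      evaluate_model(fit, parts$holdout)
    }, error = function(e) {
      fold_failure_row(nrow(parts$holdout), sum(parts$holdout$outcome),
                       paste0("fit: ", conditionMessage(e)))
    })
    list(cv = cv, holdout = holdout)
  })
}

#' Harrell's optimism-corrected bootstrap validation
#'
#' Fits the model on the full cohort (apparent performance), then on each
#' of `n_boot` bootstrap resamples; the optimism of each resample is its
#' apparent performance minus the performance of the resample's model on
#' the original cohort. The corrected estimate subtracts the mean optimism
#' from the apparent value. The apparent calibration slope is 1 by
#' construction (the slope of an ML fit on its own training data), so the
#' corrected slope is `1 - mean slope optimism`. Resamples with a
#' single-class outcome or a failed fit are redrawn, with a logged count.
#'
#' @inheritParams cross_validate
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param sampler Resampling function `function(n)` returning `n` row
#'   indices; defaults to sampling with replacement. Injectable so that
#'   degenerate-resampling behavior is testable.
#' @return A one-row tibble with apparent, optimism and corrected AUC and
#'   calibration slope, plus `n_boot` and `n_redrawn`.
#' @examples
#' cohort <- simulate_labeled_cohort(500, seed = 1)
#' bootstrap_validate(cohort, n_boot = 20, seed = 2)
#' @export
bootstrap_validate <- function(cohort, n_boot = 500, seed = NULL,
                               sampler = NULL) {
  if (!"outcome" %in% names(cohort)) stop_state("cohort must carry outcomes")
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  if (is.null(sampler)) {
    sampler <- function(n) sample.int(n, n, replace = TRUE)
  }
  n <- nrow(cohort)
  with_seed_if(seed, {
    apparent_fit <- fit_logistic(cohort)
    apparent <- evaluate_model(apparent_fit, cohort)
    opt_auc <- numeric(n_boot)
    opt_slope <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        boot <- cohort[sampler(n), ]
        res <- tryCatch({
          fit_b <- fit_logistic(boot)
          list(boot_eval = evaluate_model(fit_b, boot),
               orig_eval = evaluate_model(fit_b, cohort))
        }, error = function(e) NULL)
        ok <- !is.null(res) &&
          all(is.finite(c(res$boot_eval$auc, res$boot_eval$calibration_slope,
                          res$orig_eval$auc, res$orig_eval$calibration_slope)))
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10L * n_boot) {
          stop_degenerate("too many degenerate bootstrap resamples")
        }
      }
      opt_auc[b] <- res$boot_eval$auc - res$orig_eval$auc
      opt_slope[b] <- res$boot_eval$calibration_slope -
        res$orig_eval$calibration_slope
    }
    tibble(
      n_test = n, n_events = sum(cohort$outcome),
      apparent_auc = apparent$auc,
      optimism_auc = mean(opt_auc),
      auc = apparent$auc - mean(opt_auc),
      apparent_slope = apparent$calibration_slope,
      optimism_slope = mean(opt_slope),
      calibration_slope = apparent$calibration_slope - mean(opt_slope),
      n_boot = n_boot, n_redrawn = n_redrawn,
      error = NA_character_
    )
  })
}

#' Train/external-test validation
#'
#' Optionally cross-validates on the training cohort (reporting only),
#' then refits the model on the full training cohort and evaluates ROC AUC
#' and calibration slope on an independently generated external cohort.
#'
#' @inheritParams cross_validate
#' @param train_cohort,test_cohort Labeled cohort tibbles.
#' @param cv_repeats CV repeats on the training cohort (default 0 = skip).
#' @return A list with `cv` (fold-result tibble), `external` (one-row
#'   evaluation tibble) and `model` (the refit `risk_model`).
#' @examples
#' train <- simulate_labeled_cohort(400, seed = 1)
#' test <- simulate_labeled_cohort(500, seed = 2)
#' external_validate(train, test)$external
#' @export
external_validate <- function(train_cohort, test_cohort, k = 5,
                              cv_repeats = 0, seed = NULL) {
  if (!"outcome" %in% names(train_cohort) ||
      !"outcome" %in% names(test_cohort)) {
    stop_state("both cohorts must carry outcomes")
  }
  with_seed_if(seed, {
    cv <- if (cv_repeats > 0) {
      cross_validate(train_cohort, k = k, repeats = cv_repeats)
    } else {
      tibble()
    }
    model <- NULL
    external <- tryCatch({
      model <- fit_logistic(train_cohort)
      evaluate_model(model, test_cohort)
    }, error = function(e) {
      fold_failure_row(nrow(test_cohort), sum(test_cohort$outcome),
                       paste0("fit: ", conditionMessage(e)))
    })
    list(cv = cv, external = external, model = model)
  })
}
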