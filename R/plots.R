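#' Plot per-repeat AUCs of a scenario
#'
#' Scatter of the evaluation-record AUCs of one scenario (one point per
#' fold x repeat for cross-validation, one per repeat otherwise), with an
#' optional horizontal reference line at the expected AUC of the
#' generating mechanism (see [expected_auc_oracle()]).
#'
#' @param object A `scenario_result` from [run_scenario()].
#' @param reference Optional reference AUC drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' res <- run_scenario(scenario_spec("cv", "cv", outer_repeats = 3), 1)
#' autoplot(res, reference = expected_auc_oracle(n_large = 2e4, seed = 1))
#' @export
autoplot.scenario_result <- function(object, reference = NULL, ...) {
  dat <- filter(object$results, is.finite(.data$auc))
  p <- ggplot(dat, aes(x = .data$repeat_id, y = .data$auc)) +
    geom_point(colour = "steelblue", alpha = 0.8) +
    geom_hline(yintercept = object$auc$mean, colour = "steelblue") +
    labs(
      x = "repeat", y = "AUC",
      title = paste0("Scenario ", object$id),
      subtitle = sprintf("mean AUC %.3f ± %.3f", object$auc$mean,
                         object$auc$sd)
    ) +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_hline(yintercept = reference, linetype = "dashed")
  }
  p
}

#' Summary plot of a scenario battery
#'
#' Point-range display (mean and 95% interval) of the AUC or calibration
#' slope of every scenario in a battery.
#'
#' @param battery A `scenario_battery` from [run_all()].
#' @param metric `"auc"` or `"calibration_slope"`.
#' @return A ggplot object.
#' @export
plot_battery_summary <- function(battery, metric = c("auc", "calibration_slope")) {
  metric <- match.arg(metric)
  dat <- filter(battery$summary, !.data$skipped)
  if (metric == "auc") {
    dat <- mutate(dat, mid = .data$mean_auc, lo = .data$auc_ci_low,
                  hi = .data$auc_ci_high)
    ref <- 0.5
    lab <- "AUC (mean, 95% interval)"
  } else {
    dat <- mutate(dat, mid = .data$mean_slope, lo = .data$slope_ci_low,
                  hi = .data$slope_ci_high)
    ref <- 1
    lab <- "calibration slope (mean, 95% interval)"
  }
  dat$id <- factor(dat$id, levels = rev(dat$id))
  ggplot(dat, aes(x = .data$mid, y = .data$id)) +
    geom_vline(xintercept = ref, linetype = "dashed", colour = "grey50") +
    geom_pointrange(aes(xmin = .data$lo, xmax = .data$hi),
                    colour = "steelblue") +
    labs(x = lab, y = NULL) +
    theme_minimal()
}
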