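check_binary_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop_invalid("scores and labels must have equal length")
  }
  if (length(labels) == 0) stop_invalid("empty input")
  if (anyNA(labels) || anyNA(scores)) stop_invalid("missing values not allowed")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop_undefined("both outcome classes must be present")
  }
  invisible(TRUE)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Rank-based AUC: over all (event, non-event) pairs, the fraction of
#' concordant pairs plus half the tied fraction, computed in O(n log n)
#' with average ranks. Equivalent to the exhaustive pairwise count.
#'
#' @param scores Numeric risk scores (higher = more event-like).
#' @param labels Binary 0/1 outcome vector of the same length.
#' @return AUC in \[0, 1\].
#' @section Errors: single-class labels raise an undefined-metric error.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels) {
  check_binary_labels(labels, scores)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope of a linear predictor on test data
#'
#' The slope `b` from the maximum-likelihood logistic refit
#' `outcome ~ a + b * lp` of the test outcomes on a model's linear
#' predictor. A slope of 1 indicates perfect calibration of the
#' coefficient spread; below 1, predictions are too extreme (overfitting);
#' above 1, predictions are too compressed.
#'
#' @param lp Numeric linear-predictor vector (must not be constant).
#' @param labels Binary 0/1 outcome vector.
#' @return The slope as a single number.
#' @section Errors: constant `lp` or single-class labels raise an
#'   undefined-metric error.
#' @examples
#' lp <- rnorm(200)
#' y <- rbinom(200, 1, plogis(lp))
#' calibration_slope(lp, y)
#' @export
calibration_slope <- function(lp, labels) {
  check_binary_labels(labels, lp)
  if (diff(range(lp)) == 0) {
    stop_undefined("linear predictor is constant; calibration slope undefined")
  }
  fit <- suppressWarnings(
    glm(labels ~ lp, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100))
  )
  unname(coef(fit)[2L])
}

#' Summarize a metric over folds or repeats
#'
#' Mean, sample SD and a 95% interval of a vector of fold- or repeat-level
#' metric values. The interval is by default the empirical 2.5th/97.5th
#' percentile of the values (which accommodates the asymmetric spread seen
#' in cross-validated AUCs); a normal-approximation interval
#' `mean +/- 1.96 * sd` is available as an alternative. Non-finite values
#' (failed folds) are dropped and counted.
#'
#' @param values Numeric vector with at least one finite value.
#' @param ci `"percentile"` (default) or `"normal"`.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `n_dropped`. With a single value, `sd` and the interval are
#'   `NA` (flagged unavailable).
#' @examples
#' summarize_metric(c(0.6, 0.7, 0.8))
#' @export
summarize_metric <- function(values, ci = c("percentile", "normal")) {
  ci <- match.arg(ci)
  if (length(values) == 0) stop_invalid("empty input")
  keep <- is.finite(values)
  values <- values[keep]
  if (length(values) == 0) stop_invalid("no finite values to summarize")
  m <- mean(values)
  if (length(values) == 1) {
    return(tibble(n = 1L, mean = m, sd = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  n_dropped = sum(!keep)))
  }
  s <- sd(values)
  if (ci == "percentile") {
    q <- quantile(values, c(0.025, 0.975), names = FALSE)
  } else {
    q <- m + c(-1, 1) * qnorm(0.975) * s
  }
  tibble(n = length(values), mean = m, sd = s,
         ci_low = q[1], ci_high = q[2], n_dropped = sum(!keep))
}
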