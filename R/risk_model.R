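risk_covariates <- c("log_mtv", "log_suvpeak", "log_dmax", "age_gt60", "who_gt1")
risk_terms <- c("(Intercept)", risk_covariates)

# glm's IRLS stops on relative deviance change; a few Newton steps push the
# score equations themselves to ~0 (max |t(X)(y - p)| < 1e-8)
newton_polish <- function(beta, x, y, tol = 1e-8, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(x %*% beta))
    score <- drop(crossprod(x, y - p))
    if (max(abs(score)) < tol) break
    w <- p * (1 - p)
    step <- tryCatch(solve(crossprod(x, x * w), score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
  }
  beta
}

new_risk_model <- function(coefficients, source, n = NA_integer_,
                           n_events = NA_integer_, deviance = NA_real_,
                           converged = TRUE, std_error = NULL) {
  coefficients <- coefficients[risk_terms]
  if (anyNA(coefficients) || any(!is.finite(coefficients))) {
    stop_invalid("risk model coefficients must be finite and complete")
  }
  structure(
    list(coefficients = coefficients, source = source, n = n,
         n_events = n_events, deviance = deviance, converged = converged,
         std_error = std_error),
    class = "risk_model"
  )
}

#' The published DLBCL logistic risk model
#'
#' Returns the fixed, previously published logistic regression model for
#' two-year progression, with risk
#' \deqn{p = 1 / (1 + e^{-LP}),\quad
#'   LP = -6.532 + 0.533\,\log MTV - 1.395\,\log SUV_{peak}
#'        + 0.257\,\log D_{max} + 0.773\,\mathrm{IPIage} + 0.787\,\mathrm{WHO}.}
#' The linear predictor enters the logistic map with a positive sign, so
#' risk increases with tumor volume and dissemination; under the opposite
#' reading risk would fall with tumor burden and nearly the whole
#' population would exceed the 0.375 high-risk cutoff, both untenable.
#'
#' @return A `risk_model` object with `source = "published"`.
#' @examples
#' published_coefficients()
#' @export
published_coefficients <- function() {
  new_risk_model(
    c("(Intercept)" = -6.532, log_mtv = 0.533, log_suvpeak = -1.395,
      log_dmax = 0.257, age_gt60 = 0.773, who_gt1 = 0.787),
    source = "published"
  )
}

as_risk_coefficients <- function(model) {
  if (inherits(model, "risk_model")) return(model$coefficients)
  if (is.numeric(model) && all(risk_terms %in% names(model))) {
    return(model[risk_terms])
  }
  stop_invalid("model must be a risk_model or a named coefficient vector")
}

risk_design <- function(cohort) {
  missing_cols <- setdiff(risk_covariates, names(cohort))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0("cohort is missing covariate(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- cbind(1, as.matrix(as.data.frame(cohort)[, risk_covariates]))
  colnames(x) <- risk_terms
  if (any(!is.finite(x))) stop_invalid("covariates must be finite")
  x
}

#' Linear predictor of a risk model on a cohort
#'
#' @param model A `risk_model` or named coefficient vector.
#' @param cohort Cohort tibble with columns `log_mtv`, `log_suvpeak`,
#'   `log_dmax`, `age_gt60`, `who_gt1`.
#' @return Numeric vector, one linear-predictor value per patient.
#' @examples
#' cohort <- simulate_cohort(10, seed = 1)
#' linear_predictor(published_coefficients(), cohort)
#' @export
linear_predictor <- function(model, cohort) {
  drop(risk_design(cohort) %*% as_risk_coefficients(model))
}

#' Predicted risk probabilities of a risk model on a cohort
#'
#' Applies the logistic map elementwise to [linear_predictor()]; values are
#' strictly inside (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric probability vector.
#' @export
predict_probability <- function(model, cohort) {
  plogis(linear_predictor(model, cohort))
}

#' Refit the fixed-form logistic risk model by maximum likelihood
#'
#' Fits `outcome ~ log_mtv + log_suvpeak + log_dmax + age_gt60 + who_gt1`
#' by iteratively reweighted least squares (via [stats::glm()]) with no
#' shrinkage, matching the study design of measuring the overfitting of
#' plain ML coefficients. The covariate set is fixed; no selection occurs.
#'
#' @param cohort Labeled cohort tibble (must contain `outcome` with both
#'   classes present).
#' @return A `risk_model` with `source = "refit"`, carrying standard
#'   errors, deviance and event counts.
#' @section Errors: a single-class outcome raises a degenerate-data error;
#'   detected quasi-separation or IRLS non-convergence raises a flagged
#'   non-convergence error (callers such as [cross_validate()] record these
#'   as per-fold failures rather than aborting a whole run).
#' @examples
#' cohort <- simulate_labeled_cohort(400, seed = 7)
#' fit <- fit_logistic(cohort)
#' tidy(fit)
#' @export
fit_logistic <- function(cohort) {
  if (!"outcome" %in% names(cohort) || anyNA(cohort$outcome)) {
    stop_state("cohort must carry a complete outcome column")
  }
  y <- cohort$outcome
  if (length(unique(y)) < 2) {
    stop_degenerate("outcome has a single class; logistic fit undefined")
  }
  x <- risk_design(cohort)
  if (nrow(x) <= ncol(x)) {
    stop_invalid("need more patients than model parameters to refit")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x - 1, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separation) {
    stop_nonconvergence("perfect or quasi-separation detected; coefficients diverge")
  }
  if (!fit$converged) {
    stop_nonconvergence("IRLS did not converge within 100 iterations")
  }
  est <- newton_polish(coef(fit), x, y)
  se <- sqrt(diag(vcov(fit)))
  names(est) <- names(se) <- risk_terms
  new_risk_model(est, source = "refit", n = length(y),
                 n_events = sum(y), deviance = fit$deviance,
                 converged = TRUE, std_error = se)
}

#' Deviance of a fixed risk model on a labeled cohort
#'
#' Minus twice the Bernoulli log-likelihood of the cohort outcomes under
#' the model's predicted probabilities; useful for comparing a refit
#' against the published coefficients.
#'
#' @inheritParams linear_predictor
#' @return A single number.
#' @export
model_deviance <- function(model, cohort) {
  if (!"outcome" %in% names(cohort)) stop_state("cohort must carry outcomes")
  p <- predict_probability(model, cohort)
  -2 * sum(dbinom(cohort$outcome, 1, p, log = TRUE))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %s>\n", x$source))
  print(round(x$coefficients, 4))
  if (!is.na(x$n)) {
    cat(sprintf("n = %d, events = %d, deviance = %.2f\n",
                x$n, x$n_events, x$deviance))
  }
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `risk_model`.
#' @param ... Unused.
#' @export
tidy.risk_model <- function(x, ...) {
  out <- tibble(term = names(x$coefficients),
                estimate = unname(x$coefficients))
  if (!is.null(x$std_error)) out$std.error <- unname(x$std_error)
  out
}

#' @rdname fit_logistic
#' @export
glance.risk_model <- function(x, ...) {
  tibble(source = x$source, n = x$n, n_events = x$n_events,
         deviance = x$deviance, converged = x$converged)
}

#' Serialize risk-model coefficients to and from JSON
#'
#' Coefficients are written as a named JSON object at full precision.
#'
#' @param model A `risk_model` or named coefficient vector.
#' @param path File path.
#' @return `write_coefficients()` returns `path` invisibly;
#'   `read_coefficients()` returns a `risk_model` with `source = "file"`.
#' @export
write_coefficients <- function(model, path) {
  beta <- as_risk_coefficients(model)
  jsonlite::write_json(as.list(beta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  raw <- jsonlite::read_json(path)
  beta <- vapply(raw, as.numeric, numeric(1))
  new_risk_model(beta, source = "file")
}
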