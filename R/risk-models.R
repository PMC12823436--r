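#' Logistic outcome model with odds ratios per 1 SD
#'
#' Fits a binomial logistic regression of a binary outcome on one or more
#' predictors plus covariates (default age and sex). Predictors are
#' standardized to unit SD on the listwise-complete analysis sample before
#' fitting, so odds ratios are per 1-SD increase; covariates enter on their
#' original scale. Wald 95% confidence intervals use z = 1.96. Separation is
#' reported as an error (a standardized coefficient beyond 15 cannot be a
#' finite maximum-likelihood estimate in practice).
#'
#' @param data data frame.
#' @param outcome binary outcome column (0/1; both classes required).
#' @param predictors character vector of predictor columns.
#' @param covariates covariate columns, default `c("age", "sex")`.
#' @return A list of class `outcome_model_result` with `estimates` (tibble:
#'   `term`, `log_or`, `se`, `or`, `ci_low`, `ci_high`, `p`), `deviance`,
#'   `null_deviance`, `n_used`, `outcome`, `predictors`, `covariates`,
#'   and the fitted coefficients.
#' @export
fit_outcome_model <- function(data, outcome, predictors,
                              covariates = c("age", "sex")) {
  cols <- c(outcome, predictors, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[cols]
  ok <- complete.cases(d)
  d <- d[ok, , drop = FALSE]
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1))) abort("outcome must be coded 0/1")
  if (length(unique(y)) < 2) abort("outcome has a single class")

  keep_cov <- covariates[vapply(covariates, function(v) sd(d[[v]]) > 0, logical(1))]
  dropped <- setdiff(covariates, keep_cov)
  sds <- vapply(predictors, function(v) sd(d[[v]]), numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("constant predictor(s): %s",
                  paste(predictors[sds == 0], collapse = ", ")))
  }
  for (v in predictors) d[[v]] <- d[[v]] / sd(d[[v]])

  X <- as.data.frame(d[c(predictors, keep_cov)])
  rhs <- paste(c(predictors, keep_cov), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  fit <- suppressWarnings(
    glm(fml, data = cbind(y = y, X), family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (anyNA(coef(fit))) {
    abort(sprintf("collinear term(s) aliased in fit: %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  cf <- summary(fit)$coefficients
  pred_coef <- cf[predictors, , drop = FALSE]
  if (any(abs(pred_coef[, "Estimate"]) > 15)) {
    sep <- predictors[abs(pred_coef[, "Estimate"]) > 15]
    abort(sprintf("separation detected for predictor(s): %s",
                  paste(sep, collapse = ", ")))
  }
  est <- tibble::tibble(
    term = rownames(pred_coef),
    log_or = pred_coef[, "Estimate"],
    se = pred_coef[, "Std. Error"],
    or = exp(pred_coef[, "Estimate"]),
    ci_low = exp(pred_coef[, "Estimate"] - 1.96 * pred_coef[, "Std. Error"]),
    ci_high = exp(pred_coef[, "Estimate"] + 1.96 * pred_coef[, "Std. Error"]),
    p = pred_coef[, "Pr(>|z|)"]
  )
  structure(list(
    outcome = outcome, predictors = predictors,
    covariates = keep_cov, covariates_dropped = dropped,
    estimates = est,
    coefficients = coef(fit),
    deviance = deviance(fit),
    null_deviance = fit$null.deviance,
    n_used = length(y),
    case_index = which(ok)
  ), class = "outcome_model_result")
}

#' @export
print.outcome_model_result <- function(x, ...) {
  cat(sprintf("<outcome_model_result> %s ~ %s (+ %s), n = %d, deviance = %.2f\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              paste(x$covariates, collapse = ", "), x$n_used, x$deviance))
  print(x$estimates)
  invisible(x)
}

#' Likelihood-ratio test between nested outcome models
#'
#' Statistic = deviance(reduced) - deviance(full), referred to a chi-square
#' with degrees of freedom equal to the parameter-count difference. Both
#' models must target the same outcome on the same analysis rows and the
#' reduced predictor set must nest inside the full one.
#'
#' @param full,reduced `outcome_model_result` objects.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$outcome != reduced$outcome) abort("models target different outcomes")
  if (!identical(full$case_index, reduced$case_index)) {
    abort("models were fitted on different samples")
  }
  full_terms <- c(full$predictors, full$covariates)
  red_terms <- c(reduced$predictors, reduced$covariates)
  if (!all(red_terms %in% full_terms)) {
    abort("reduced model terms are not a subset of the full model's")
  }
  df <- length(full_terms) - length(red_terms)
  stat <- reduced$deviance - full$deviance
  if (stat < -1e-8) abort("reduced model fits better than full: models not nested")
  stat <- max(stat, 0)
  if (df == 0 && stat > 1e-8) abort("equal parameter counts but unequal deviance: models not nested")
  tibble::tibble(statistic = stat, df = df,
                 p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Outcome model under extended risk-factor adjustment
#'
#' [fit_outcome_model()] with the traditional cardiometabolic risk-factor
#' covariates appended (lipids, glucose, blood pressure, waist-to-hip ratio
#' and statin use, when present in the data) — used to test whether a
#' predictor's association is independent of conventional risk factors.
#'
#' @inheritParams fit_outcome_model
#' @param extra_covariates extended covariate columns; defaults to the
#'   traditional risk-factor set intersected with `names(data)`.
#' @return An `outcome_model_result`; the covariate set actually used is
#'   recorded verbatim on the result.
#' @export
extended_adjustment <- function(data, outcome, predictors,
                                covariates = c("age", "sex"),
                                extra_covariates = intersect(
                                  c("whr", "hdl", "ldl", "triglycerides",
                                    "sbp", "dbp", "glucose", "statin"),
                                  names(data))) {
  fit_outcome_model(data, outcome, predictors,
                    covariates = unique(c(covariates, extra_covariates)))
}

#' Fit the three outcome model specifications
#'
#' Convenience wrapper fitting the BMI-only, metBMI-only and nested
#' (BMI + metBMI) logistic models for one outcome on the shared
#' listwise-complete sample, plus the likelihood-ratio test of the nested
#' model against the BMI-only model.
#'
#' @param data data frame with `bmi`, `metbmi`, the outcome and covariates.
#' @param outcome binary outcome column.
#' @param covariates covariates, default age and sex.
#' @return List with `bmi_only`, `metbmi_only`, `nested`
#'   (`outcome_model_result`s) and `lrt` (tibble).
#' @export
fit_outcome_model_set <- function(data, outcome, covariates = c("age", "sex")) {
  cols <- c(outcome, "bmi", "metbmi", covariates)
  d <- data[complete.cases(data[cols]), , drop = FALSE]
  bmi_only <- fit_outcome_model(d, outcome, "bmi", covariates)
  metbmi_only <- fit_outcome_model(d, outcome, "metbmi", covariates)
  nested <- fit_outcome_model(d, outcome, c("bmi", "metbmi"), covariates)
  list(bmi_only = bmi_only, metbmi_only = metbmi_only, nested = nested,
       lrt = likelihood_ratio_test(nested, bmi_only))
}
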