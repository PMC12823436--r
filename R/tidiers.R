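# broom-style tidiers for the fitted-object classes

#' @rdname metbmi-tidiers
#' @name metbmi-tidiers
#' @title Tidy and glance methods for metbmi result objects
#' @description One-row-per-component `tidy()` tibbles and one-row `glance()`
#'   summaries, in the broom convention, for every fitted object the package
#'   produces.
#' @param x a fitted object.
#' @param ... unused.
NULL

#' @rdname metbmi-tidiers
#' @method tidy nested_cv_result
#' @export
tidy.nested_cv_result <- function(x, ...) {
  tibble::tibble(target = x$target_name, layer = x$layer_name,
                 penalty_kind = x$penalty_kind,
                 fold = seq_along(x$per_fold_r2),
                 r2 = x$per_fold_r2,
                 penalty = x$chosen_penalty_per_fold)
}

#' @rdname metbmi-tidiers
#' @method glance nested_cv_result
#' @export
glance.nested_cv_result <- function(x, ...) {
  tibble::tibble(target = x$target_name, layer = x$layer_name,
                 penalty_kind = x$penalty_kind,
                 median_r2 = x$median_r2,
                 k_outer = length(x$per_fold_r2),
                 n = nrow(x$fold_assignment), seed = x$seed)
}

#' @rdname metbmi-tidiers
#' @method tidy metbmi_model
#' @export
tidy.metbmi_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)),
                 feature_mean = c(NA_real_, unname(x$feature_means)))
}

#' @rdname metbmi-tidiers
#' @method glance metbmi_model
#' @export
glance.metbmi_model <- function(x, ...) {
  tibble::tibble(penalty_kind = x$penalty_kind,
                 chosen_penalty = x$chosen_penalty,
                 n_features = length(x$coefficients),
                 n_train = length(x$train_ids), n_test = length(x$test_ids),
                 test_r2 = x$test_r2 %||% NA_real_, seed = x$seed)
}

#' @rdname metbmi-tidiers
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total"),
    estimate = c(x$acme, x$ade, x$total_effect),
    ci_low = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1]),
    ci_high = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2]),
    p = c(x$p_acme, x$p_ade, x$p_total))
}

#' @rdname metbmi-tidiers
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(exposure = x$exposure_id, mediator = x$mediator_id,
                 outcome = x$outcome_id, acme = x$acme, ade = x$ade,
                 total_effect = x$total_effect, n_boot = x$n_boot,
                 n_used = x$n_used)
}

#' @rdname metbmi-tidiers
#' @method tidy outcome_model_result
#' @export
tidy.outcome_model_result <- function(x, ...) x$estimates

#' @rdname metbmi-tidiers
#' @method glance outcome_model_result
#' @export
glance.outcome_model_result <- function(x, ...) {
  tibble::tibble(outcome = x$outcome,
                 predictors = paste(x$predictors, collapse = "+"),
                 covariates = paste(x$covariates, collapse = "+"),
                 deviance = x$deviance, null_deviance = x$null_deviance,
                 n_used = x$n_used)
}

#' @rdname metbmi-tidiers
#' @method tidy residual_classification
#' @export
tidy.residual_classification <- function(x, ...) x$samples

#' @rdname metbmi-tidiers
#' @method glance residual_classification
#' @export
glance.residual_classification <- function(x, ...) {
  gs <- as.integer(x$group_sizes)
  names(gs) <- names(x$group_sizes)
  dplyr::bind_cols(tibble::tibble(n = nrow(x$samples),
                                  residual_sd = x$residual_sd),
                   tibble::as_tibble(as.list(gs)))
}

#' @rdname metbmi-tidiers
#' @method tidy panel_selection_result
#' @export
tidy.panel_selection_result <- function(x, ...) x$final_panel

#' @rdname metbmi-tidiers
#' @method glance panel_selection_result
#' @export
glance.panel_selection_result <- function(x, ...) {
  tibble::tibble(rule = x$rule, panel_size = nrow(x$final_panel),
                 panel_r2 = x$panel_r2, full_model_r2 = x$full_model_r2,
                 retention = x$panel_r2 / x$full_model_r2)
}
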