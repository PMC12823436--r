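# ggplot2 autoplot methods for the main result types

#' Plot per-fold hold-out R-squared for one nested-CV result
#'
#' @param object a [nested_cv_r2()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot nested_cv_result
#' @export
autoplot.nested_cv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$layer, y = .data$r2)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(y = "hold-out R² (per outer fold)", x = NULL,
                  title = sprintf("%s ~ %s (%s)", object$target_name,
                                  object$layer_name, object$penalty_kind)) +
    ggplot2::theme_minimal()
}

#' Compare per-fold performance across layers
#'
#' Boxplots of per-fold hold-out R^2 per layer, annotated with the compact
#' letter display from [compare_layer_performance()].
#'
#' @param results list of `nested_cv_result` objects.
#' @param alpha significance level for the letters, default 0.05.
#' @return A ggplot.
#' @export
plot_layer_performance <- function(results, alpha = 0.05) {
  cmp <- compare_layer_performance(results, alpha = alpha)
  d <- purrr::map_dfr(results, tidy)
  lab <- cmp$letters
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$layer, -.data$r2,
                                                     FUN = median),
                                  y = .data$r2)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$layer, y = max(d$r2) + 0.05,
                                    label = .data$letters)) +
    ggplot2::labs(x = NULL, y = "hold-out R² (per outer fold)",
                  subtitle = "layers sharing a letter do not differ (BH-adjusted rank-sum)") +
    ggplot2::theme_minimal()
}

#' Residual distribution coloured by metabolic group
#'
#' @param object a [residualize_and_classify()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot residual_classification
#' @export
autoplot.residual_classification <- function(object, ...) {
  d <- object$samples
  thr <- object$thresholds
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residual, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 60, colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = unname(thr), linetype = 2) +
    ggplot2::labs(x = "metBMI residual (kg m⁻²)", y = "participants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bootstrap distributions of the mediation effects
#'
#' @param object a [mediate()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  d <- tibble::tibble(
    effect = rep(c("ACME", "ADE", "total"),
                 times = c(length(object$boot_acme), length(object$boot_ade),
                           length(object$boot_total))),
    draw = c(object$boot_acme, object$boot_ade, object$boot_total))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::labs(x = "bootstrap draw", y = NULL,
                  title = sprintf("%s → %s → %s", object$exposure_id,
                                  object$mediator_id, object$outcome_id)) +
    ggplot2::theme_minimal()
}

#' Linkage class counts across the mediation grids
#'
#' @param object a [classify_linkages()] table.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot linkage_table
#' @export
autoplot.linkage_table <- function(object, ...) {
  d <- dplyr::count(tibble::as_tibble(object), .data$linkage)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$linkage, .data$n),
                                  y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "triples") +
    ggplot2::theme_minimal()
}

#' Odds ratios per 1 SD with Wald confidence intervals
#'
#' @param object an [fit_outcome_model()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot outcome_model_result
#' @export
autoplot.outcome_model_result <- function(object, ...) {
  d <- object$estimates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio per 1 SD (95% CI)", y = NULL,
                  title = object$outcome) +
    ggplot2::theme_minimal()
}
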