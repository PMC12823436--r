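#' Variance explained by an omics layer via nested cross-validated
#' penalized regression
#'
#' Estimates how much of a target's variance an omics layer can explain,
#' guarding against optimistic penalty selection by nesting: each of
#' `k_outer` outer folds is held out in turn while the remaining folds run an
#' inner `k_inner`-fold grid search (100 log-spaced penalties, minimum ratio
#' 1e-5) for the penalty minimising inner-CV mean squared error; the refit
#' model then predicts the untouched outer fold. Hold-out R^2 uses the
#' held-out fold's own mean in the denominator and negative values are
#' reported as-is. Features are standardized on the training folds only
#' (inside the penalized fit), so no information leaks from held-out samples.
#' Outer folds are stratified on target deciles to stabilise fold R^2 for
#' skewed targets; inner-CV ties break toward the larger penalty.
#'
#' @param data a data frame (e.g. the cohort table) containing `target`.
#' @param target column name of the numeric target.
#' @param layer an [omics_layer()] providing the predictors; sample ids are
#'   matched to `data$sample_id`.
#' @param penalty_kind `"ridge"` or `"lasso"`.
#' @param k_outer,k_inner outer/inner fold counts (default 10/10).
#' @param seed integer seed driving fold assignment and inner CV.
#' @param folds optional explicit outer-fold assignment (integer vector in
#'   `1..k_outer`, one entry per complete-case sample); overrides the seeded
#'   stratified assignment.
#' @return A list of class `nested_cv_result`: `target_name`, `layer_name`,
#'   `penalty_kind`, `per_fold_r2`, `median_r2`, `chosen_penalty_per_fold`,
#'   `fold_assignment` (tibble `sample_id`, `fold`), `n_dropped_constant`,
#'   `seed`.
#' @export
nested_cv_r2 <- function(data, target, layer,
                         penalty_kind = c("ridge", "lasso"),
                         k_outer = 10, k_inner = 10, seed = 1, folds = NULL) {
  penalty_kind <- match.arg(penalty_kind)
  k_outer <- check_count(k_outer, "k_outer", min = 2)
  k_inner <- check_count(k_inner, "k_inner", min = 2)
  stopifnot(target %in% names(data))
  X <- layer_values(layer)
  idx <- match(data$sample_id, rownames(X))
  if (anyNA(idx)) abort("layer is missing samples present in `data`")
  X <- X[idx, , drop = FALSE]
  y <- data[[target]]
  ok <- complete.cases(y, X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 2 * k_outer) abort("need at least 2 samples per outer fold")
  if (sd(y) == 0) abort("constant target")
  const <- apply(X, 2, sd) == 0
  if (any(const)) X <- X[, !const, drop = FALSE]
  alpha <- if (penalty_kind == "ridge") 0 else 1

  fold <- if (is.null(folds)) {
    stratified_folds(y, k_outer, seed)
  } else {
    stopifnot(length(folds) == n, all(folds %in% seq_len(k_outer)))
    as.integer(folds)
  }
  per_fold <- numeric(k_outer)
  lam <- numeric(k_outer)
  for (f in seq_len(k_outer)) {
    tr <- fold != f
    cvfit <- with_seed(derive_seed(seed, paste0("inner", f)), {
      glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                        nfolds = k_inner, nlambda = 100,
                        lambda.min.ratio = 1e-5, standardize = TRUE)
    })
    lam[f] <- cvfit$lambda.min
    yhat <- drop(predict(cvfit, X[!tr, , drop = FALSE], s = "lambda.min"))
    per_fold[f] <- holdout_r2(y[!tr], yhat)
  }
  structure(list(
    target_name = target,
    layer_name = attr(layer, "layer_name") %||% "layer",
    penalty_kind = penalty_kind,
    per_fold_r2 = per_fold,
    median_r2 = median(per_fold),
    chosen_penalty_per_fold = lam,
    fold_assignment = tibble::tibble(sample_id = data$sample_id[ok], fold = fold),
    n_dropped_constant = sum(const),
    seed = seed
  ), class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %s ~ %s (%s): median hold-out R^2 = %.3f over %d folds\n",
              x$target_name, x$layer_name, x$penalty_kind, x$median_r2,
              length(x$per_fold_r2)))
  invisible(x)
}

#' Drop the layer containing a target feature
#'
#' When predicting a single omics variable, the whole feature space it
#' belongs to is excluded (a metabolite is never predicted from the
#' metabolome). Targets absent from every layer (e.g. BMI, gene richness)
#' leave the set unchanged; a target found in several layers is an error.
#'
#' @param target_feature_id feature id (or cohort column name).
#' @param layers named list of [omics_layer()] objects.
#' @return The layer list without the layer holding the target.
#' @export
exclude_self_layer <- function(target_feature_id, layers) {
  hit <- names(layers)[vapply(layers, function(l) {
    target_feature_id %in% setdiff(names(l), "sample_id")
  }, logical(1))]
  if (length(hit) > 1) {
    abort(sprintf("'%s' appears in multiple layers: %s", target_feature_id,
                  paste(hit, collapse = ", ")))
  }
  if (length(hit) == 1) layers[setdiff(names(layers), hit)] else layers
}

#' Compare per-fold performance across layers
#'
#' All pairwise two-sided Wilcoxon rank-sum tests on the per-fold hold-out
#' R^2 vectors, Benjamini-Hochberg adjusted across pairs, summarised as a
#' compact letter display: layers sharing a letter do not differ at adjusted
#' p >= `alpha`. Letters are the maximal cliques of the
#' not-significantly-different graph.
#'
#' @param results list of `nested_cv_result` objects (>= 2, equal fold counts,
#'   >= 3 folds each).
#' @param alpha significance level for the letter display, default 0.05.
#' @return List with `pairwise` (tibble: `layer1`, `layer2`, `statistic`,
#'   `p`, `q`) and `letters` (tibble: `layer`, `median_r2`, `letters`).
#' @export
compare_layer_performance <- function(results, alpha = 0.05) {
  if (length(results) < 2) abort("need >= 2 layers")
  folds <- vapply(results, function(r) length(r$per_fold_r2), integer(1))
  if (length(unique(folds)) != 1) abort("fold counts differ across layers")
  if (folds[1] < 3) abort("need >= 3 folds per layer")
  nms <- vapply(results, `[[`, character(1), "layer_name")
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  prs <- utils::combn(length(results), 2, simplify = FALSE)
  pw <- purrr::map_dfr(prs, function(pr) {
    a <- results[[pr[1]]]$per_fold_r2
    b <- results[[pr[2]]]$per_fold_r2
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    tibble::tibble(layer1 = nms[pr[1]], layer2 = nms[pr[2]],
                   statistic = unname(wt$statistic), p = wt$p.value)
  })
  pw$q <- bh_adjust(pw$p)

  # compact letter display: maximal cliques of the "not different" graph
  g <- igraph::make_empty_graph(n = length(nms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nms)
  ns_pairs <- pw[pw$q >= alpha, c("layer1", "layer2")]
  if (nrow(ns_pairs)) {
    g <- igraph::add_edges(g, t(as.matrix(ns_pairs)))
  }
  cliques <- igraph::max_cliques(g)
  ord <- order(vapply(cliques, function(cl) {
    -max(vapply(results[match(names(cl), nms)], `[[`, numeric(1), "median_r2"))
  }, numeric(1)))
  cliques <- cliques[ord]
  letter_of <- setNames(rep("", length(nms)), nms)
  for (i in seq_along(cliques)) {
    members <- names(cliques[[i]])
    letter_of[members] <- paste0(letter_of[members], letters[i])
  }
  med <- vapply(results, `[[`, numeric(1), "median_r2")
  lt <- tibble::tibble(layer = nms, median_r2 = med,
                       letters = unname(letter_of[nms]))
  lt <- dplyr::arrange(lt, dplyr::desc(.data$median_r2))
  list(pairwise = pw, letters = lt)
}
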