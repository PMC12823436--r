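# All-relevant feature screening with shadow features, plus sparse-stability
# frequencies, feeding a compact metabolite panel.

# default importance source: z-scored permutation importance of a
# random-forest regressor on the augmented (real + shadow) design; scaling
# by the per-tree SE calibrates the max-shadow threshold so persistent
# in-sample noise does not accumulate hits
ranger_importance <- function(X, y, num_trees = 150) {
  d <- as.data.frame(X)
  d$.target <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = d,
    num.trees = num_trees, importance = "permutation",
    scale.permutation.importance = TRUE,
    num.threads = 1, verbose = FALSE,
    respect.unordered.factors = FALSE)
  fit$variable.importance
}

# alternative importance source: |standardized ridge coefficient|
ridge_importance <- function(X, y, num_trees = NULL) {
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  fit <- glmnet::glmnet(X, y, alpha = 0, nlambda = 20, standardize = TRUE)
  beta <- abs(fit$beta[, ncol(fit$beta)]) * sds
  setNames(as.numeric(beta), colnames(X))
}

#' Shadow-feature all-relevant selection
#'
#' Iteratively appends a permuted "shadow" copy of every candidate feature,
#' scores all columns with a permutation-importance source (random-forest by
#' default), and records a *hit* for each real feature whose importance
#' exceeds the maximum shadow importance. After each run, two-sided binomial
#' tests on the hit counts (Bonferroni-corrected across the still-undecided
#' features) confirm features hitting significantly more than half the runs
#' and reject features hitting significantly less; the loop ends when every
#' feature is resolved or the run budget is exhausted, leaving the remainder
#' tentative. Rejected features are removed from subsequent designs.
#'
#' @param features data frame (or [omics_layer()]) of numeric candidates;
#'   a `sample_id` column is ignored.
#' @param target numeric target vector (length `nrow(features)`, n >= 50).
#' @param n_runs maximum importance-source runs, default 999.
#' @param alpha decision level for the binomial tests, default 0.05.
#' @param seed integer seed.
#' @param importance `"ranger"` (permutation importance, default) or
#'   `"ridge"` (|standardized ridge coefficient|), or a function
#'   `f(X, y, num_trees)` returning a named importance vector.
#' @param num_trees trees per forest for the default source, default 150.
#' @return A list of class `panel_partition`: `confirmed`, `tentative`,
#'   `rejected` (character vectors partitioning the candidates), `hits`
#'   (tibble with per-feature hit counts and runs used), `n_runs_used`.
#' @export
shadow_feature_selection <- function(features, target, n_runs = 999,
                                     alpha = 0.05, seed = 1,
                                     importance = c("ranger", "ridge"),
                                     num_trees = 150) {
  imp_fun <- if (is.function(importance)) {
    importance
  } else {
    switch(match.arg(importance), ranger = ranger_importance,
           ridge = ridge_importance)
  }
  X <- as.matrix(strip_ids(tibble::as_tibble(as.data.frame(features))))
  n <- nrow(X); p <- ncol(X)
  if (n < 50) abort("need n >= 50 samples")
  if (length(target) != n) abort("target length mismatch")
  n_runs <- check_count(n_runs, "n_runs")
  # the smallest achievable two-sided binomial p after all runs must clear
  # the Bonferroni-corrected level, else no decision is ever possible
  if (2 * 0.5^n_runs >= alpha / p) {
    abort(sprintf("n_runs = %d cannot reach alpha/p = %.3g for any feature",
                  n_runs, alpha / p))
  }
  feats <- colnames(X)
  status <- setNames(rep("undecided", p), feats)
  hits <- setNames(integer(p), feats)
  runs <- setNames(integer(p), feats)
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      active <- feats[status != "rejected"]
      Xa <- X[, active, drop = FALSE]
      Xs <- apply(Xa, 2, sample)
      colnames(Xs) <- paste0(".shadow.", active)
      imp <- imp_fun(cbind(Xa, Xs), target, num_trees)
      thr <- max(imp[colnames(Xs)])
      hit_now <- imp[active] > thr
      und <- feats[status == "undecided"]
      hits[und] <- hits[und] + as.integer(hit_now[und])
      runs[und] <- runs[und] + 1L
      # Bonferroni across the features still in play
      lvl <- alpha / max(sum(status == "undecided"), 1)
      for (f in und) {
        p_hi <- stats::pbinom(hits[f] - 1L, runs[f], 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[f], runs[f], 0.5)
        p2 <- 2 * min(p_hi, p_lo)
        if (p2 < lvl) {
          status[f] <- if (hits[f] > runs[f] / 2) "confirmed" else "rejected"
        }
      }
      if (!any(status == "undecided")) break
    }
  })
  status[status == "undecided"] <- "tentative"
  structure(list(
    confirmed = feats[status == "confirmed"],
    tentative = feats[status == "tentative"],
    rejected = feats[status == "rejected"],
    hits = tibble::tibble(feature = feats, hits = unname(hits),
                          runs = unname(runs), status = unname(status)),
    n_runs_used = max(runs)
  ), class = "panel_partition")
}

#' @export
print.panel_partition <- function(x, ...) {
  cat(sprintf("<panel_partition> %d confirmed / %d tentative / %d rejected (runs used: %d)\n",
              length(x$confirmed), length(x$tentative), length(x$rejected),
              x$n_runs_used))
  invisible(x)
}

#' Selection frequency under iterative sparse resampling
#'
#' Fits an L1-penalized (lasso) regression with a cross-validation-chosen
#' penalty on each of `n_resamples` seeded 80% row resamples; a feature's
#' frequency is the fraction of resamples in which its coefficient is
#' non-zero. The penalty defaults to the one-standard-error rule
#' (`"1se"`): the largest penalty whose CV error is within one SE of the
#' minimum. The parsimonious choice keeps the selection frequencies of
#' irrelevant features near zero, which is the point of a stability stage;
#' `"min"` (the CV-MSE minimiser) is available for sensitivity checks.
#'
#' @inheritParams shadow_feature_selection
#' @param n_resamples number of resamples, default 10.
#' @param penalty `"1se"` (default) or `"min"`.
#' @return Tibble with `feature`, `frequency`.
#' @export
iterative_sparse_stability <- function(features, target, n_resamples = 10,
                                       seed = 1, penalty = c("1se", "min")) {
  penalty <- match.arg(penalty)
  X <- as.matrix(strip_ids(tibble::as_tibble(as.data.frame(features))))
  n <- nrow(X)
  if (n < 50) abort("need n >= 50 samples")
  n_resamples <- check_count(n_resamples, "n_resamples")
  sel <- matrix(FALSE, n_resamples, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (r in seq_len(n_resamples)) {
    idx <- with_seed(derive_seed(seed, paste0("resample", r)),
                     sample.int(n, round(0.8 * n)))
    if (sd(target[idx]) == 0) abort("degenerate resample: constant target")
    cvfit <- with_seed(derive_seed(seed, paste0("cv", r)), {
      glmnet::cv.glmnet(X[idx, , drop = FALSE], target[idx], alpha = 1,
                        nfolds = 10, nlambda = 100, lambda.min.ratio = 1e-5,
                        standardize = TRUE)
    })
    beta <- drop(as.matrix(coef(cvfit, s = paste0("lambda.", penalty))))[-1]
    sel[r, ] <- beta != 0
  }
  tibble::tibble(feature = colnames(X), frequency = unname(colMeans(sel)))
}

#' Assemble the final metabolite panel and verify retained power
#'
#' Combines the shadow-feature partition and the stability frequencies into
#' a panel (default rule: the confirmed features, ranked by selection
#' frequency then by `|rho|` with the target; `"union"` additionally admits
#' tentative features selected in at least `union_freq` of the sparse
#' resamples), then refits the ridge metBMI pipeline on the original
#' training/test split with the panel only and with the full candidate set,
#' reporting both hold-out R^2 values side by side.
#'
#' @param partition a [shadow_feature_selection()] result.
#' @param frequencies tibble from [iterative_sparse_stability()].
#' @param metabolome an [omics_layer()].
#' @param cohort cohort tibble.
#' @param split list from [split_train_test()].
#' @param rule `"confirmed"` (default) or `"union"`.
#' @param union_freq stability-frequency gate for the union rule, default 0.8.
#' @param seed integer seed for the refits.
#' @return A list of class `panel_selection_result`: `final_panel` (ranked
#'   tibble), `panel_r2`, `full_model_r2`, `rule`.
#' @export
assemble_panel <- function(partition, frequencies, metabolome, cohort, split,
                           rule = c("confirmed", "union"), union_freq = 0.8,
                           seed = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(partition, "panel_partition"))
  panel <- partition$confirmed
  if (rule == "union") {
    stable <- frequencies$feature[frequencies$frequency >= union_freq]
    panel <- union(panel, intersect(stable, c(partition$confirmed,
                                              partition$tentative)))
  }
  if (!length(panel)) abort("empty panel: nothing confirmed (or admitted by the union rule)")
  X <- layer_values(metabolome)
  bmi <- cohort$bmi[match(rownames(X), cohort$sample_id)]
  rho <- vapply(panel, function(f) {
    suppressWarnings(abs(cor(rank(X[, f]), rank(bmi), use = "complete.obs")))
  }, numeric(1))
  freq <- setNames(frequencies$frequency, frequencies$feature)[panel]
  freq[is.na(freq)] <- 0
  ranked <- tibble::tibble(feature = panel, frequency = unname(freq),
                           abs_rho = unname(rho))
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$frequency),
                           dplyr::desc(.data$abs_rho))
  candidates <- c(partition$confirmed, partition$tentative, partition$rejected)
  fit_panel <- fit_metbmi(metabolome, cohort, ranked$feature, split,
                          penalty_kind = "ridge", seed = seed)
  fit_full <- fit_metbmi(metabolome, cohort, candidates, split,
                         penalty_kind = "ridge", seed = seed)
  structure(list(final_panel = ranked,
                 panel_r2 = fit_panel$test_r2,
                 full_model_r2 = fit_full$test_r2,
                 rule = rule),
            class = "panel_selection_result")
}

#' @export
print.panel_selection_result <- function(x, ...) {
  cat(sprintf("<panel_selection_result> %d-feature panel (%s rule): panel R^2 = %.3f vs full %.3f (%.0f%% retained)\n",
              nrow(x$final_panel), x$rule, x$panel_r2, x$full_model_r2,
              100 * x$panel_r2 / x$full_model_r2))
  invisible(x)
}
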