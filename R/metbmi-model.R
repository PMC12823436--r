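#' Pre-select metabolites associated with BMI
#'
#' Retains metabolites whose absolute Spearman correlation with BMI exceeds
#' `rho_threshold` and whose Benjamini-Hochberg adjusted p-value is below
#' `q_threshold`, sorted by `|rho|` descending. Both gates default on; the
#' significance gate can be disabled with `q_threshold = 1`.
#'
#' @param metabolome an [omics_layer()] of log-scale metabolite intensities.
#' @param cohort cohort tibble with `sample_id` and `bmi`.
#' @param rho_threshold minimum `|rho|`, default 0.1.
#' @param q_threshold maximum BH-adjusted p, default 0.05.
#' @return Tibble with `metabolite`, `rho`, `p`, `q`, sorted by `|rho|`
#'   descending. Errors if no metabolite passes.
#' @export
select_bmi_metabolites <- function(metabolome, cohort,
                                   rho_threshold = 0.1, q_threshold = 0.05) {
  X <- layer_values(metabolome)
  idx <- match(cohort$sample_id, rownames(X))
  if (anyNA(idx)) abort("metabolome is missing cohort samples")
  X <- X[idx, , drop = FALSE]
  bmi <- cohort$bmi
  const <- apply(X, 2, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(sprintf("dropping %d constant metabolite(s) before association testing",
                 sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) abort("no metabolite with variation available for the pre-filter")
  res <- purrr::map_dfr(colnames(X), function(j) {
    ok <- complete.cases(X[, j], bmi)
    if (sum(ok) < 30) abort(sprintf("metabolite '%s' has < 30 complete pairs", j))
    s <- rank_cor_t(rank(X[ok, j]), rank(bmi[ok]))
    tibble::tibble(metabolite = j, rho = s$rho, p = s$p)
  })
  res$q <- bh_adjust(res$p)
  keep <- dplyr::filter(res, abs(.data$rho) > rho_threshold,
                        .data$q < q_threshold)
  if (!nrow(keep)) {
    abort("no metabolite passed the BMI association pre-filter; consider relaxing rho_threshold / q_threshold")
  }
  dplyr::arrange(keep, dplyr::desc(abs(.data$rho)))
}

#' WHO BMI class and metabolic-group labelling rules
#'
#' `who_bmi_class()` maps BMI to the WHO classes (normal weight below
#' 25 kg m^-2, overweight 25-29.9, obesity >= 30; the rare participant below
#' 18.5 is folded into normal weight). `classify_metbmi_groups()` applies the
#' residual rule: residual strictly below `low` is LmetBMI, strictly above
#' `high` is HmetBMI, boundary values and the interior keep their WHO class.
#'
#' @param bmi numeric BMI vector (kg m^-2).
#' @return Character vector of class labels.
#' @export
who_bmi_class <- function(bmi) {
  dplyr::case_when(
    bmi >= 30 ~ "obesity",
    bmi >= 25 ~ "overweight",
    TRUE ~ "normal weight"   # cohort members below 18.5 fold into this class
  )
}

#' @rdname who_bmi_class
#' @param residual metBMI residual vector (kg m^-2).
#' @param low,high residual cut points (strict inequalities), defaults -2.5 / +2.5.
#' @export
classify_metbmi_groups <- function(residual, bmi, low = -2.5, high = 2.5) {
  dplyr::case_when(
    residual < low ~ "LmetBMI",
    residual > high ~ "HmetBMI",
    TRUE ~ who_bmi_class(bmi)
  )
}

strata_labels <- function(cohort) {
  in_bins <- cohort$bmi >= 18.5
  cls <- dplyr::case_when(
    cohort$bmi >= 30 ~ "obesity",
    cohort$bmi >= 25 ~ "overweight",
    cohort$bmi >= 18.5 ~ "normal",
    TRUE ~ NA_character_
  )
  ifelse(in_bins, paste0(ifelse(cohort$sex == 1, "male", "female"), ".", cls),
         NA_character_)
}

#' Balanced sampling from sex-by-WHO-BMI strata
#'
#' Forms the six strata {female, male} x {BMI 18.5-24.9, 25-29.9, >= 30} and
#' draws, without replacement, from every stratum as many samples as the
#' smallest stratum holds, yielding a sex- and BMI-balanced training pool.
#' Participants outside all strata (BMI < 18.5) are routed to the non-test
#' set.
#'
#' @param cohort cohort tibble with `sample_id`, `sex` (0/1), `bmi`.
#' @param seed integer seed.
#' @return List with `pool` (tibble: `sample_id`, `stratum`), `strata_counts`
#'   (named integer vector of the six stratum sizes), `non_strata_ids`
#'   (BMI < 18.5 sample ids).
#' @export
balanced_strata_sample <- function(cohort, seed = 1) {
  lab <- strata_labels(cohort)
  all6 <- c(t(outer(c("female", "male"), c("normal", "overweight", "obesity"),
                    paste, sep = ".")))
  counts <- table(factor(lab, levels = all6))
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    abort(sprintf("empty stratum(s): %s", paste(empty, collapse = ", ")))
  }
  m <- min(counts)
  pool <- with_seed(seed, {
    purrr::map_dfr(all6, function(s) {
      ids <- cohort$sample_id[!is.na(lab) & lab == s]
      tibble::tibble(sample_id = sample(ids, m), stratum = s)
    })
  })
  list(pool = pool,
       strata_counts = setNames(as.integer(counts), names(counts)),
       non_strata_ids = cohort$sample_id[is.na(lab)])
}

#' Split the balanced pool into training and test sets
#'
#' A seeded 75/25 split stratified on the six sex-by-BMI strata; all cohort
#' members outside the pool join the test set to form the extended test set.
#'
#' @param pool tibble from [balanced_strata_sample()] (`sample_id`, `stratum`).
#' @param cohort full cohort tibble (supplies the non-pool samples).
#' @param train_fraction training fraction, default 0.75.
#' @param seed integer seed.
#' @return List with `train_ids`, `test_ids`, `non_test_ids`,
#'   `extended_test_ids` (= test + non-test).
#' @export
split_train_test <- function(pool, cohort, train_fraction = 0.75, seed = 1) {
  check_fraction(train_fraction, "train_fraction", lo_open = TRUE, hi_open = TRUE)
  if (nrow(pool) < 8) abort("pool too small to split (need >= 8)")
  train <- with_seed(seed, {
    unlist(lapply(split(pool$sample_id, pool$stratum), function(ids) {
      sample(ids, round(train_fraction * length(ids)))
    }), use.names = FALSE)
  })
  test <- setdiff(pool$sample_id, train)
  non_test <- setdiff(cohort$sample_id, pool$sample_id)
  list(train_ids = train, test_ids = test, non_test_ids = non_test,
       extended_test_ids = c(test, non_test))
}

#' Fit the metabolome BMI model
#'
#' Penalized (default ridge) regression of BMI on the pre-filtered
#' metabolites over the training set, with the penalty chosen by k-fold
#' cross-validation minimising mean squared error over a 100-value log-spaced
#' grid (minimum ratio 1e-5). Performance is the hold-out R^2 on the
#' untouched test set.
#'
#' @param metabolome an [omics_layer()].
#' @param cohort cohort tibble with `sample_id`, `bmi`.
#' @param prefilter_ids metabolite ids from [select_bmi_metabolites()].
#' @param split list from [split_train_test()].
#' @param penalty_kind `"ridge"` (default) or `"lasso"`.
#' @param grid_length penalty grid length, default 100.
#' @param k_cv CV folds, default 10.
#' @param seed integer seed.
#' @return A list of class `metbmi_model` with the coefficients (centred
#'   coding: intercept plus per-feature slopes and stored feature means),
#'   `chosen_penalty`, `test_r2`, the split record and provenance.
#' @export
fit_metbmi <- function(metabolome, cohort, prefilter_ids, split,
                       penalty_kind = c("ridge", "lasso"),
                       grid_length = 100, k_cv = 10, seed = 1) {
  penalty_kind <- match.arg(penalty_kind)
  X <- layer_values(metabolome)
  missing_ids <- setdiff(prefilter_ids, colnames(X))
  if (length(missing_ids)) {
    abort(sprintf("metabolome lacks prefilter metabolite(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  X <- X[, prefilter_ids, drop = FALSE]
  if (any(!is.finite(X))) {
    bad <- colnames(X)[colSums(!is.finite(X)) > 0]
    abort(sprintf("non-finite values in feature(s): %s", paste(bad, collapse = ", ")))
  }
  bmi <- setNames(cohort$bmi, cohort$sample_id)
  tr_idx <- match(split$train_ids, rownames(X))
  te_idx <- match(split$test_ids, rownames(X))
  if (anyNA(tr_idx) || anyNA(te_idx)) abort("split ids missing from metabolome")
  alpha <- if (penalty_kind == "ridge") 0 else 1
  # glmnet needs >= 2 columns; a constant pad column takes coefficient 0
  Xtr <- X[tr_idx, , drop = FALSE]
  padded <- ncol(Xtr) < 2
  if (padded) Xtr <- cbind(Xtr, .pad = 0)
  cvfit <- with_seed(seed, {
    glmnet::cv.glmnet(Xtr, bmi[split$train_ids],
                      alpha = alpha, nfolds = k_cv, nlambda = grid_length,
                      lambda.min.ratio = 1e-5, standardize = TRUE)
  })
  beta <- drop(as.matrix(coef(cvfit, s = "lambda.min")))
  if (padded) beta <- beta[names(beta) != ".pad"]
  b0_raw <- beta[1]; b <- beta[-1]
  x_mean <- colMeans(X[tr_idx, , drop = FALSE])
  # centred coding: prediction = intercept_centred + (x - x_mean) %*% b
  intercept_centred <- b0_raw + sum(b * x_mean)
  model <- structure(list(
    prefilter_ids = prefilter_ids,
    penalty_kind = penalty_kind,
    chosen_penalty = cvfit$lambda.min,
    coefficients = setNames(b, prefilter_ids),
    intercept = intercept_centred,
    feature_means = x_mean,
    train_ids = split$train_ids, test_ids = split$test_ids,
    non_test_ids = split$non_test_ids,
    grid_length = grid_length, k_cv = k_cv, seed = seed
  ), class = "metbmi_model")
  pred_test <- predict_metbmi(model, metabolome)
  te <- match(split$test_ids, pred_test$sample_id)
  model$test_r2 <- holdout_r2(bmi[split$test_ids], pred_test$metbmi[te])
  model
}

#' @export
print.metbmi_model <- function(x, ...) {
  cat(sprintf("<metbmi_model> %s, %d metabolites, lambda = %.4g, test R^2 = %.3f\n",
              x$penalty_kind, length(x$prefilter_ids), x$chosen_penalty,
              x$test_r2 %||% NA_real_))
  invisible(x)
}

#' Predict metBMI for every sample
#'
#' Deterministic linear score from the stored coefficients and training
#' feature means; all pre-filter metabolites must be present.
#'
#' @param model a [fit_metbmi()] model.
#' @param metabolome an [omics_layer()].
#' @return Tibble with `sample_id`, `metbmi`.
#' @export
predict_metbmi <- function(model, metabolome) {
  X <- layer_values(metabolome)
  missing_ids <- setdiff(model$prefilter_ids, colnames(X))
  if (length(missing_ids)) {
    abort(sprintf("missing required metabolite(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  X <- X[, model$prefilter_ids, drop = FALSE]
  score <- model$intercept +
    drop(sweep(X, 2, model$feature_means) %*% model$coefficients)
  tibble::tibble(sample_id = rownames(X), metbmi = unname(score))
}

#' Residualize metBMI and classify metabolic groups
#'
#' Extracts the residuals of `metbmi ~ age + sex + bmi` (ordinary least
#' squares over the full cohort) and labels participants: residual below
#' `low` is LmetBMI, above `high` is HmetBMI (strict inequalities — boundary
#' residuals keep their WHO class), all others take their WHO BMI class.
#' Thresholds are in metBMI units (kg m^-2).
#'
#' @param metbmi tibble from [predict_metbmi()].
#' @param cohort cohort tibble with `sample_id`, `age`, `sex`, `bmi`.
#' @param low,high residual cut points, defaults -2.5 / +2.5 kg m^-2.
#' @return A list of class `residual_classification` with `samples` (tibble:
#'   `sample_id`, `metbmi`, `residual`, `group`), `group_sizes`,
#'   `residual_sd` and the residual-covariate correlations.
#' @export
residualize_and_classify <- function(metbmi, cohort, low = -2.5, high = 2.5) {
  stopifnot(low < high)
  d <- dplyr::inner_join(metbmi, cohort, by = "sample_id")
  if (anyNA(d$age) || anyNA(d$sex) || anyNA(d$bmi)) {
    abort("age, sex and bmi must be non-missing")
  }
  Z <- cbind(1, d$age, d$sex, d$bmi)
  if (qr(Z)$rank < ncol(Z)) abort("rank-deficient residualization design")
  fit <- lm.fit(Z, d$metbmi)
  resid <- fit$residuals
  group <- classify_metbmi_groups(resid, d$bmi, low, high)
  samples <- tibble::tibble(sample_id = d$sample_id, metbmi = d$metbmi,
                            residual = resid, group = group)
  structure(list(
    samples = samples,
    group_sizes = table(factor(group, levels = c("LmetBMI", "normal weight",
                                                 "overweight", "obesity",
                                                 "HmetBMI"))),
    residual_sd = sd(resid),
    thresholds = c(low = low, high = high),
    residual_covariate_cor = c(age = cor(resid, d$age),
                               sex = cor(resid, d$sex),
                               bmi = cor(resid, d$bmi))
  ), class = "residual_classification")
}

#' @export
print.residual_classification <- function(x, ...) {
  cat("<residual_classification> residual SD =", round(x$residual_sd, 2),
      "kg m^-2\n")
  print(x$group_sizes)
  invisible(x)
}
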