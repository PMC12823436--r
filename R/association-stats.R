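# Rank-based association utilities used across the descriptive analyses.

# average-rank Spearman rho with t-approximation p-value; df optionally
# reduced when covariates were projected out beforehand
rank_cor_t <- function(rx, ry, n_covariates = 0) {
  n <- length(rx)
  r <- cor(rx, ry)
  df <- n - n_covariates - 2
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(rho = r, p = min(p, 1), n = n, df = df)
}

#' Spearman correlation with t-approximation p-value
#'
#' Average ranks for ties; p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors (pairwise-complete cases are used;
#'   at least 4 required).
#' @return Tibble with `rho`, `p`, `n_used`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 4) abort("need >= 4 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) abort("constant input vector")
  res <- rank_cor_t(rank(x), rank(y))
  tibble::tibble(rho = res$rho, p = res$p, n_used = res$n)
}

#' Partial Spearman correlation adjusted for covariates
#'
#' Rank-transforms `x` and `y` (average ranks), residualises each on the
#' covariate design by ordinary least squares, and correlates the residuals;
#' the p-value uses the t approximation with `n - k - 2` degrees of freedom
#' for `k` covariates. With an empty covariate set this reduces exactly to
#' [spearman_cor()]. Categorical covariates (e.g. sex) must already be coded
#' numerically.
#'
#' @param data data frame holding all columns.
#' @param x,y column names of the two variables.
#' @param covariates character vector of covariate column names (may be empty).
#' @return Tibble with `x`, `y`, `covariates`, `rho`, `p`, `n_used`.
#' @export
partial_spearman <- function(data, x, y, covariates = character()) {
  cols <- c(x, y, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[cols]
  ok <- complete.cases(d)
  if (sum(ok) < length(covariates) + 3) {
    abort("need >= covariates + 3 complete cases")
  }
  d <- d[ok, , drop = FALSE]
  rx <- rank(d[[x]]); ry <- rank(d[[y]])
  if (sd(rx) == 0 || sd(ry) == 0) abort("constant variable after ranking")
  if (length(covariates)) {
    Z <- cbind(1, as.matrix(d[covariates]))
    rx <- lm.fit(Z, rx)$residuals
    ry <- lm.fit(Z, ry)$residuals
  }
  res <- rank_cor_t(rx, ry, n_covariates = length(covariates))
  tibble::tibble(x = x, y = y,
                 covariates = paste(covariates, collapse = ","),
                 rho = res$rho, p = res$p, n_used = res$n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps `stats::p.adjust`); `NA`
#' inputs propagate as `NA` with a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) warn("NA p-values propagated as NA")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Omnibus and pairwise group-difference tests
#'
#' Kruskal-Wallis omnibus test (tie-corrected) across groups, followed by all
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment across pairs. Direction is reported as the difference of group
#' medians. Groups with fewer than 2 members are dropped with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @return List with `omnibus` (tibble: `statistic`, `df`, `p`) and
#'   `pairwise` (tibble: `group1`, `group2`, `median_diff`, `p`, `q`).
#' @export
group_difference_tests <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("dropping group(s) with < 2 members: %s",
                 paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  lv <- sort(unique(groups))
  if (length(lv) < 2) abort("need >= 2 groups with >= 2 members")
  kw <- kruskal.test(values, factor(groups))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   median_diff = median(a) - median(b), p = wt$p.value)
  })
  pw$q <- bh_adjust(pw$p)
  list(omnibus = tibble::tibble(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
       pairwise = pw)
}
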