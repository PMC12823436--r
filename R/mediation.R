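# Bidirectional bootstrap mediation: the model pair
#   m = a0 + a x            (mediator model)
#   y = b0 + c' x + b m     (outcome model)
# estimated by ordinary least squares; ACME = a*b (unstandardized indirect
# effect), ADE = c', total = a*b + c'. Uncertainty by nonparametric
# case-resampling of both fits jointly.

# closed-form OLS paths for a matrix of bootstrap resamples; columns of
# X, M, Y are resampled datasets
boot_paths <- function(X, M, Y) {
  n <- nrow(X)
  cm <- function(A) colMeans(A)
  xm <- cm(X); mm <- cm(M); ym <- cm(Y)
  Sxx <- colSums(X * X) - n * xm^2
  Smm <- colSums(M * M) - n * mm^2
  Sxm <- colSums(X * M) - n * xm * mm
  Sxy <- colSums(X * Y) - n * xm * ym
  Smy <- colSums(M * Y) - n * mm * ym
  a <- Sxm / Sxx
  det <- Sxx * Smm - Sxm^2
  # singular outcome design (mediator collinear with exposure): attribute the
  # shared effect to the mediator (b from y ~ m, direct effect 0)
  singular <- det <= 1e-12 * Sxx * Smm
  det_safe <- ifelse(singular, 1, det)
  c_prime <- ifelse(singular, 0, (Sxy * Smm - Smy * Sxm) / det_safe)
  b <- ifelse(singular, Smy / Smm, (Smy * Sxx - Sxy * Sxm) / det_safe)
  list(a = a, b = b, c_prime = c_prime)
}

boot_p_two_sided <- function(draws, n_boot) {
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  min(max(p, 2 / (n_boot + 1)), 1)
}

#' Bootstrap mediation analysis for one triple
#'
#' Ordinary-least-squares mediation of `y` on exposure `x` through mediator
#' `m` (no covariates: the outcome model is `y ~ x + m`). Point estimates are
#' the product-of-coefficients ACME `a*b`, the direct effect ADE `c'` and the
#' total effect `a*b + c'` (an exact identity for linear models).
#' Nonparametric case resampling refits both regressions on each bootstrap
#' draw; confidence intervals are percentile and two-sided p-values are
#' `2 * min(Pr(draw <= 0), Pr(draw >= 0))`, floored at `2/(n_boot + 1)`.
#'
#' @param x,m,y numeric vectors (complete cases >= 30 after pairwise removal).
#' @param n_boot bootstrap draws, default 1000 (a warning below 100).
#' @param seed integer seed.
#' @param ids optional feature ids recorded on the result
#'   (`exposure_id`, `mediator_id`, `outcome_id`).
#' @return A list of class `mediation_result`: `acme`, `ade`, `total_effect`,
#'   `prop_mediated`, per-quantity percentile CIs and p-values, the path
#'   coefficients `a`, `b`, `c_prime`, the bootstrap draws and `n_used`.
#' @export
mediate <- function(x, m, y, n_boot = 1000, seed = 1,
                    ids = c(exposure_id = "x", mediator_id = "m",
                            outcome_id = "y")) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 30) abort("need >= 30 complete cases")
  if (sd(x) == 0 || sd(m) == 0) abort("constant exposure or mediator")
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 100) warn("n_boot < 100 gives coarse p-values and CIs")

  pt_ <- boot_paths(matrix(x), matrix(m), matrix(y))
  acme <- pt_$a * pt_$b
  ade <- pt_$c_prime
  total <- acme + ade

  draws <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    bp <- boot_paths(matrix(x[idx], n), matrix(m[idx], n), matrix(y[idx], n))
    list(acme = bp$a * bp$b, ade = bp$c_prime,
         total = bp$a * bp$b + bp$c_prime)
  })
  ci <- function(v) unname(quantile(v, c(0.025, 0.975), na.rm = TRUE))
  structure(list(
    exposure_id = unname(ids[["exposure_id"]]),
    mediator_id = unname(ids[["mediator_id"]]),
    outcome_id = unname(ids[["outcome_id"]]),
    a = pt_$a[1], b = pt_$b[1], c_prime = pt_$c_prime[1],
    acme = acme[1], ade = ade[1], total_effect = total[1],
    acme_ci = ci(draws$acme), ade_ci = ci(draws$ade),
    total_ci = ci(draws$total),
    p_acme = boot_p_two_sided(draws$acme, n_boot),
    p_ade = boot_p_two_sided(draws$ade, n_boot),
    p_total = boot_p_two_sided(draws$total, n_boot),
    boot_acme = draws$acme, boot_ade = draws$ade, boot_total = draws$total,
    n_boot = n_boot, n_used = n, seed = seed
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s -> %s -> %s\n  ACME %.4f [%.4f, %.4f] p=%.4g; ADE %.4f [%.4f, %.4f] p=%.4g; total %.4f\n",
    x$exposure_id, x$mediator_id, x$outcome_id,
    x$acme, x$acme_ci[1], x$acme_ci[2], x$p_acme,
    x$ade, x$ade_ci[1], x$ade_ci[2], x$p_ade, x$total_effect))
  invisible(x)
}

#' Proportion of the total effect that is mediated
#'
#' Per-draw ratio `acme / total`; the point estimate is the median of the
#' bootstrap draws and the interval the 95% percentile CI. When the total
#' effect's bootstrap draws cross zero in more than 5% of draws the ratio is
#' unstable and the result is flagged.
#'
#' @param result a [mediate()] result.
#' @return Tibble with `prop_mediated`, `ci_low`, `ci_high`, `unstable`.
#' @export
proportion_mediated <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  tot <- result$boot_total
  sign_point <- sign(result$total_effect)
  crossing <- mean(sign(tot) != sign_point | tot == 0)
  ratio <- result$boot_acme / tot
  qs <- quantile(ratio, c(0.025, 0.5, 0.975), na.rm = TRUE)
  tibble::tibble(prop_mediated = unname(qs[2]),
                 ci_low = unname(qs[1]), ci_high = unname(qs[3]),
                 unstable = crossing > 0.05)
}

#' Pre-filter features for the mediation grids
#'
#' Computes pairwise Spearman correlations between every pair of the three
#' feature sets (microbiome x metabolite, microbiome x phenotype,
#' metabolite x phenotype), applies Benjamini-Hochberg within each set pair
#' (default) or pooled across all cross-set tests, and retains a feature only
#' when it has at least one cross-set partner with `|rho| >= rho_min` and
#' adjusted p < `q_max`. Candidate triples are the Cartesian grid over the
#' retained features of the three sets. Per-pair adjustment runs three BH
#' families, so under a global null the chance of retaining anything is up to
#' three times the per-family level; `bh_scope = "pooled"` caps it at `q_max`
#' overall.
#'
#' @param set_a,set_b,set_c data frames of numeric features on shared,
#'   aligned samples (microbiome, metabolites, phenotypes respectively; a
#'   `sample_id` column, if present, is used to align and then dropped).
#' @param rho_min minimum absolute Spearman rho, default 0.1.
#' @param q_max maximum BH-adjusted p, default 0.05.
#' @param bh_scope `"within_pair"` (default) or `"pooled"`.
#' @return List with `retained` (named list of kept feature ids per set),
#'   `triples` (tibble: `exposure`, `mediator`, `outcome`) and
#'   `pair_correlations` (tibble of all cross-set tests).
#' @export
prefilter_candidates <- function(set_a, set_b, set_c,
                                 rho_min = 0.1, q_max = 0.05,
                                 bh_scope = c("within_pair", "pooled")) {
  bh_scope <- match.arg(bh_scope)
  sets <- list(a = strip_ids(set_a), b = strip_ids(set_b), c = strip_ids(set_c))
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  cors <- purrr::map_dfr(pairs, function(pr) {
    A <- sets[[pr[1]]]; B <- sets[[pr[2]]]
    RA <- apply(as.matrix(A), 2, rank)
    RB <- apply(as.matrix(B), 2, rank)
    R <- suppressWarnings(cor(RA, RB))
    n <- nrow(RA)
    tv <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
    P <- 2 * pt(abs(tv), n - 2, lower.tail = FALSE)
    grid <- expand.grid(f1 = colnames(A), f2 = colnames(B),
                        stringsAsFactors = FALSE)
    tibble::tibble(pair = paste(pr, collapse = "-"),
                   f1 = grid$f1, f2 = grid$f2,
                   rho = as.vector(R), p = pmin(as.vector(P), 1))
  })
  if (bh_scope == "within_pair") {
    cors <- dplyr::group_by(cors, .data$pair)
    cors <- dplyr::mutate(cors, q = bh_adjust(.data$p))
    cors <- dplyr::ungroup(cors)
  } else {
    cors$q <- bh_adjust(cors$p)
  }
  sig <- dplyr::filter(cors, abs(.data$rho) >= rho_min, .data$q < q_max)
  retained <- list(
    a = intersect(colnames(sets$a), c(sig$f1[sig$pair %in% c("a-b", "a-c")])),
    b = intersect(colnames(sets$b),
                  c(sig$f2[sig$pair == "a-b"], sig$f1[sig$pair == "b-c"])),
    c = intersect(colnames(sets$c), c(sig$f2[sig$pair %in% c("a-c", "b-c")]))
  )
  if (!all(lengths(retained) > 0)) {
    warn("a retained set is empty; candidate grid is empty")
    triples <- tibble::tibble(exposure = character(), mediator = character(),
                              outcome = character())
  } else {
    triples <- tibble::as_tibble(expand.grid(exposure = retained$a,
                                             mediator = retained$b,
                                             outcome = retained$c,
                                             stringsAsFactors = FALSE))
  }
  list(retained = retained, triples = triples, pair_correlations = cors)
}

strip_ids <- function(d) {
  d <- tibble::as_tibble(d)
  dplyr::select(d, -dplyr::any_of("sample_id"))
}

#' Run the three bidirectional mediation grids
#'
#' Every candidate triple is evaluated in three orderings: `direct`
#' (microbiome -> metabolite -> phenotype), `reverse1` (microbiome ->
#' phenotype -> metabolite) and `reverse2` (phenotype -> metabolite ->
#' microbiome). ACME p-values are Benjamini-Hochberg adjusted within each
#' grid; ADE p-values are additionally adjusted within `reverse2` (the only
#' grid whose direct effect enters the linkage rules). Per-triple seeds
#' derive deterministically from the master seed and the triple's ids.
#'
#' @param triples tibble with `exposure`, `mediator`, `outcome` (ids into the
#'   three sets).
#' @param set_a,set_b,set_c aligned data frames: microbiome features,
#'   metabolites, phenotypes.
#' @param n_boot bootstrap draws per fit, default 1000.
#' @param seed master seed.
#' @return A tibble of class `grid_records`: one row per triple x grid with
#'   estimates, CIs, p-values, `fdr_acme` and (reverse2) `fdr_ade`.
#' @export
run_grids <- function(triples, set_a, set_b, set_c, n_boot = 1000, seed = 1) {
  set_a <- strip_ids(set_a); set_b <- strip_ids(set_b); set_c <- strip_ids(set_c)
  if (!nrow(triples)) {
    out <- tibble::tibble(exposure = character(), mediator = character(),
                          outcome = character(), grid = character(),
                          acme = numeric(), ade = numeric(),
                          total_effect = numeric(),
                          acme_ci_low = numeric(), acme_ci_high = numeric(),
                          p_acme = numeric(), p_ade = numeric(),
                          fdr_acme = numeric(), fdr_ade = numeric(),
                          error = character())
    class(out) <- c("grid_records", class(out))
    return(out)
  }
  grids <- c("direct", "reverse1", "reverse2")
  rows <- purrr::map_dfr(seq_len(nrow(triples)), function(i) {
    tr <- triples[i, ]
    xa <- set_a[[tr$exposure]]; mb <- set_b[[tr$mediator]]; yc <- set_c[[tr$outcome]]
    if (is.null(xa) || is.null(mb) || is.null(yc)) {
      abort(sprintf("triple (%s, %s, %s): feature not found in its set",
                    tr$exposure, tr$mediator, tr$outcome))
    }
    purrr::map_dfr(grids, function(g) {
      xmy <- switch(g,
        direct = list(x = xa, m = mb, y = yc),
        reverse1 = list(x = xa, m = yc, y = mb),
        reverse2 = list(x = yc, m = mb, y = xa))
      sd_ <- derive_seed(seed, paste(tr$exposure, tr$mediator, tr$outcome, g))
      res <- tryCatch(
        mediate(xmy$x, xmy$m, xmy$y, n_boot = n_boot, seed = sd_),
        error = function(e) e)
      if (inherits(res, "error")) {
        tibble::tibble(exposure = tr$exposure, mediator = tr$mediator,
                       outcome = tr$outcome, grid = g,
                       acme = NA_real_, ade = NA_real_,
                       total_effect = NA_real_,
                       acme_ci_low = NA_real_, acme_ci_high = NA_real_,
                       p_acme = NA_real_, p_ade = NA_real_,
                       error = conditionMessage(res))
      } else {
        tibble::tibble(exposure = tr$exposure, mediator = tr$mediator,
                       outcome = tr$outcome, grid = g,
                       acme = res$acme, ade = res$ade,
                       total_effect = res$total_effect,
                       acme_ci_low = res$acme_ci[1],
                       acme_ci_high = res$acme_ci[2],
                       p_acme = res$p_acme, p_ade = res$p_ade,
                       error = NA_character_)
      }
    })
  })
  rows <- dplyr::group_by(rows, .data$grid)
  rows <- dplyr::mutate(rows, fdr_acme = bh_adjust(.data$p_acme))
  rows <- dplyr::ungroup(rows)
  rows$fdr_ade <- NA_real_
  r2 <- rows$grid == "reverse2"
  rows$fdr_ade[r2] <- bh_adjust(rows$p_ade[r2])
  class(rows) <- c("grid_records", class(rows))
  rows
}

#' Classify linkages from three-grid mediation evidence
#'
#' Applies the rule conjunctions, in order, to every triple's three grid
#' records (significance level `alpha = 0.05` throughout):
#'
#' * **microbiome->phenotype via metabolite**: `fdr_acme(direct) < alpha` and
#'   `p_acme(reverse1) > alpha` and `p_acme(reverse2) > alpha` and
#'   `p_ade(reverse2) > alpha` — a forward mediated path with no reverse
#'   mediation and no direct phenotype-to-bacteria effect.
#' * **microbiome->metabolome via phenotype**: `fdr_acme(reverse1) < alpha`
#'   and `p_acme(direct) > alpha` and `p_acme(reverse2) > alpha` and
#'   `p_ade(reverse2) > alpha`.
#' * **phenotype->microbiome** (`mediated` / `direct` / `combined` by which
#'   branch fires): `p_acme(direct) > alpha` and `p_acme(reverse1) > alpha`
#'   and (`fdr_acme(reverse2) < alpha` or `fdr_ade(reverse2) < alpha`).
#' * otherwise **none**.
#'
#' @param records a [run_grids()] tibble (all three grids per triple).
#' @param alpha decision level, default 0.05.
#' @return A tibble of class `linkage_table`: per triple, `linkage` class and
#'   `rule` (the conjunction that fired), joined to the three-grid evidence.
#' @export
classify_linkages <- function(records, alpha = 0.05) {
  need <- c("exposure", "mediator", "outcome", "grid", "p_acme", "p_ade",
            "fdr_acme", "fdr_ade")
  stopifnot(all(need %in% names(records)))
  wide <- tidyr::pivot_wider(
    dplyr::select(records, dplyr::all_of(need)),
    names_from = "grid",
    values_from = c("p_acme", "p_ade", "fdr_acme", "fdr_ade"))
  for (col in c("p_acme_direct", "p_acme_reverse1", "p_acme_reverse2",
                "p_ade_reverse2", "fdr_acme_direct", "fdr_acme_reverse1",
                "fdr_acme_reverse2", "fdr_ade_reverse2")) {
    if (!col %in% names(wide)) {
      abort(sprintf("missing grid evidence column '%s' (incomplete grids?)", col))
    }
  }
  if (anyNA(wide$p_acme_direct) || anyNA(wide$p_acme_reverse1) ||
      anyNA(wide$p_acme_reverse2)) {
    bad <- wide[is.na(wide$p_acme_direct) | is.na(wide$p_acme_reverse1) |
                  is.na(wide$p_acme_reverse2), ]
    abort(sprintf("missing grid record(s) for triple(s): %s",
                  paste(paste(bad$exposure, bad$mediator, bad$outcome, sep = "/"),
                        collapse = "; ")))
  }
  cls <- dplyr::mutate(wide,
    fwd = .data$fdr_acme_direct < alpha & .data$p_acme_reverse1 > alpha &
      .data$p_acme_reverse2 > alpha & .data$p_ade_reverse2 > alpha,
    rev1 = .data$fdr_acme_reverse1 < alpha & .data$p_acme_direct > alpha &
      .data$p_acme_reverse2 > alpha & .data$p_ade_reverse2 > alpha,
    rev2_med = .data$fdr_acme_reverse2 < alpha,
    rev2_dir = .data$fdr_ade_reverse2 < alpha,
    rev2 = .data$p_acme_direct > alpha & .data$p_acme_reverse1 > alpha &
      (.data$rev2_med | .data$rev2_dir),
    linkage = dplyr::case_when(
      fwd ~ "microbiome->phenotype via metabolite",
      rev1 ~ "microbiome->metabolome via phenotype",
      rev2 & rev2_med & rev2_dir ~ "phenotype->microbiome combined",
      rev2 & rev2_med ~ "phenotype->microbiome mediated",
      rev2 & rev2_dir ~ "phenotype->microbiome direct",
      TRUE ~ "none"),
    rule = dplyr::case_when(
      fwd ~ "fdr_acme(direct)<a & p_acme(rev1)>a & p_acme(rev2)>a & p_ade(rev2)>a",
      rev1 ~ "fdr_acme(rev1)<a & p_acme(direct)>a & p_acme(rev2)>a & p_ade(rev2)>a",
      rev2 ~ "p_acme(direct)>a & p_acme(rev1)>a & (fdr_acme(rev2)<a | fdr_ade(rev2)<a)",
      TRUE ~ "none fired"))
  out <- dplyr::select(cls, "exposure", "mediator", "outcome", "linkage",
                       "rule", dplyr::starts_with("p_"),
                       dplyr::starts_with("fdr_"))
  class(out) <- c("linkage_table", class(out))
  out
}
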