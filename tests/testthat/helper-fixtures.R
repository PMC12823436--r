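# shared fixture builders (everything generated in code; no stored data)

make_layer <- function(values, layer_name = "test", state = "raw",
                       ids = NULL, feats = NULL) {
  values <- as.matrix(values)
  rownames(values) <- ids %||% sprintf("s%02d", seq_len(nrow(values)))
  colnames(values) <- feats %||% sprintf("f%02d", seq_len(ncol(values)))
  omics_layer(values, layer_name, state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort with prescribed sex-by-WHO-class stratum sizes (named
# female.normal, male.obesity, ...); BMI drawn in-band, deterministic
make_strata_cohort <- function(sizes, n_underweight = 0, seed = 1) {
  set.seed(seed)
  rows <- purrr::imap_dfr(sizes, function(k, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    rng <- switch(parts[2], normal = c(19, 24.9), overweight = c(25, 29.9),
                  obesity = c(30, 40))
    tibble::tibble(sex = as.integer(parts[1] == "male"),
                   bmi = runif(k, rng[1], rng[2]))
  })
  if (n_underweight > 0) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      sex = rep_len(0:1, n_underweight), bmi = runif(n_underweight, 18, 18.4)))
  }
  rows$sample_id <- sprintf("p%04d", seq_len(nrow(rows)))
  rows$age <- runif(nrow(rows), 50, 65)
  dplyr::relocate(rows, sample_id)
}

# aligned feature sets with planted forward mediation triples:
# A_k -> B_k -> C_k with coefficients a, b, c_prime; extra null features padded
make_grid_sets <- function(n, n_triples, a = 0.5, b = 0.5, c_prime = 0,
                           noise_sd = 1, seed = 1, reverse = FALSE) {
  set.seed(seed)
  A <- matrix(rnorm(n * n_triples), n)
  if (reverse) {
    # generative order phenotype -> metabolite -> microbiome
    C <- matrix(rnorm(n * n_triples), n)
    B <- a * C + matrix(rnorm(n * n_triples, 0, noise_sd), n)
    A <- b * B + c_prime * C + matrix(rnorm(n * n_triples, 0, noise_sd), n)
  } else {
    B <- a * A + matrix(rnorm(n * n_triples, 0, noise_sd), n)
    C <- b * B + c_prime * A + matrix(rnorm(n * n_triples, 0, noise_sd), n)
  }
  colnames(A) <- paste0("sp_", seq_len(n_triples))
  colnames(B) <- paste0("met_", seq_len(n_triples))
  colnames(C) <- paste0("ph_", seq_len(n_triples))
  triples <- tibble::tibble(exposure = colnames(A), mediator = colnames(B),
                            outcome = colnames(C))
  list(a = tibble::as_tibble(A), b = tibble::as_tibble(B),
       c = tibble::as_tibble(C), triples = triples)
}

# fully null sets: independent Gaussians, k features per set
make_null_sets <- function(n, k, seed = 1) {
  set.seed(seed)
  mk <- function(prefix) {
    X <- matrix(rnorm(n * k), n)
    colnames(X) <- paste0(prefix, seq_len(k))
    tibble::as_tibble(X)
  }
  list(a = mk("sp_"), b = mk("met_"), c = mk("ph_"))
}

# hand-built three-grid evidence table for linkage-rule tests
make_evidence <- function(p_acme_direct = 1, p_acme_reverse1 = 1,
                          p_acme_reverse2 = 1, p_ade_reverse2 = 1,
                          fdr_acme_direct = p_acme_direct,
                          fdr_acme_reverse1 = p_acme_reverse1,
                          fdr_acme_reverse2 = p_acme_reverse2,
                          fdr_ade_reverse2 = p_ade_reverse2) {
  grids <- c("direct", "reverse1", "reverse2")
  tibble::tibble(
    exposure = "sp_1", mediator = "met_1", outcome = "ph_1", grid = grids,
    acme = 0.1, ade = 0.1, total_effect = 0.2,
    acme_ci_low = 0, acme_ci_high = 0.2,
    p_acme = c(p_acme_direct, p_acme_reverse1, p_acme_reverse2),
    p_ade = c(1, 1, p_ade_reverse2),
    fdr_acme = c(fdr_acme_direct, fdr_acme_reverse1, fdr_acme_reverse2),
    fdr_ade = c(NA, NA, fdr_ade_reverse2),
    error = NA_character_)
}
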