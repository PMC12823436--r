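#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defines the study conditions the generator emulates: a middle-aged cohort
#' (ages 50-65, both sexes, BMI 18-46 kg m^-2) whose circulating metabolome
#' carries a controllable fraction of BMI variance, a zero-inflated
#' compositional gut microbiome, gut metabolic module and proteome layers,
#' binary cardiometabolic outcomes generated from a logistic model, and
#' optional planted exposure-mediator-outcome triples with known path
#' coefficients. All randomness derives from `seed`.
#'
#' @param n_samples number of participants (default 1408).
#' @param n_metabolites,n_species,n_modules,n_proteins feature counts per layer.
#' @param bmi_r2_from_metabolome population fraction of BMI variance carried
#'   by the informative metabolites, in `[0, 1)` (default 0.39, the hold-out
#'   performance regime of metabolome BMI models in cohorts of this size).
#' @param n_informative_metabolites number of metabolites carrying BMI signal.
#' @param mediation_triples list of [planted_triple()] objects.
#' @param outcome_specs tibble with columns `name`, `intercept`,
#'   `log_or_bmi`, `log_or_resid`: per-outcome logistic intercept and per-SD
#'   log-odds for BMI and for the metabolic-deviation score.
#' @param species_prevalence_range per-species presence probability range.
#' @param sequencing_depth_range per-sample total-count range for the species
#'   layer.
#' @param bmi_mean,bmi_sd population mean and SD of BMI (kg m^-2).
#' @param seed integer seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 1408,
                             n_metabolites = 300,
                             n_species = 150,
                             n_modules = 50,
                             n_proteins = 100,
                             bmi_r2_from_metabolome = 0.39,
                             n_informative_metabolites = 20,
                             mediation_triples = list(),
                             outcome_specs = default_outcome_specs(),
                             species_prevalence_range = c(0.10, 0.90),
                             sequencing_depth_range = c(20000, 100000),
                             bmi_mean = 27,
                             bmi_sd = 4.1,
                             seed = 1) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_metabolites = check_count(n_metabolites, "n_metabolites"),
    n_species = check_count(n_species, "n_species"),
    n_modules = check_count(n_modules, "n_modules"),
    n_proteins = check_count(n_proteins, "n_proteins"),
    bmi_r2_from_metabolome =
      check_fraction(bmi_r2_from_metabolome, "bmi_r2_from_metabolome",
                     hi_open = TRUE),
    n_informative_metabolites =
      check_count(n_informative_metabolites, "n_informative_metabolites"),
    mediation_triples = mediation_triples,
    outcome_specs = tibble::as_tibble(outcome_specs),
    species_prevalence_range = species_prevalence_range,
    sequencing_depth_range = sequencing_depth_range,
    bmi_mean = bmi_mean,
    bmi_sd = bmi_sd,
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_informative_metabolites > cfg$n_metabolites) {
    abort("n_informative_metabolites cannot exceed n_metabolites")
  }
  pr <- cfg$species_prevalence_range
  if (length(pr) != 2 || any(pr <= 0) || any(pr > 1) || pr[1] > pr[2]) {
    abort("species_prevalence_range must be an increasing pair within (0, 1]")
  }
  dr <- cfg$sequencing_depth_range
  if (length(dr) != 2 || any(dr < 1) || dr[1] > dr[2]) {
    abort("sequencing_depth_range must be an increasing pair of counts >= 1")
  }
  need <- c("name", "intercept", "log_or_bmi", "log_or_resid")
  if (!all(need %in% names(cfg$outcome_specs))) {
    abort(sprintf("outcome_specs needs columns: %s", paste(need, collapse = ", ")))
  }
  for (tr in cfg$mediation_triples) {
    if (!inherits(tr, "planted_triple")) abort("mediation_triples must be planted_triple objects")
  }
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
default_outcome_specs <- function() {
  tibble::tribble(
    ~name,                 ~intercept, ~log_or_bmi, ~log_or_resid,
    "type2diabetes",       -2.2,        0.60,        0.40,
    "hypertension",        -0.8,        0.50,        0.25
  )
}

#' A planted exposure-mediator-outcome triple
#'
#' Encodes one ground-truth mediation pathway: the mediator is regenerated as
#' `a * exposure + noise` and the outcome as
#' `b * mediator + c_prime * exposure + noise`, so the implied indirect
#' effect (ACME) is `a * b` and the implied total effect `a * b + c_prime`.
#'
#' @param exposure_id feature id in a microbiome layer (species or module).
#' @param mediator_id metabolite feature id.
#' @param outcome_id phenotype column name in the cohort table.
#' @param a,b,c_prime path coefficients.
#' @param noise_sd_m,noise_sd_y positive noise SDs for mediator and outcome.
#' @return A list of class `planted_triple`.
#' @export
planted_triple <- function(exposure_id, mediator_id, outcome_id,
                           a, b, c_prime = 0,
                           noise_sd_m = 1, noise_sd_y = 1) {
  if (noise_sd_m <= 0 || noise_sd_y <= 0) abort("noise SDs must be > 0")
  structure(list(exposure_id = exposure_id, mediator_id = mediator_id,
                 outcome_id = outcome_id, a = a, b = b, c_prime = c_prime,
                 noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y),
            class = "planted_triple")
}

# shifted lognormal noise with mean 0 and the requested variance (tau fixed);
# gives BMI its right-skewed marginal while keeping an exact linear-plus-noise
# decomposition
skewed_noise <- function(n, variance, tau = 0.4) {
  if (variance <= 0) return(rep(0, n))
  nu <- (log(variance / (exp(tau^2) - 1)) - tau^2) / 2
  rlnorm(n, nu, tau) - exp(nu + tau^2 / 2)
}

#' Generate a synthetic multi-omics cohort
#'
#' Produces the four omics layers, the cohort phenotype table and a ground
#' truth record. The metabolome follows a latent-factor model; BMI is a
#' linear combination of the informative metabolites plus independent skewed
#' noise scaled so that the population R^2 of BMI on those metabolites equals
#' `bmi_r2_from_metabolome` exactly; species counts are zero-inflated
#' compositions drawn multinomially at a random depth; binary outcomes come
#' from a logistic model on standardized BMI and the metabolic-deviation
#' score (the metabolome-driven BMI component orthogonal to BMI itself).
#' Identical `(config, seed)` give byte-identical output.
#'
#' @param config a [generator_config()].
#' @return List with `layers` (named list of [omics_layer()]: `metabolome`,
#'   `species_counts`, `modules`, `proteome`), `cohort` (tibble) and `truth`
#'   (list; never consumed by inference stages).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  sex <- sample(rep_len(c(0L, 1L), n))
  age <- runif(n, 50, 65)

  # --- metabolome: latent factors + uniqueness, log-scale intensities
  k_extra <- 3L
  p <- cfg$n_metabolites
  p_inf <- cfg$n_informative_metabolites
  met_ids <- sprintf("metab_%03d", seq_len(p))
  inf_ids <- met_ids[seq_len(p_inf)]
  z1 <- rnorm(n)                      # BMI-linked factor
  Zx <- matrix(rnorm(n * k_extra), n) # nuisance factors
  load_inf <- runif(p_inf, 0.6, 1.0)
  psi_inf <- rep(0.6, p_inf)
  M <- matrix(0, n, p, dimnames = list(ids, met_ids))
  M[, seq_len(p_inf)] <- outer(z1, load_inf) +
    matrix(rnorm(n * p_inf), n) * rep(psi_inf, each = n)
  if (p > p_inf) {
    idx <- (p_inf + 1L):p
    load_x <- matrix(runif(length(idx) * k_extra, 0, 0.5), ncol = k_extra)
    M[, idx] <- Zx %*% t(load_x) + matrix(rnorm(n * length(idx)), n)
  }

  # --- BMI: linear in the informative metabolites, exact population R^2
  w <- runif(p_inf, 0.5, 1.0)
  var_signal_pop <- sum(load_inf * w)^2 + sum((w * psi_inf)^2)
  r2 <- cfg$bmi_r2_from_metabolome
  sigma2 <- cfg$bmi_sd^2
  noise_var <- (1 - r2) * sigma2
  if (noise_var <= 0) {
    abort(sprintf("implied BMI noise variance %.3g is not positive (bmi_r2_from_metabolome = %s, bmi_sd = %s)",
                  noise_var, r2, cfg$bmi_sd))
  }
  if (r2 > 0) {
    kappa <- sqrt(r2 * sigma2 / var_signal_pop)
    beta <- kappa * w
    signal <- drop(M[, seq_len(p_inf), drop = FALSE] %*% beta)
  } else {
    beta <- rep(0, p_inf)
    signal <- rep(0, n)
  }
  bmi <- cfg$bmi_mean + signal + skewed_noise(n, noise_var)
  bmi <- pmin(pmax(bmi, 18), 46)

  # metabolic deviation: metabolome-driven component orthogonal to BMI
  z_bmi <- (bmi - cfg$bmi_mean) / cfg$bmi_sd
  if (r2 > 0) {
    dev <- signal - r2 * (bmi - cfg$bmi_mean)
    z_dev <- dev / sqrt(r2 * sigma2 * (1 - r2))
  } else {
    z_dev <- rep(0, n)
  }

  # --- adiposity / clinical phenotypes tracking BMI
  whr <- 0.90 + 0.05 * z_bmi + rnorm(n, 0, 0.05)
  vat_attenuation <- -85 - 5 * z_bmi + rnorm(n, 0, 5)
  sat_attenuation <- -100 - 4 * z_bmi + rnorm(n, 0, 6)
  homa_ir <- exp(0.6 + 0.35 * z_bmi + 0.15 * z_dev + rnorm(n, 0, 0.4))
  homa_b <- exp(4.6 + 0.10 * z_bmi + 0.10 * z_dev + rnorm(n, 0, 0.3))
  gene_richness <- round(2e5 * exp(-0.10 * z_bmi + rnorm(n, 0, 0.15)))

  # --- binary outcomes from the stated logistic model
  outcomes <- purrr::pmap(cfg$outcome_specs, function(name, intercept,
                                                      log_or_bmi, log_or_resid) {
    eta <- intercept + log_or_bmi * z_bmi + log_or_resid * z_dev
    rbinom(n, 1, 1 / (1 + exp(-eta)))
  })
  names(outcomes) <- cfg$outcome_specs$name

  cohort <- tibble::tibble(sample_id = ids, age = age, sex = sex, bmi = bmi,
                           whr = whr, vat_attenuation = vat_attenuation,
                           sat_attenuation = sat_attenuation,
                           homa_ir = homa_ir, homa_b = homa_b,
                           gene_richness = gene_richness)
  for (nm in names(outcomes)) cohort[[nm]] <- outcomes[[nm]]

  # --- species: zero-inflated composition, multinomial at random depth
  ns <- cfg$n_species
  sp_ids <- sprintf("species_%03d", seq_len(ns))
  prev <- runif(ns, cfg$species_prevalence_range[1], cfg$species_prevalence_range[2])
  mu_sp <- rnorm(ns, 0, 1.5)
  latent <- matrix(rnorm(n * ns, rep(mu_sp, each = n), 1), n)
  present <- matrix(rbinom(n * ns, 1, rep(prev, each = n)), n)
  intensity <- exp(latent) * present
  zero_rows <- rowSums(intensity) == 0
  if (any(zero_rows)) {
    j <- which.max(prev)
    intensity[zero_rows, j] <- exp(mu_sp[j])
  }
  depth <- round(runif(n, cfg$sequencing_depth_range[1], cfg$sequencing_depth_range[2]))
  counts <- t(vapply(seq_len(n), function(i) {
    drop(rmultinom(1, depth[i], intensity[i, ] / sum(intensity[i, ])))
  }, numeric(ns)))
  dimnames(counts) <- list(ids, sp_ids)

  # --- gut metabolic modules and proteome
  nm_ <- cfg$n_modules
  mod_ids <- sprintf("module_%03d", seq_len(nm_))
  modules <- exp(matrix(rnorm(n * nm_, 0, 1), n, dimnames = list(ids, mod_ids)))
  np <- cfg$n_proteins
  prot_ids <- sprintf("protein_%03d", seq_len(np))
  prot_load <- matrix(runif(np * k_extra, 0, 0.6), ncol = k_extra)
  proteome <- Zx %*% t(prot_load) + matrix(rnorm(n * np), n)
  dimnames(proteome) <- list(ids, prot_ids)

  layers <- list(
    metabolome = omics_layer(M, "metabolome", "log"),
    species_counts = omics_layer(counts, "species_counts", "counts"),
    modules = omics_layer(modules, "modules", "raw"),
    proteome = omics_layer(proteome, "proteome", "log")
  )

  truth <- list(
    requested_bmi_r2 = r2,
    population_bmi_r2 = r2,
    informative_metabolites = inf_ids,
    bmi_effect_vector = setNames(beta, inf_ids),
    metabolite_loadings = setNames(load_inf, inf_ids),
    outcome_log_odds = cfg$outcome_specs,
    planted_triples = list(),
    bmi_mean = cfg$bmi_mean, bmi_sd = cfg$bmi_sd,
    seed = cfg$seed
  )

  out <- list(layers = layers, cohort = cohort, truth = truth)
  if (length(cfg$mediation_triples)) {
    out <- plant_mediation_paths(out$layers, out$cohort, cfg$mediation_triples,
                                 seed = derive_seed(cfg$seed, "plant"),
                                 truth = out$truth)
  }
  out
}

#' Plant ground-truth mediation paths into generated data
#'
#' For each triple, regenerates the mediator column as
#' `a * exposure + N(0, noise_sd_m)` and the outcome column as
#' `b * mediator + c_prime * exposure + N(0, noise_sd_y)`. Exposure values
#' are used exactly as stored in their layer (transform first if a CLR-scale
#' exposure is intended). Two triples sharing a mediator with different
#' generative rules conflict and raise an error.
#'
#' @param layers named list of [omics_layer()] objects.
#' @param cohort cohort tibble (outcome columns are created when absent).
#' @param triples list of [planted_triple()].
#' @param seed integer seed.
#' @param truth optional truth list to update.
#' @return List with updated `layers`, `cohort` and `truth`.
#' @export
plant_mediation_paths <- function(layers, cohort, triples, seed, truth = list()) {
  med_ids <- vapply(triples, `[[`, character(1), "mediator_id")
  if (anyDuplicated(med_ids)) {
    key <- vapply(triples, function(tr) {
      paste(tr$mediator_id, tr$exposure_id, tr$a, tr$noise_sd_m)
    }, character(1))
    dup <- med_ids[duplicated(med_ids)]
    for (d in dup) {
      if (length(unique(key[med_ids == d])) > 1) {
        abort(sprintf("conflicting triples share mediator '%s' with different rules", d))
      }
    }
  }
  with_seed(seed, {
    for (tr in triples) {
      x <- resolve_feature(layers, tr$exposure_id)
      lyr <- find_layer(layers, tr$mediator_id)
      if (is.na(lyr)) abort(sprintf("mediator '%s' not found in any layer", tr$mediator_id))
      n <- nrow(cohort)
      m <- tr$a * x + rnorm(n, 0, tr$noise_sd_m)
      layers[[lyr]][[tr$mediator_id]] <- m
      y <- tr$b * m + tr$c_prime * x + rnorm(n, 0, tr$noise_sd_y)
      cohort[[tr$outcome_id]] <- y
    }
    truth$planted_triples <- c(truth$planted_triples %||% list(),
                               lapply(triples, unclass))
    list(layers = layers, cohort = cohort, truth = truth)
  })
}

find_layer <- function(layers, feature_id) {
  hit <- names(layers)[vapply(layers, function(l) feature_id %in% names(l),
                              logical(1))]
  if (length(hit) == 0) return(NA_character_)
  if (length(hit) > 1) {
    abort(sprintf("feature '%s' appears in multiple layers: %s", feature_id,
                  paste(hit, collapse = ", ")))
  }
  hit
}

resolve_feature <- function(layers, feature_id) {
  lyr <- find_layer(layers, feature_id)
  if (is.na(lyr)) abort(sprintf("feature '%s' not found in any layer", feature_id))
  layers[[lyr]][[feature_id]]
}

#' Simulate one mediation triple as a plain tibble
#'
#' Small fixture generator: `x ~ N(0, 1)`, `m = a x + N(0, noise_sd_m)`,
#' `y = b m + c_prime x + N(0, noise_sd_y)`. Setting a noise SD to 0 gives
#' the noiseless deterministic system.
#'
#' @inheritParams planted_triple
#' @param n sample size.
#' @param seed integer seed.
#' @return Tibble with columns `x`, `m`, `y`.
#' @export
simulate_triple_system <- function(n, a, b, c_prime = 0,
                                   noise_sd_m = 1, noise_sd_y = 1, seed = 1) {
  with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + if (noise_sd_m > 0) rnorm(n, 0, noise_sd_m) else 0
    y <- b * m + c_prime * x + if (noise_sd_y > 0) rnorm(n, 0, noise_sd_y) else 0
    tibble::tibble(x = x, m = m, y = y)
  })
}

#' Generate a synthetic gene count table
#'
#' Per-sample sequencing depth is drawn uniformly from `depth_range`; reads
#' are spread over genes multinomially with lognormal gene weights. Used as
#' the fixture source for rarefaction-based gene richness.
#'
#' @param n_samples,n_genes table dimensions.
#' @param depth_range pair of total-read bounds (>= 1).
#' @param seed integer seed.
#' @return An [omics_layer()] of counts (`gene_*` columns).
#' @export
generate_gene_count_table <- function(n_samples, n_genes, depth_range, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  if (length(depth_range) != 2 || any(depth_range < 1) ||
      depth_range[1] > depth_range[2]) {
    abort("depth_range must be an increasing pair of counts >= 1")
  }
  with_seed(seed, {
    wt <- rlnorm(n_genes, 0, 1)
    depth <- round(runif(n_samples, depth_range[1], depth_range[2]))
    X <- matrix(unlist(lapply(seq_len(n_samples), function(i) {
      drop(rmultinom(1, depth[i], wt / sum(wt)))
    })), nrow = n_samples, byrow = TRUE)
    dimnames(X) <- list(sprintf("S%04d", seq_len(n_samples)),
                        sprintf("gene_%04d", seq_len(n_genes)))
    omics_layer(X, "gene_counts", "counts")
  })
}

#' Oracle BMI R-squared on an oversized sample
#'
#' Regenerates the metabolome/BMI system of a configuration at a large
#' independent sample size and measures the R^2 of ordinary least squares of
#' BMI on all metabolites — the direct check that the generator achieves the
#' requested population variance explained.
#'
#' @param config a [generator_config()].
#' @param n_oracle oracle sample size (default 100000).
#' @param seed seed for the oracle draw (independent of `config$seed`).
#' @return Single numeric R^2.
#' @export
oracle_bmi_r2 <- function(config, n_oracle = 100000, seed = 999) {
  cfg <- config
  cfg$n_samples <- check_count(n_oracle, "n_oracle")
  # only the metabolome/BMI subsystem matters: shrink the other layers
  cfg$n_species <- 2L; cfg$n_modules <- 2L; cfg$n_proteins <- 2L
  cfg$sequencing_depth_range <- c(100, 100)
  cfg$mediation_triples <- list()
  cfg$seed <- check_count(seed, "seed", min = 0)
  sim <- generate_cohort(cfg)
  X <- layer_values(sim$layers$metabolome)
  fit <- lm.fit(cbind(1, X), sim$cohort$bmi)
  1 - sum(fit$residuals^2) / sum((sim$cohort$bmi - mean(sim$cohort$bmi))^2)
}

#' Serialize / read the ground-truth record
#'
#' The truth file lives alongside the cohort tables but is never consumed by
#' inference stages; it exists so tests can compare recovered quantities with
#' planted ones.
#'
#' @param truth truth list from [generate_cohort()].
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
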