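#' Validate and normalise a pipeline configuration
#'
#' Fills defaults (every analysis threshold defaults to its standard value:
#' prevalence 0.05, |rho| 0.1, q 0.05, residual cuts -2.5/+2.5 kg m^-2,
#' 1000 mediation bootstrap draws, 999 shadow runs, 10 stability resamples,
#' 10/10 nested CV folds, train fraction 0.75, penalty grid length 100),
#' rejects unknown keys and contradictory stage toggles, and checks units
#' and ranges.
#'
#' @param config named list of overrides (may be empty).
#' @return The normalised config (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    seed = 1,
    generator = list(n_samples = 800, n_metabolites = 300, n_species = 150),
    stages = list(preprocess = TRUE, variance_explained = TRUE,
                  metbmi = TRUE, risk = TRUE, panel = TRUE,
                  prefilter = TRUE, mediation = TRUE),
    prevalence = 0.05,
    rho_threshold = 0.1,
    q_threshold = 0.05,
    residual_low = -2.5,
    residual_high = 2.5,
    n_boot = 1000,
    shadow_runs = 999,
    shadow_trees = 150,
    stability_resamples = 10,
    k_outer = 10,
    k_inner = 10,
    train_fraction = 0.75,
    grid_length = 100,
    richness_depth = 22e6,
    mediation_max_features = 12,
    outcomes = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  errors <- character()
  if (cfg$n_boot < 1) errors <- c(errors, "n_boot must be positive")
  if (cfg$residual_low >= cfg$residual_high) {
    errors <- c(errors, "residual_low must be below residual_high (kg m^-2)")
  }
  if (cfg$prevalence < 0 || cfg$prevalence > 1) {
    errors <- c(errors, "prevalence must lie in [0, 1]")
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    errors <- c(errors, "train_fraction must lie in (0, 1)")
  }
  if (isTRUE(cfg$stages$mediation) && !isTRUE(cfg$stages$prefilter)) {
    errors <- c(errors, "mediation requires the prefilter stage")
  }
  if (length(errors)) abort(paste(errors, collapse = "; "))
  structure(cfg, class = "run_config")
}

log_stage <- function(manifest, stage, event, ...) {
  counts <- list(...)
  message(sprintf("[%s] %s%s", stage, event,
                  if (length(counts)) paste0(" (", paste(names(counts), unlist(counts),
                                                         sep = "=", collapse = ", "), ")")
                  else ""))
  manifest$stages[[stage]] <- c(manifest$stages[[stage]],
                                list(c(list(event = event), counts)))
  manifest
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort from the configured generator, then runs the stages in
#' order: preprocess (prevalence filter, TSS, multiplicative zero
#' replacement, CLR), variance explained (nested-CV ridge of BMI on each
#' layer), metBMI (pre-filter, balanced strata, split, ridge fit, prediction,
#' residual classification), risk (three logistic models + LRT per outcome),
#' panel (shadow + stability selection and panel refit) and mediation
#' (pre-filter, three grids, linkage classification). Each stage's outputs
#' feed the next; all tables are written as TSV under `out_dir`, records as
#' JSON, and a run manifest (config snapshot, per-stage events and counts,
#' seed ledger, package version) is written last.
#'
#' @param config a [validate_config()] config (or a plain list of overrides).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("metbmi_run_")) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("metbmi")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seeds = list(master = config$seed),
                   stages = list())
  results <- list()
  seed_of <- function(stage) derive_seed(config$seed, stage)

  # --- simulate
  gen_args <- utils::modifyList(config$generator,
                                list(seed = seed_of("simulate")))
  gcfg <- do.call(generator_config, gen_args)
  sim <- generate_cohort(gcfg)
  manifest <- log_stage(manifest, "simulate", "cohort generated",
                        n = nrow(sim$cohort),
                        metabolites = ncol(sim$layers$metabolome) - 1L)
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_truth(sim$truth, file.path(truth_dir, "truth.json"))
  for (nm in names(sim$layers)) {
    write_layer(sim$layers[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  readr::write_tsv(sim$cohort, file.path(out_dir, "cohort.tsv"))
  results$simulate <- sim

  layers <- sim$layers
  cohort <- sim$cohort

  # --- preprocess
  species_clr <- NULL
  if (isTRUE(config$stages$preprocess)) {
    sp <- prevalence_filter(layers$species_counts, config$prevalence)
    species_clr <- clr_transform(multiplicative_zero_replacement(tss_normalize(sp)))
    write_layer(species_clr, file.path(out_dir, "species_clr.tsv"))
    manifest <- log_stage(manifest, "preprocess", "species filtered + CLR",
                          kept = ncol(species_clr) - 1L,
                          removed = ncol(layers$species_counts) - ncol(species_clr))
    results$preprocess <- species_clr
  }

  # --- variance explained
  if (isTRUE(config$stages$variance_explained)) {
    ve_layers <- list(metabolome = layers$metabolome)
    if (!is.null(species_clr)) ve_layers$species <- species_clr
    ve <- purrr::map(ve_layers, function(l) {
      nested_cv_r2(cohort, "bmi", l, penalty_kind = "ridge",
                   k_outer = config$k_outer, k_inner = config$k_inner,
                   seed = seed_of("variance_explained"))
    })
    ve_tbl <- purrr::map_dfr(ve, glance)
    readr::write_tsv(ve_tbl, file.path(out_dir, "variance_explained.tsv"))
    manifest <- log_stage(manifest, "variance_explained", "layers scored",
                          layers = length(ve))
    results$variance_explained <- ve
  }

  # --- metBMI
  classification <- NULL
  model <- NULL
  if (isTRUE(config$stages$metbmi)) {
    pre <- select_bmi_metabolites(layers$metabolome, cohort,
                                  config$rho_threshold, config$q_threshold)
    strata <- balanced_strata_sample(cohort, seed = seed_of("strata"))
    split <- split_train_test(strata$pool, cohort, config$train_fraction,
                              seed = seed_of("split"))
    model <- fit_metbmi(layers$metabolome, cohort, pre$metabolite, split,
                        penalty_kind = "ridge",
                        grid_length = config$grid_length,
                        seed = seed_of("metbmi_fit"))
    pred <- predict_metbmi(model, layers$metabolome)
    classification <- residualize_and_classify(pred, cohort,
                                               config$residual_low,
                                               config$residual_high)
    cohort <- dplyr::left_join(cohort, classification$samples, by = "sample_id")
    readr::write_tsv(cohort, file.path(out_dir, "cohort_classified.tsv"))
    jsonlite::write_json(tidy(model), file.path(out_dir, "metbmi_model.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- log_stage(manifest, "metbmi", "model fitted",
                          prefilter = nrow(pre), pool = nrow(strata$pool),
                          test_r2 = round(model$test_r2, 3))
    results$metbmi <- list(prefilter = pre, split = split, model = model,
                           classification = classification)
  }

  # --- risk models
  if (isTRUE(config$stages$risk)) {
    if (is.null(classification)) abort("risk stage needs the metbmi stage")
    outcomes <- config$outcomes %||%
      intersect(sim$truth$outcome_log_odds$name, names(cohort))
    risk <- purrr::map(setNames(outcomes, outcomes), function(oc) {
      fit_outcome_model_set(cohort, oc)
    })
    risk_tbl <- purrr::map_dfr(names(risk), function(oc) {
      purrr::map_dfr(c("bmi_only", "metbmi_only", "nested"), function(spec) {
        dplyr::mutate(risk[[oc]][[spec]]$estimates, outcome = oc,
                      model_spec = spec, .before = 1)
      })
    })
    readr::write_tsv(risk_tbl, file.path(out_dir, "risk_models.tsv"))
    manifest <- log_stage(manifest, "risk", "outcome models fitted",
                          outcomes = length(risk))
    results$risk <- risk
  }

  # --- panel selection
  if (isTRUE(config$stages$panel)) {
    if (is.null(model)) abort("panel stage needs the metbmi stage")
    Xp <- dplyr::select(tibble::as_tibble(as.data.frame(layers$metabolome)),
                        "sample_id", dplyr::all_of(model$prefilter_ids))
    part <- shadow_feature_selection(Xp, cohort$bmi,
                                     n_runs = config$shadow_runs,
                                     seed = seed_of("shadow"),
                                     num_trees = config$shadow_trees)
    freq <- iterative_sparse_stability(Xp, cohort$bmi,
                                       n_resamples = config$stability_resamples,
                                       seed = seed_of("stability"))
    panel <- assemble_panel(part, freq, layers$metabolome, cohort,
                            results$metbmi$split, seed = seed_of("panel_refit"))
    readr::write_tsv(panel$final_panel, file.path(out_dir, "panel.tsv"))
    jsonlite::write_json(list(panel_r2 = panel$panel_r2,
                              full_model_r2 = panel$full_model_r2),
                         file.path(out_dir, "panel_r2.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- log_stage(manifest, "panel", "panel assembled",
                          size = nrow(panel$final_panel))
    results$panel <- panel
  }

  # --- mediation
  if (isTRUE(config$stages$mediation)) {
    if (is.null(species_clr)) abort("mediation stage needs the preprocess stage")
    k <- config$mediation_max_features
    top_var <- function(d, k) {
      d <- strip_ids(d)
      v <- vapply(d, stats::var, numeric(1))
      d[order(-v)[seq_len(min(k, ncol(d)))]]
    }
    set_a <- top_var(species_clr, k)
    set_b <- top_var(layers$metabolome, k)
    pheno_cols <- intersect(c("whr", "vat_attenuation", "sat_attenuation",
                              "homa_ir", "homa_b", "residual"), names(cohort))
    set_c <- cohort[pheno_cols]
    pf <- prefilter_candidates(set_a, set_b, set_c,
                               rho_min = config$rho_threshold,
                               q_max = config$q_threshold)
    manifest <- log_stage(manifest, "prefilter", "candidates retained",
                          triples = nrow(pf$triples))
    records <- run_grids(pf$triples, set_a, set_b, set_c,
                         n_boot = config$n_boot, seed = seed_of("mediation"))
    linkages <- if (nrow(records)) classify_linkages(records) else records
    readr::write_tsv(records, file.path(out_dir, "grid_records.tsv"))
    readr::write_tsv(linkages, file.path(out_dir, "linkages.tsv"))
    manifest <- log_stage(manifest, "mediation", "grids evaluated",
                          records = nrow(records),
                          linkages = if (nrow(records))
                            sum(linkages$linkage != "none") else 0L)
    results$mediation <- list(prefilter = pf, records = records,
                              linkages = linkages)
  } else {
    manifest <- log_stage(manifest, "mediation", "skipped")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
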