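gen_small <- function(seed = 1, ...) {
  generate_cohort(generator_config(n_samples = 400, n_metabolites = 60,
                                   n_species = 20, n_modules = 5,
                                   n_proteins = 5,
                                   sequencing_depth_range = c(1000, 2000),
                                   seed = seed, ...))
}

test_that("BMI metabolite pre-filter keeps signal and rejects noise", {
  sim <- gen_small(seed = 2)
  met <- sim$layers$metabolome
  # a metabolite equal to BMI is retained with rho = 1
  met$metab_060 <- sim$cohort$bmi
  sel <- select_bmi_metabolites(met, sim$cohort)
  expect_true("metab_060" %in% sel$metabolite)
  expect_equal(sel$rho[sel$metabolite == "metab_060"], 1)
  # sorted by |rho| descending
  expect_identical(order(-abs(sel$rho)), seq_len(nrow(sel)))

  # independent metabolites at cohort scale are excluded
  sim14 <- generate_cohort(generator_config(
    n_samples = 1400, n_metabolites = 40, n_species = 5, n_modules = 2,
    n_proteins = 2, n_informative_metabolites = 20,
    sequencing_depth_range = c(500, 600), seed = 3))
  sel14 <- select_bmi_metabolites(sim14$layers$metabolome, sim14$cohort)
  noise_ids <- setdiff(sprintf("metab_%03d", 1:40),
                       sim14$truth$informative_metabolites)
  expect_lte(length(intersect(sel14$metabolite, noise_ids)), 2)
  # planted informative metabolites are recalled
  recall <- mean(sim14$truth$informative_metabolites %in% sel14$metabolite)
  expect_gte(recall, 0.95)

  const <- make_layer(matrix(rep(1, 400), 400), feats = "flat",
                      ids = sim$cohort$sample_id)
  expect_error(suppressWarnings(select_bmi_metabolites(const, sim$cohort)),
               "no metabolite")
})

test_that("balanced strata sampling draws 6x the smallest stratum", {
  co <- make_strata_cohort(c(female.normal = 200, female.overweight = 180,
                             female.obesity = 150, male.normal = 129,
                             male.overweight = 300, male.obesity = 140),
                           n_underweight = 7)
  bs <- balanced_strata_sample(co, seed = 1)
  expect_equal(nrow(bs$pool), 774)           # 6 * 129
  expect_equal(unname(bs$strata_counts["male.normal"]), 129L)
  expect_equal(length(bs$non_strata_ids), 7)
  expect_true(all(table(bs$pool$stratum) == 129))

  eq <- make_strata_cohort(setNames(rep(50, 6),
                                    names(bs$strata_counts)))
  expect_equal(nrow(balanced_strata_sample(eq, 1)$pool), 300)

  mixed <- make_strata_cohort(setNames(c(10, 20, 30, 40, 50, 60),
                                       names(bs$strata_counts)))
  expect_equal(nrow(balanced_strata_sample(mixed, 1)$pool), 60)

  no_ob <- make_strata_cohort(c(female.normal = 30, female.overweight = 30,
                                male.normal = 30, male.overweight = 30,
                                male.obesity = 30))
  expect_error(balanced_strata_sample(no_ob, 1), "female.obesity")
})

test_that("train/test split is stratified, disjoint and reproducible", {
  co <- make_strata_cohort(c(female.normal = 200, female.overweight = 180,
                             female.obesity = 150, male.normal = 129,
                             male.overweight = 300, male.obesity = 140),
                           n_underweight = 7)
  bs <- balanced_strata_sample(co, seed = 2)
  sp <- split_train_test(bs$pool, co, seed = 3)
  expect_lte(abs(length(sp$train_ids) - 0.75 * 774), 3)
  expect_equal(length(sp$train_ids) + length(sp$test_ids), 774)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(sp$extended_test_ids, c(sp$test_ids, sp$non_test_ids))
  expect_setequal(c(sp$train_ids, sp$extended_test_ids), co$sample_id)
  sp2 <- split_train_test(bs$pool, co, seed = 3)
  expect_identical(sort(sp$train_ids), sort(sp2$train_ids))
})

test_that("metBMI fit nails noiseless signal and rejects permuted labels", {
  set.seed(4)
  n <- 400
  X <- matrix(rnorm(n * 10), n, dimnames = list(sprintf("s%04d", 1:n),
                                                sprintf("metab_%02d", 1:10)))
  co <- tibble::tibble(sample_id = rownames(X),
                       age = runif(n, 50, 65),
                       sex = rep_len(0:1, n),
                       bmi = 27 + drop(X %*% runif(10, 0.3, 1)))
  co$bmi <- pmin(pmax(co$bmi, 18.6), 45)  # keep strata occupied
  lyr <- omics_layer(X, "metabolome", "log")
  bs <- balanced_strata_sample(co, 5)
  sp <- split_train_test(bs$pool, co, seed = 6)
  fit <- fit_metbmi(lyr, co, colnames(X), sp, seed = 7)
  expect_gte(fit$test_r2, 0.99)

  r2_perm <- purrr::map_dbl(1:5, function(s) {
    cop <- co
    set.seed(s); cop$bmi <- sample(cop$bmi)
    bsp <- balanced_strata_sample(cop, s)
    spp <- split_train_test(bsp$pool, cop, seed = s)
    fit_metbmi(lyr, cop, colnames(X), spp, seed = s)$test_r2
  })
  expect_lte(median(r2_perm), 0.05)
})

test_that("metBMI recovers the planted variance-explained regime", {
  # the test-set R^2 of a single draw scatters around the planted value with
  # SD ~0.05 (n_test ~ 190), so the regime is checked on the median of three
  # independent cohorts
  r2s <- purrr::map_dbl(c(8, 108, 208), function(s) {
    sim <- generate_cohort(generator_config(
      n_samples = 1400, n_metabolites = 100, n_species = 5, n_modules = 2,
      n_proteins = 2, bmi_r2_from_metabolome = 0.4,
      sequencing_depth_range = c(500, 600), seed = s))
    sel <- select_bmi_metabolites(sim$layers$metabolome, sim$cohort)
    bs <- balanced_strata_sample(sim$cohort, s + 1)
    sp <- split_train_test(bs$pool, sim$cohort, seed = s + 2)
    fit_metbmi(sim$layers$metabolome, sim$cohort, sel$metabolite, sp,
               seed = s + 3)$test_r2
  })
  expect_gte(median(r2s), 0.33)
  expect_lte(median(r2s), 0.47)
})

test_that("metBMI prediction is a deterministic centred linear score", {
  sim <- gen_small(seed = 12)
  sel <- select_bmi_metabolites(sim$layers$metabolome, sim$cohort)
  bs <- balanced_strata_sample(sim$cohort, 13)
  sp <- split_train_test(bs$pool, sim$cohort, seed = 14)
  fit <- fit_metbmi(sim$layers$metabolome, sim$cohort, sel$metabolite, sp,
                    seed = 15)
  p1 <- predict_metbmi(fit, sim$layers$metabolome)
  p2 <- predict_metbmi(fit, sim$layers$metabolome)
  expect_identical(p1, p2)

  # duplicated sample row gives an identical prediction
  dup <- sim$layers$metabolome[c(1, 1), ]
  dup$sample_id <- c("d1", "d2")
  pd <- predict_metbmi(fit, omics_layer(dup, "metabolome", "log"))
  expect_equal(pd$metbmi[1], pd$metbmi[2])

  # an all-training-mean profile scores exactly the centred intercept
  mean_prof <- matrix(fit$feature_means, 1,
                      dimnames = list("avg", names(fit$feature_means)))
  pm <- predict_metbmi(fit, omics_layer(mean_prof, "metabolome", "log"))
  expect_equal(pm$metbmi, unname(fit$intercept), tolerance = 1e-9)

  expect_error(predict_metbmi(fit, sim$layers$proteome), "missing required")
})

test_that("group labelling rules: strict cuts, WHO fallback, partition", {
  # boundary and override cases, straight from the rules
  expect_equal(classify_metbmi_groups(-3.0, 31), "LmetBMI")
  expect_equal(classify_metbmi_groups(0, 22), "normal weight")
  expect_equal(classify_metbmi_groups(2.5, 27), "overweight")   # boundary
  expect_equal(classify_metbmi_groups(-2.5, 31), "obesity")     # boundary
  expect_equal(classify_metbmi_groups(2.6, 22), "HmetBMI")
  expect_equal(who_bmi_class(c(18.2, 24.9, 25, 29.9, 30)),
               c("normal weight", "normal weight", "overweight",
                 "overweight", "obesity"))
})

test_that("residualization is orthogonal to its covariates and partitions", {
  sim <- gen_small(seed = 16)
  sel <- select_bmi_metabolites(sim$layers$metabolome, sim$cohort)
  bs <- balanced_strata_sample(sim$cohort, 17)
  sp <- split_train_test(bs$pool, sim$cohort, seed = 18)
  fit <- fit_metbmi(sim$layers$metabolome, sim$cohort, sel$metabolite, sp,
                    seed = 19)
  cls <- residualize_and_classify(predict_metbmi(fit, sim$layers$metabolome),
                                  sim$cohort)
  expect_lt(max(abs(cls$residual_covariate_cor)), 1e-8)
  expect_equal(sum(cls$group_sizes), nrow(sim$cohort))
  expect_setequal(unique(cls$samples$group),
                  names(cls$group_sizes)[cls$group_sizes > 0])
  # rule consistency on the realized residuals
  expect_identical(cls$samples$group,
                   classify_metbmi_groups(cls$samples$residual,
                                          sim$cohort$bmi[match(cls$samples$sample_id,
                                                               sim$cohort$sample_id)]))
  expect_error(residualize_and_classify(
    predict_metbmi(fit, sim$layers$metabolome),
    dplyr::mutate(sim$cohort, sex = 0, age = 5)), "rank-deficient")
})
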