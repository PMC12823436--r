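test_that("layer TSV round trip preserves values, order and ids", {
  lyr <- make_layer(matrix(c(1.25, -3.5, pi, exp(1), 0, 1e-12), nrow = 3),
                    layer_name = "demo", state = "raw")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer(lyr, path)
  back <- read_layer(path, layer_name = "demo")
  expect_identical(back$sample_id, lyr$sample_id)
  expect_equal(layer_values(back), layer_values(lyr), tolerance = 0)
})

test_that("malformed layer files fail naming the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_layer(path), "s1")

  writeLines(c("id\tmetab_5\tm2", "s1\t1\t2", "s2\toops\t4"), path)
  expect_error(read_layer(path), "row 2.*metab_5")

  expect_error(omics_layer(tibble::tibble(sample_id = "a", x = "text")),
               "not numeric")
  expect_error(make_layer(matrix(c(1.5, 2, 3, 4), 2), state = "counts"),
               "integral")
})

test_that("prevalence filter keeps the >= boundary and drops empty features", {
  X <- matrix(0, 100, 3)
  X[1:5, 1] <- 1          # exactly 5% prevalence
  X[1:4, 2] <- 1          # below threshold
  lyr <- make_layer(X, state = "counts")
  kept <- prevalence_filter(lyr, 0.05)
  expect_identical(setdiff(names(kept), "sample_id"), "f01")

  expect_warning(res <- prevalence_filter(make_layer(matrix(0, 4, 2),
                                                     state = "counts"), 0.5),
                 "every feature")
  expect_identical(ncol(res), 1L)
  # min_prevalence 0 is the identity
  ident <- prevalence_filter(lyr, 0)
  expect_identical(names(ident), names(lyr))
})

test_that("prevalence filters compose as the max of thresholds", {
  set.seed(42)
  X <- matrix(rbinom(50 * 20, 1, rep(runif(20, 0.01, 0.5), each = 50)), 50, 20)
  lyr <- make_layer(X, state = "counts")
  twice <- prevalence_filter(prevalence_filter(lyr, 0.10), 0.25)
  once <- prevalence_filter(lyr, 0.25)
  expect_identical(names(twice), names(once))
})

test_that("TSS produces proportions and rejects zero-sum samples", {
  lyr <- make_layer(matrix(c(1, 1, 2), 1), state = "counts")
  expect_equal(unname(layer_values(tss_normalize(lyr))[1, ]),
               c(0.25, 0.25, 0.5))
  zero <- make_layer(rbind(c(1, 1), c(0, 0)), state = "counts")
  expect_error(tss_normalize(zero), "s02")
})

test_that("multiplicative zero replacement matches the hand-worked rule", {
  lyr <- make_layer(matrix(c(0.5, 0.5, 0), 1), state = "proportions")
  out <- layer_values(multiplicative_zero_replacement(lyr))
  expect_equal(unname(out[1, ]), c(0.375, 0.375, 0.25))
  expect_equal(sum(out), 1, tolerance = 1e-12)

  nz <- make_layer(matrix(c(0.2, 0.3, 0.5), 1), state = "proportions")
  expect_equal(layer_values(multiplicative_zero_replacement(nz)),
               layer_values(nz))

  # scaled copies of a row give identical replaced rows after TSS
  counts <- make_layer(rbind(c(4, 2, 0, 6), c(8, 4, 0, 12)), state = "counts")
  rep2 <- layer_values(multiplicative_zero_replacement(tss_normalize(counts)))
  expect_equal(rep2[1, ], rep2[2, ], tolerance = 1e-12)

  allz <- make_layer(rbind(c(1, 0) / 1, c(0, 0)), state = "raw")
  expect_error(multiplicative_zero_replacement(
    make_layer(rbind(c(0.5, 0.5), c(0, 0)))), "sum to 1|all zero")
})

test_that("CLR has the closed form, scale invariance and zero row sums", {
  u <- make_layer(matrix(rep(0.25, 4), 1))
  expect_equal(unname(layer_values(clr_transform(u))[1, ]), rep(0, 4))

  r <- make_layer(matrix(c(1, 2, 4), 1))
  expect_equal(unname(layer_values(clr_transform(r))[1, ]),
               c(-log(2), 0, log(2)))
  r10 <- make_layer(matrix(10 * c(1, 2, 4), 1))
  expect_equal(layer_values(clr_transform(r10)), layer_values(clr_transform(r)))

  set.seed(7)
  big <- make_layer(matrix(rlnorm(200), 20))
  expect_true(all(abs(rowSums(layer_values(clr_transform(big)))) < 1e-9))
  expect_error(clr_transform(make_layer(matrix(c(1, 0), 1))), "zero_replacement")
})

test_that("near-zero-variance flags apply both criteria", {
  d <- tibble::tibble(
    const = rep(1, 100),
    unique_vals = seq_len(100) + 0,
    sparse = c(rep(0, 96), rep(1, 4)))
  fl <- near_zero_variance_flags(d)
  expect_true(fl$nzv[fl$feature == "const"])
  expect_false(fl$nzv[fl$feature == "unique_vals"])
  row <- fl[fl$feature == "sparse", ]
  expect_equal(row$freq_ratio, 24)
  expect_equal(row$unique_fraction, 0.02)
  expect_true(row$nzv)
})

test_that("normality gate leaves Gaussian data alone and fixes lognormal", {
  keep <- vapply(1:20, function(s) {
    set.seed(s)
    !normality_gated_log(rnorm(1000))$transformed
  }, logical(1))
  expect_gte(sum(keep), 18)  # >= 95% expected untouched under the null

  set.seed(1)
  ln <- normality_gated_log(rlnorm(1000))
  expect_true(ln$transformed)
  expect_gte(nortest::ad.test(ln$values)$p.value, 0.05)

  withz <- normality_gated_log(c(rlnorm(999), 0))
  expect_equal(withz$offset, 1)
  expect_true(all(is.finite(withz$values)))

  expect_false(normality_gated_log(rep(3, 10))$transformed)
  expect_error(normality_gated_log(c(1, 2, 3)), ">= 8")
})

test_that("rarefied richness honours exact and enumerable cases", {
  X <- rbind(a = c(10, 0, 0), b = c(5, 3, 2), c = c(1, 1, 1))
  colnames(X) <- paste0("g", 1:3)
  # full depth: richness = occupied genes, SD 0; shallow sample missing
  r <- rarefied_gene_richness(X, depth = 10, n_repeats = 5, seed = 1)
  expect_equal(r$richness[1], 1)
  expect_equal(r$richness_sd[1], 0)
  expect_equal(r$richness[2], 3)      # depth equals total for sample b
  expect_false(r$depth_ok[3])

  # single occupied gene: richness 1 at any viable depth
  r5 <- rarefied_gene_richness(X[1, , drop = FALSE], depth = 5,
                               n_repeats = 20, seed = 2)
  expect_equal(r5$richness, 1)

  # (1,1,1,1) at depth 2: every 2-subset has two distinct genes, so the
  # mean over repeats is exactly 2 (brute-force enumeration of all C(4,2)
  # subsets confirms richness 2 for each)
  subsets <- utils::combn(4, 2)
  expect_true(all(apply(subsets, 2, function(s) length(unique(s))) == 2))
  Y <- matrix(c(1, 1, 1, 1), 1, dimnames = list("s", paste0("g", 1:4)))
  r2 <- rarefied_gene_richness(Y, depth = 2, n_repeats = 50, seed = 3)
  expect_equal(r2$richness, 2)
  expect_equal(r2$richness_sd, 0)

  expect_error(rarefied_gene_richness(X, depth = 0), ">= 1")
})

test_that("expected rarefied richness is monotone in depth", {
  gc <- generate_gene_count_table(6, 40, c(500, 500), seed = 5)
  means <- vapply(c(50, 150, 400), function(d) {
    out <- purrr::map_dbl(1:20, function(s) {
      mean(rarefied_gene_richness(gc, d, n_repeats = 3, seed = s)$richness)
    })
    mean(out)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
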