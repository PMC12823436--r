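#' Construct an omics layer
#'
#' An omics layer is a tibble with the sample identifier in the first column
#' (`sample_id`) and one numeric column per feature, tagged with a layer name
#' and a transform state. The transform state records provenance:
#' `"counts"` (non-negative integers), `"proportions"` (rows sum to 1),
#' `"clr"` (centred log-ratio, rows sum to 0), `"log"` or `"raw"`.
#'
#' @param data data frame with a `sample_id` column and numeric feature
#'   columns, or a numeric matrix with rownames as sample ids.
#' @param layer_name single string naming the layer (e.g. `"metabolome"`).
#' @param transform_state one of `"counts"`, `"proportions"`, `"clr"`,
#'   `"log"`, `"raw"`.
#' @return A tibble of class `omics_layer` with attributes `layer_name` and
#'   `transform_state`.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' omics_layer(m, "demo", "counts")
#' @export
omics_layer <- function(data, layer_name,
                        transform_state = c("raw", "counts", "proportions",
                                            "clr", "log")) {
  transform_state <- match.arg(transform_state)
  if (is.matrix(data)) {
    ids <- rownames(data) %||% paste0("S", seq_len(nrow(data)))
    data <- tibble::as_tibble(data, .name_repair = "minimal")
    data <- dplyr::bind_cols(tibble::tibble(sample_id = ids), data)
  }
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    names(data)[1] <- "sample_id"
  }
  data$sample_id <- as.character(data$sample_id)
  feats <- setdiff(names(data), "sample_id")
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(sprintf("duplicate sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    abort(sprintf("duplicate feature id(s): %s", paste(dup, collapse = ", ")))
  }
  for (f in feats) {
    if (!is.numeric(data[[f]])) {
      abort(sprintf("feature column '%s' is not numeric", f))
    }
  }
  X <- layer_values(data)
  if (transform_state == "counts" &&
      (any(X < 0, na.rm = TRUE) ||
       any(abs(X - round(X)) > 1e-8, na.rm = TRUE))) {
    abort("transform_state 'counts' requires non-negative integral values")
  }
  if (transform_state == "clr" &&
      any(abs(rowSums(X)) > 1e-9)) {
    abort("transform_state 'clr' requires rows summing to 0 (within 1e-9)")
  }
  structure(data,
            class = c("omics_layer", class(tibble::tibble()))[
              !duplicated(c("omics_layer", class(tibble::tibble())))],
            layer_name = as.character(layer_name)[1],
            transform_state = transform_state)
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s'> %d samples x %d features, state = %s\n",
              attr(x, "layer_name"), nrow(x), ncol(x) - 1L,
              attr(x, "transform_state")))
  NextMethod()
}

#' Extract the numeric value matrix of a layer
#'
#' @param layer an [omics_layer()] (or any data frame with `sample_id` first).
#' @return Numeric matrix, samples as rows (rownames = sample ids).
#' @export
layer_values <- function(layer) {
  feats <- setdiff(names(layer), "sample_id")
  X <- as.matrix(as.data.frame(layer)[, feats, drop = FALSE])
  rownames(X) <- layer$sample_id
  X
}

#' @rdname omics_layer
#' @export
layer_state <- function(data) attr(data, "transform_state") %||% "raw"

retag <- function(layer, template, state = NULL) {
  omics_layer(layer,
              layer_name = attr(template, "layer_name") %||% "layer",
              transform_state = state %||% layer_state(template))
}

#' Read / write an omics layer as TSV
#'
#' Layers are stored as tab-separated tables with a header row and the sample
#' id in the first column. Reading validates rectangularity, numeric cells and
#' id uniqueness; the error message names the offending row and column.
#'
#' @param path file path.
#' @param layer_name layer name to tag the result with.
#' @param transform_state transform state to tag the result with.
#' @return `read_layer()` returns an [omics_layer()]; `write_layer()` returns
#'   `path` invisibly. A write/read round trip reproduces values to full
#'   precision and preserves sample order.
#' @export
read_layer <- function(path, layer_name = basename(path),
                       transform_state = "raw") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("layer file needs a sample-id column and >= 1 feature")
  names(raw)[1] <- "sample_id"
  out <- raw
  for (j in setdiff(names(raw), "sample_id")) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) &
                   !raw[[j]] %in% c("NA", "NaN", ""))
    if (length(bad)) {
      abort(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                    bad[1], j, raw[[j]][bad[1]]))
    }
    out[[j]] <- v
  }
  omics_layer(out, layer_name = layer_name, transform_state = transform_state)
}

#' @rdname read_layer
#' @param layer the layer to write.
#' @export
write_layer <- function(layer, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(layer)), path)
  invisible(path)
}

#' Filter features by prevalence
#'
#' Retains features observed (value > 0) in at least
#' `ceiling(min_prevalence * n_samples)` samples — the standard 5% prevalence
#' filter applied to species tables before compositional transforms. The
#' boundary is kept (a feature present in exactly 5% of samples survives the
#' default filter).
#'
#' @param layer an [omics_layer()] with non-negative values.
#' @param min_prevalence minimum fraction of samples, default 0.05.
#' @return The filtered layer; feature order preserved. An empty result
#'   triggers a warning, not an error.
#' @export
prevalence_filter <- function(layer, min_prevalence = 0.05) {
  check_fraction(min_prevalence, "min_prevalence")
  X <- layer_values(layer)
  if (any(X < 0, na.rm = TRUE)) abort("prevalence_filter() needs non-negative values")
  need <- ceiling(min_prevalence * nrow(X))
  keep <- colSums(X > 0, na.rm = TRUE) >= need
  if (!any(keep)) warn("prevalence filter removed every feature")
  out <- dplyr::select(tibble::as_tibble(as.data.frame(layer)),
                       "sample_id", dplyr::all_of(colnames(X)[keep]))
  retag(out, layer)
}

#' Total-sum scaling of a count layer
#'
#' Divides each sample's counts by its total, producing relative abundances
#' (proportions summing to 1 per sample).
#'
#' @param layer an [omics_layer()] of non-negative values with positive row sums.
#' @return An [omics_layer()] with `transform_state = "proportions"`.
#' @export
tss_normalize <- function(layer) {
  X <- layer_values(layer)
  if (any(X < 0, na.rm = TRUE)) abort("tss_normalize() needs non-negative values")
  tot <- rowSums(X)
  if (any(tot <= 0)) {
    abort(sprintf("zero-sum sample(s): %s",
                  paste(rownames(X)[tot <= 0], collapse = ", ")))
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = layer$sample_id),
                          tibble::as_tibble(X / tot))
  retag(out, layer, state = "proportions")
}

#' Multiplicative replacement of zero proportions
#'
#' Replaces each zero in a composition with half the smallest non-zero
#' proportion of that sample, shrinking the non-zero entries multiplicatively
#' so the composition still sums to one. This is the standard preparation for
#' the centred log-ratio transform, which requires strictly positive parts.
#'
#' @param layer an [omics_layer()] in `proportions` state (rows sum to 1
#'   within 1e-9).
#' @return An [omics_layer()] of strictly positive proportions.
#' @export
multiplicative_zero_replacement <- function(layer) {
  X <- layer_values(layer)
  if (any(abs(rowSums(X) - 1) > 1e-9)) {
    abort("rows must sum to 1; run tss_normalize() first")
  }
  for (i in seq_len(nrow(X))) {
    row <- X[i, ]
    z <- row == 0
    if (all(z)) abort(sprintf("sample '%s' is all zero", rownames(X)[i]))
    if (any(z)) {
      delta <- 0.5 * min(row[!z])
      row[z] <- delta
      row[!z] <- row[!z] * (1 - delta * sum(z))
      X[i, ] <- row
    }
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = layer$sample_id),
                          tibble::as_tibble(X))
  retag(out, layer, state = "proportions")
}

#' Centred log-ratio transform
#'
#' `clr(x)_j = ln(x_j) - mean(ln(x))` per sample. Scale-invariant within a
#' sample, so proportions and raw positive abundances give the same result;
#' rows of the output sum to zero.
#'
#' @param layer an [omics_layer()] with strictly positive values.
#' @return An [omics_layer()] with `transform_state = "clr"`.
#' @export
clr_transform <- function(layer) {
  X <- layer_values(layer)
  if (any(X <= 0, na.rm = TRUE)) {
    abort("clr_transform() needs strictly positive values; apply multiplicative_zero_replacement() first")
  }
  L <- log(X)
  L <- L - rowMeans(L)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = layer$sample_id),
                          tibble::as_tibble(L))
  retag(out, layer, state = "clr")
}

#' Flag near-zero-variance variables
#'
#' A variable is flagged when the ratio of the most common value's frequency
#' to the second most common value's frequency is at least `freq_cut` and the
#' fraction of distinct values is at most `unique_cut`. Constant columns are
#' always flagged. Defaults (19 = 95/5 and 10%) match the widely used
#' screening convention for degenerate predictors.
#'
#' @param data data frame of numeric columns.
#' @param freq_cut frequency-ratio threshold, default 19.
#' @param unique_cut distinct-value fraction threshold, default 0.10.
#' @return Tibble with columns `feature`, `freq_ratio`, `unique_fraction`,
#'   `nzv` (logical flag).
#' @export
near_zero_variance_flags <- function(data, freq_cut = 19, unique_cut = 0.10) {
  data <- tibble::as_tibble(data)
  data <- dplyr::select(data, -dplyr::any_of("sample_id"))
  purrr::map_dfr(names(data), function(nm) {
    x <- data[[nm]][!is.na(data[[nm]])]
    tab <- sort(table(x), decreasing = TRUE)
    fr <- if (length(tab) == 1L) Inf else unname(tab[1] / tab[2])
    uf <- length(tab) / length(x)
    tibble::tibble(feature = nm, freq_ratio = fr, unique_fraction = uf,
                   nzv = (fr >= freq_cut && uf <= unique_cut) ||
                     length(tab) == 1L)
  })
}

#' Log-transform a variable when it fails a normality test
#'
#' Applies the Anderson-Darling normality test; when p < `alpha` the variable
#' is returned as `ln(x + offset)` with `offset = 0` if `min(x) > 0` and
#' `1 - min(x)` otherwise, so the argument of the log is at least 1. The
#' decision and offset are recorded on the result.
#'
#' @param x numeric vector with at least 8 non-missing values.
#' @param alpha significance level for the normality gate, default 0.05.
#' @return A list with `values`, `transformed` (logical), `offset` and
#'   `ad_p` (the pre-transform Anderson-Darling p-value, `NA` for constants).
#' @export
normality_gated_log <- function(x, alpha = 0.05) {
  ok <- !is.na(x)
  if (sum(ok) < 8) abort("need >= 8 non-missing values")
  if (sd(x[ok]) == 0) {
    return(list(values = x, transformed = FALSE, offset = 0, ad_p = NA_real_))
  }
  p <- nortest::ad.test(x[ok])$p.value
  if (p < alpha) {
    offset <- if (min(x[ok]) > 0) 0 else 1 - min(x[ok])
    list(values = log(x + offset), transformed = TRUE, offset = offset, ad_p = p)
  } else {
    list(values = x, transformed = FALSE, offset = 0, ad_p = p)
  }
}

#' Gene richness by repeated rarefaction
#'
#' Each sample's reads are subsampled without replacement to exactly `depth`
#' reads (multivariate hypergeometric draw over genes); richness is the number
#' of genes with at least one read in the rarefied set, averaged over
#' `n_repeats` independent rarefactions. Samples with fewer than `depth`
#' total reads are reported as missing.
#'
#' @param gene_counts an [omics_layer()] (or matrix) of non-negative integer
#'   gene counts, samples as rows.
#' @param depth rarefaction depth (reads per sample), >= 1.
#' @param n_repeats number of repeated rarefactions, default 50.
#' @param seed integer seed.
#' @return Tibble with `sample_id`, `richness` (mean over repeats),
#'   `richness_sd`, `depth_ok`.
#' @export
rarefied_gene_richness <- function(gene_counts, depth, n_repeats = 50, seed = 1) {
  depth <- check_count(depth, "depth")
  n_repeats <- check_count(n_repeats, "n_repeats")
  X <- if (is.matrix(gene_counts)) gene_counts else layer_values(gene_counts)
  ids <- rownames(X) %||% paste0("S", seq_len(nrow(X)))
  with_seed(seed, {
    res <- purrr::map_dfr(seq_len(nrow(X)), function(i) {
      counts <- X[i, ]
      total <- sum(counts)
      if (total < depth) {
        return(tibble::tibble(sample_id = ids[i], richness = NA_real_,
                              richness_sd = NA_real_, depth_ok = FALSE))
      }
      if (total == depth) {
        # taking every read is deterministic
        r <- sum(counts > 0)
        return(tibble::tibble(sample_id = ids[i], richness = as.numeric(r),
                              richness_sd = 0, depth_ok = TRUE))
      }
      rich <- vapply(seq_len(n_repeats), function(rep) {
        sum(rarefy_once(counts, depth) > 0)
      }, numeric(1))
      tibble::tibble(sample_id = ids[i], richness = mean(rich),
                     richness_sd = sd(rich), depth_ok = TRUE)
    })
    res
  })
}

# one multivariate hypergeometric draw: sequential conditional rhyper
rarefy_once <- function(counts, depth) {
  k <- length(counts)
  out <- integer(k)
  remaining <- sum(counts)
  need <- depth
  for (j in seq_len(k)) {
    if (need == 0L) break
    cj <- counts[j]
    remaining <- remaining - cj
    if (remaining <= 0) {
      out[j] <- need
      need <- 0L
    } else {
      x <- rhyper(1, cj, remaining, need)
      out[j] <- x
      need <- need - x
    }
  }
  out
}
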