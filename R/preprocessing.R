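#' Bucket edges for a chemical-shift range
#'
#' Buckets tile `[range[1], range[2])` as left-closed, right-open intervals of
#' the given width; a trailing partial bucket is dropped.
#'
#' @param range `(low, high)` ppm.
#' @param width Bucket width, ppm (default 0.004).
#' @return Numeric vector of n+1 edges for n buckets.
#' @export
bucket_edges <- function(range = c(0.5, 9.0), width = 0.004) {
  assert_that(width > 0, "width must be > 0")
  assert_that(range[1] < range[2], "range must be (low, high)")
  n <- floor((range[2] - range[1]) / width + 1e-9)
  assert_that(n >= 1, "range narrower than one bucket")
  range[1] + width * (0:n)
}

# Cumulative trapezoidal integral of the piecewise-linear interpolant of
# (x, y) evaluated at arbitrary points `at` (must lie within [min(x), max(x)]).
# Exact for piecewise-linear spectra, including edges between grid nodes.
cum_integral_at <- function(x, y, at) {
  dx <- diff(x)
  seg <- dx * (y[-1] + y[-length(y)]) / 2
  C <- c(0, cumsum(seg))
  i <- findInterval(at, x, rightmost.closed = TRUE)
  i[i >= length(x)] <- length(x) - 1L
  h <- at - x[i]
  yi <- y[i] + (y[i + 1L] - y[i]) * h / dx[i]
  C[i] + h * (y[i] + yi) / 2
}

#' Integrate a spectrum into fixed-width buckets
#'
#' Each bucket value is the trapezoidal integral of the intensity over the
#' bucket interval, so the bucket vector conserves the total integral over
#' the bucketed range.
#'
#' @param spectrum An `nmr_spectrum` (or any list with monotone `ppm` and
#'   matching `intensity`).
#' @param width Bucket width in ppm; default 0.004.
#' @param range Bucketed range `(low, high)` in ppm; default `c(0.5, 9.0)`,
#'   giving 2125 buckets at the default width.
#' @return Named numeric vector of bucket integrals; names are bucket centers
#'   (left edge + width/2).
#' @export
bucket <- function(spectrum, width = 0.004, range = c(0.5, 9.0)) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  assert_that(length(ppm) == length(y) && length(ppm) >= 2,
              "ppm and intensity must have equal length >= 2")
  d <- diff(ppm)
  if (all(d < 0)) {  # stored in display (descending) order; flip ascending
    ppm <- rev(ppm); y <- rev(y); d <- diff(ppm)
  }
  assert_that(all(d > 0), "ppm axis must be strictly monotone")
  edges <- bucket_edges(range, width)
  if (min(ppm) > edges[1] + 1e-12 || max(ppm) < edges[length(edges)] - 1e-12) {
    stop2(sprintf("spectrum [%.4f, %.4f] does not cover the bucket range [%.4f, %.4f]",
                  min(ppm), max(ppm), edges[1], edges[length(edges)]))
  }
  C <- cum_integral_at(ppm, y, edges)
  v <- diff(C)
  names(v) <- sprintf("%.4f", edges[-length(edges)] + width / 2)
  v
}

#' Build a bucket table from a set of spectra
#'
#' Buckets every spectrum onto a common grid and assembles the
#' samples-by-buckets matrix together with sample metadata.
#'
#' @inheritParams bucket
#' @param spectra List of `nmr_spectrum` objects sharing a tissue mode.
#' @return A `bucket_table`: list with `matrix` (samples x buckets),
#'   `sample_ids`, `groups`, `centers` (ppm), `width`, `tissue_mode`,
#'   `wet_weights` (mg, or NULL), `normalization` (`"none"` until
#'   [normalize_buckets()]), `excluded_regions`.
#' @export
bucket_table <- function(spectra, width = 0.004, range = c(0.5, 9.0)) {
  assert_that(length(spectra) >= 1, "need at least one spectrum")
  rows <- lapply(spectra, bucket, width = width, range = range)
  mat <- do.call(rbind, rows)
  centers <- bucket_edges(range, width)
  centers <- centers[-length(centers)] + width / 2
  ww <- vapply(spectra, function(s) s$wet_weight %||% NA_real_, 0)
  structure(list(matrix = unname(mat),
                 sample_ids = vapply(spectra, `[[`, "", "sample_id"),
                 groups = vapply(spectra, `[[`, "", "group"),
                 centers = centers, width = width,
                 tissue_mode = spectra[[1]]$tissue_mode %||% "intact",
                 wet_weights = if (all(is.na(ww))) NULL else ww,
                 normalization = "none",
                 excluded_regions = list()),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d buckets (width %.4g ppm, %s-normalized)\n",
              nrow(x$matrix), ncol(x$matrix), x$width, x$normalization))
  if (length(x$excluded_regions)) {
    for (r in x$excluded_regions) {
      cat(sprintf("  excluded: %.2f-%.2f ppm\n", r[1], r[2]))
    }
  }
  invisible(x)
}

#' Discard buckets in a chemical-shift region
#'
#' Removes every bucket whose center lies inside the closed region, the
#' standard treatment of the residual-water window (default 4.20-5.20 ppm)
#' before multivariate analysis.
#'
#' @param table A `bucket_table`.
#' @param region `(low, high)` ppm; must intersect the bucketed range.
#' @return The reduced `bucket_table`, with the region recorded in
#'   `excluded_regions`.
#' @export
exclude_region <- function(table, region = c(4.20, 5.20)) {
  assert_that(inherits(table, "bucket_table"), "table must be a bucket_table")
  assert_that(length(region) == 2L && region[1] < region[2],
              "region must be (low, high)")
  rng <- range(table$centers)
  if (region[2] < rng[1] || region[1] > rng[2]) {
    stop2("exclusion region lies outside the bucketed range")
  }
  drop <- table$centers >= region[1] & table$centers <= region[2]
  if (all(drop)) stop2("exclusion region would remove every bucket")
  table$matrix <- table$matrix[, !drop, drop = FALSE]
  table$centers <- table$centers[!drop]
  table$excluded_regions <- c(table$excluded_regions, list(as.numeric(region)))
  table
}

#' Normalize a bucket table
#'
#' `total_integral` divides each row by its own sum (each normalized row sums
#' to 1), the convention for intact-tissue spectra; `wet_weight` divides each
#' row by the sample's wet weight in grams, the convention for tissue
#' extracts with known extraction masses. Normalization runs after water
#' exclusion so the residual water signal cannot distort row sums.
#'
#' @param table A `bucket_table`.
#' @param mode `"total_integral"` or `"wet_weight"`.
#' @return The normalized `bucket_table`.
#' @export
normalize_buckets <- function(table, mode = c("total_integral", "wet_weight")) {
  assert_that(inherits(table, "bucket_table"), "table must be a bucket_table")
  mode <- match.arg(mode)
  if (mode == "total_integral") {
    rs <- rowSums(table$matrix)
    if (any(rs <= 0)) {
      stop2("total_integral normalization needs strictly positive row sums; offending sample(s): ",
            paste(table$sample_ids[rs <= 0], collapse = ", "))
    }
    table$matrix <- table$matrix / rs
  } else {
    if (is.null(table$wet_weights) || anyNA(table$wet_weights)) {
      stop2("wet_weight normalization needs a wet weight for every sample")
    }
    table$matrix <- table$matrix / (table$wet_weights / 1000)  # mg -> g
  }
  table$normalization <- mode
  table
}

#' Default preprocessing chain
#'
#' bucket -> exclude water region -> normalize, with the standard parameters
#' (0.004 ppm buckets over 0.5-9.0 ppm, 4.20-5.20 ppm discarded,
#' normalization chosen by tissue mode: total integral for intact tissue,
#' wet weight for extracts).
#'
#' @inheritParams bucket_table
#' @param exclusion Water region to discard, or NULL to keep everything.
#' @param normalization Override; default picks by tissue mode.
#' @return Normalized `bucket_table`.
#' @export
preprocess_spectra <- function(spectra, width = 0.004, range = c(0.5, 9.0),
                               exclusion = c(4.20, 5.20),
                               normalization = NULL) {
  tab <- bucket_table(spectra, width = width, range = range)
  if (!is.null(exclusion)) tab <- exclude_region(tab, exclusion)
  if (is.null(normalization)) {
    normalization <- if (identical(tab$tissue_mode, "extract"))
      "wet_weight" else "total_integral"
  }
  normalize_buckets(tab, normalization)
}

#' Write / read a bucket table
#'
#' The matrix goes to CSV (first columns `sample_id`, `group`; remaining
#' column names are bucket centers) with a JSON sidecar recording the bucket
#' width, normalization mode and excluded regions.
#'
#' @param table A `bucket_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, the CSV path.
#' @export
write_bucket_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, group = table$groups,
                   table$matrix, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("%.4f", table$centers)
  utils::write.csv(df, path, row.names = FALSE)
  write_json_file(list(width = table$width,
                       normalization = table$normalization,
                       tissue_mode = table$tissue_mode,
                       wet_weights = table$wet_weights,
                       excluded_regions = table$excluded_regions),
                  paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_bucket_table
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(matrix = unname(as.matrix(df[, -(1:2)])),
                 sample_ids = as.character(df$sample_id),
                 groups = as.character(df$group),
                 centers = as.numeric(names(df)[-(1:2)]),
                 width = meta$width,
                 tissue_mode = meta$tissue_mode %||% "intact",
                 wet_weights = meta$wet_weights,
                 normalization = meta$normalization,
                 excluded_regions = if (is.null(meta$excluded_regions)) list()
                 else lapply(seq_len(nrow(meta$excluded_regions)),
                             function(i) as.numeric(meta$excluded_regions[i, ]))),
            class = "bucket_table")
}

# Subset a bucket table by sample index, keeping metadata aligned.
subset_samples <- function(table, idx) {
  table$matrix <- table$matrix[idx, , drop = FALSE]
  table$sample_ids <- table$sample_ids[idx]
  table$groups <- table$groups[idx]
  if (!is.null(table$wet_weights)) table$wet_weights <- table$wet_weights[idx]
  table
}
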