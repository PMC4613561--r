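#' Critical Pearson correlation at a given sample size
#'
#' The magnitude above which a Pearson correlation is significant at level
#' `alpha` (two-sided) for `n` samples:
#' `r_crit = t* / sqrt(t*^2 + (n - 2))` with `t*` the two-sided critical
#' value of Student's t on `n - 2` degrees of freedom. Used as the
#' significance cutoff for correlation-scaled loadings (e.g. |r| > 0.29 at
#' n = 44, |r| > 0.39 at n = 25, alpha = 0.05).
#'
#' @param n Sample count (>= 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Full-precision critical |r|.
#' @seealso [critical_r_display()] for the truncated display value.
#' @export
critical_r <- function(n, alpha = 0.05) {
  assert_that(all(n >= 3), "n must be >= 3")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + (n - 2))
}

#' @rdname critical_r
#' @details The display value truncates (floors toward zero) at two decimals
#'   rather than rounding: the cutoff 0.297 is conventionally printed as
#'   0.29, since any |r| above the printed value is significant.
#' @export
critical_r_display <- function(n, alpha = 0.05) {
  trunc_digits(critical_r(n, alpha), 2)
}

#' Correlation-scaled back-transformed loadings
#'
#' For each bucket, the Pearson correlation `r` between the bucket's
#' (normalized, unscaled) intensities and the model's predictive score t, and
#' the back-scaled coefficient `cov(bucket, t) / sd(t)` — covariance in
#' original intensity units, so strong peaks dominate the coefficient plot
#' the way they dominate the spectrum. Buckets with |r| above
#' [critical_r()] for the model's sample count are flagged significant.
#' Zero-variance buckets have undefined correlation; they are reported with
#' r = 0 and flagged in `zero_variance`.
#'
#' @param model A fitted `oplsda_model`.
#' @param X The `bucket_table` (or matrix) the model was fit on.
#' @param alpha Significance level for the critical-|r| mask.
#' @return A `loadings_report`: data.frame `table` (`center`, `coefficient`,
#'   `r`, `significant`, `zero_variance`), plus `n`, `alpha`, `r_crit`.
#' @export
correlation_loadings <- function(model, X, alpha = 0.05) {
  M <- as_X(X)
  centers <- if (inherits(X, "bucket_table")) X$centers else
    seq_len(ncol(M))
  t <- model$t
  assert_that(nrow(M) == length(t),
              "X rows must match the model's training samples")
  n <- length(t)
  sdt <- stats::sd(t)
  v <- apply(M, 2, stats::var)
  zero <- v <= 0
  r <- rep(0, ncol(M))
  cov_jt <- as.vector(crossprod(sweep(M, 2, colMeans(M)), t - mean(t))) / (n - 1)
  r[!zero] <- cov_jt[!zero] / (sqrt(v[!zero]) * sdt)
  coefficient <- cov_jt / sdt
  coefficient[zero] <- 0
  rc <- critical_r(n, alpha)
  structure(list(table = data.frame(center = centers,
                                    coefficient = coefficient,
                                    r = r,
                                    significant = abs(r) > rc & !zero,
                                    zero_variance = zero),
                 n = n, alpha = alpha, r_crit = rc),
            class = "loadings_report")
}

#' @export
print.loadings_report <- function(x, ...) {
  cat(sprintf("<loadings_report> %d buckets, n = %d, |r| > %.3f: %d significant\n",
              nrow(x$table), x$n, x$r_crit, sum(x$table$significant)))
  invisible(x)
}

#' Roll a loadings report up to a per-metabolite change table
#'
#' For each metabolite in the region map, takes the strongest-|r| significant
#' bucket among the buckets falling in its ppm regions and reports the change
#' direction (`up`/`down`); `ns` when no bucket in the region passes the
#' critical-|r| cutoff, and `not_evaluable` when the regions contain no
#' buckets at all (e.g. resonances lost to the water exclusion window).
#'
#' @param report A `loadings_report`.
#' @param region_map data.frame with `metabolite`, `low`, `high` (ppm), as
#'   from [metabolite_regions()]; a metabolite may span several rows.
#' @param comparison Label copied into the output (e.g.
#'   `"lesion-vs-healthy"`).
#' @return data.frame `metabolite`, `comparison`, `r`, `direction`.
#' @export
build_change_table <- function(report, region_map, comparison = "") {
  assert_that(inherits(report, "loadings_report"),
              "report must come from correlation_loadings()")
  assert_that(all(c("metabolite", "low", "high") %in% names(region_map)),
              "region_map needs metabolite/low/high columns")
  assert_that(all(region_map$low < region_map$high),
              "empty region (low >= high) in region_map")
  tab <- report$table
  out <- lapply(unique(region_map$metabolite), function(m) {
    rg <- region_map[region_map$metabolite == m, , drop = FALSE]
    inside <- rep(FALSE, nrow(tab))
    for (i in seq_len(nrow(rg))) {
      inside <- inside | (tab$center >= rg$low[i] & tab$center <= rg$high[i])
    }
    if (!any(inside)) {
      return(data.frame(metabolite = m, comparison = comparison,
                        r = NA_real_, direction = "not_evaluable"))
    }
    hits <- tab[inside & tab$significant, , drop = FALSE]
    if (nrow(hits) == 0L) {
      return(data.frame(metabolite = m, comparison = comparison,
                        r = NA_real_, direction = "ns"))
    }
    best <- hits[which.max(abs(hits$r)), ]
    data.frame(metabolite = m, comparison = comparison, r = best$r,
               direction = if (best$r > 0) "up" else "down")
  })
  do.call(rbind, out)
}

#' Two-sample t-test for a single measured quantity
#'
#' Student's (equal-variance) two-sided two-sample t-test, the convention
#' used for assay tables such as GSH/GSSG; Welch's correction is available
#' behind `var_equal = FALSE`.
#'
#' @param values Numeric measurements.
#' @param groups Two-level grouping aligned with `values`.
#' @param alpha Significance level for the flag.
#' @param var_equal Use the pooled-variance Student test (default TRUE).
#' @return List with `t`, `df`, `p`, `significant`, `means` (named per
#'   group).
#' @export
univariate_ttest <- function(values, groups, alpha = 0.05, var_equal = TRUE) {
  groups <- as.character(groups)
  lev <- unique(groups)
  assert_that(length(lev) == 2L, "groups must have exactly two levels")
  assert_that(min(table(groups)) >= 2, "each group needs >= 2 values")
  ht <- stats::t.test(values[groups == lev[1]], values[groups == lev[2]],
                      var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha,
       means = stats::setNames(as.numeric(tapply(values, groups, mean)[lev]),
                               lev))
}
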