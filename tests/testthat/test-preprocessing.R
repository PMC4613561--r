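flat_spectrum <- function(value = 1, lo = 0.4, hi = 9.1, n = 5000,
                          id = "S1") {
  structure(list(sample_id = id, group = "healthy", tissue_mode = "intact",
                 wet_weight = NULL, ppm = seq(lo, hi, length.out = n),
                 intensity = rep(value, n)),
            class = "nmr_spectrum")
}

test_that("bucket grid tiles the range: 2125 buckets, 250 excluded", {
  e <- bucket_edges(c(0.5, 9.0), 0.004)
  expect_identical(length(e) - 1L, 2125L)
  v <- bucket(flat_spectrum())
  expect_identical(length(v), 2125L)
  centers <- as.numeric(names(v))
  inside <- centers >= 4.20 & centers <= 5.20
  expect_identical(sum(inside), 250L)
  expect_identical(sum(!inside), 1875L)
})

test_that("constant intensity gives equal bucket integrals", {
  v <- bucket(flat_spectrum(2.5))
  expect_equal(max(abs(v / (2.5 * 0.004) - 1)), 0, tolerance = 1e-9)
})

test_that("a narrow Lorentzian is captured by its bucket (quadrature oracle)", {
  # unit-area line centred mid-bucket, much narrower than the bucket
  center <- 1.302; hw <- 1e-4
  f <- function(x) (hw / pi) / ((x - center)^2 + hw^2)
  s <- flat_spectrum(0, n = 400000)
  s$intensity <- f(s$ppm)
  v <- bucket(s)
  k <- which.min(abs(as.numeric(names(v)) - center))
  oracle <- integrate(f, 1.300, 1.304, rel.tol = 1e-10)$value
  expect_equal(unname(v[k]), oracle, tolerance = 1e-4)
  expect_lt(max(v[-k]), 0.05 * v[k])
})

test_that("bucketing conserves the total integral", {
  sim <- small_cohort(n_per = 2, seed = 2, resolution = 500)
  s <- sim$spectra[[1]]
  v <- bucket(s)
  rng <- range(bucket_edges())
  inside <- s$ppm >= rng[1] & s$ppm <= rng[2]
  total <- sum(diff(s$ppm[inside]) *
                 (s$intensity[inside][-1] + head(s$intensity[inside], -1)) / 2)
  expect_equal(sum(v), total, tolerance = 1e-6)
})

test_that("bucket boundaries are independent of spectrum resolution", {
  smooth <- function(n) {
    s <- flat_spectrum(0, n = n)
    s$intensity <- 2 + sin(s$ppm) +
      (0.05 / pi) / ((s$ppm - 3)^2 + 0.05^2)   # broad line, well resolved
    s
  }
  v1 <- bucket(smooth(20000))
  v2 <- bucket(smooth(40000))
  expect_identical(names(v1), names(v2))
  expect_equal(unname(v2 / v1), rep(1, length(v1)), tolerance = 1e-3)
})

test_that("descending ppm axes are accepted, non-monotone ones are not", {
  s <- flat_spectrum()
  s_desc <- s
  s_desc$ppm <- rev(s$ppm); s_desc$intensity <- rev(s$intensity)
  expect_equal(bucket(s_desc), bucket(s))
  s_bad <- s
  s_bad$ppm[10] <- s_bad$ppm[12]
  expect_error(bucket(s_bad), "monotone")
  expect_error(bucket(flat_spectrum(lo = 1, hi = 5)), "cover")
})

test_that("water-region exclusion validates its region", {
  tab <- bucket_table(list(flat_spectrum()))
  red <- exclude_region(tab)
  expect_identical(ncol(red$matrix), 1875L)
  expect_false(any(red$centers >= 4.20 & red$centers <= 5.20))
  expect_error(exclude_region(tab, c(10, 12)), "outside")
  expect_error(exclude_region(tab, c(0, 10)), "every bucket")
  # no exclusion -> identity
  expect_identical(tab$matrix, bucket_table(list(flat_spectrum()))$matrix)
})

test_that("total-integral rows sum to one and are scale invariant", {
  sim <- small_cohort(n_per = 2, seed = 4, resolution = 300,
                      tissue_mode = "intact")
  tab <- exclude_region(bucket_table(sim$spectra))
  norm <- normalize_buckets(tab, "total_integral")
  expect_equal(rowSums(norm$matrix), rep(1, nrow(norm$matrix)),
               tolerance = 1e-12)
  scaled <- tab
  scaled$matrix <- tab$matrix * 37.5
  expect_equal(normalize_buckets(scaled, "total_integral")$matrix,
               norm$matrix, tolerance = 1e-12)
})

test_that("wet-weight normalization divides by grams", {
  tab <- structure(list(matrix = matrix(2, 1, 3), sample_ids = "S1",
                        groups = "healthy", centers = c(1, 2, 3) / 10,
                        width = 0.1, tissue_mode = "extract",
                        wet_weights = 2, normalization = "none",
                        excluded_regions = list()),
                   class = "bucket_table")   # 2 mg = 0.002 g
  out <- normalize_buckets(tab, "wet_weight")
  expect_equal(out$matrix, matrix(1000, 1, 3))
  tab$wet_weights <- NULL
  expect_error(normalize_buckets(tab, "wet_weight"), "wet weight")
})

test_that("normalization order is pinned: exclude first, then normalize", {
  sim <- small_cohort(n_per = 2, seed = 6, resolution = 300,
                      tissue_mode = "intact")
  tab <- bucket_table(sim$spectra)
  pipeline_way <- normalize_buckets(exclude_region(tab), "total_integral")
  other_way <- exclude_region(normalize_buckets(tab, "total_integral"))
  expect_gt(max(abs(pipeline_way$matrix - other_way$matrix)), 0)
  default <- preprocess_spectra(sim$spectra)
  expect_equal(default$matrix, pipeline_way$matrix, tolerance = 1e-12)
})

test_that("zero rows are rejected by total-integral normalization", {
  tab <- bucket_table(list(flat_spectrum(0)))
  expect_error(normalize_buckets(tab, "total_integral"), "positive row sums")
})

test_that("bucket tables round-trip through CSV with sidecar metadata", {
  sim <- small_cohort(n_per = 3, seed = 9, resolution = 300)
  tab <- preprocess_spectra(sim$spectra)
  path <- file.path(withr::local_tempdir(), "buckets.csv")
  write_bucket_table(tab, path)
  back <- read_bucket_table(path)
  expect_equal(back$matrix, tab$matrix, tolerance = 1e-6)
  expect_identical(back$normalization, tab$normalization)
  expect_equal(back$excluded_regions, tab$excluded_regions)
  expect_equal(back$centers, tab$centers, tolerance = 1e-9)
})
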