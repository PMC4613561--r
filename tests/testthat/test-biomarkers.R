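test_that("critical correlation cutoffs match the t-distribution oracle", {
  # n = 6: t*(0.975, 4) = 2.776; r = t*/sqrt(t*^2 + 4) = 0.811
  expect_equal(critical_r(6), 0.811, tolerance = 1e-3)
  expect_identical(critical_r_display(44), 0.29)
  expect_identical(critical_r_display(25), 0.39)
  # truncation, not rounding: full-precision values round to 0.30 / 0.40
  expect_identical(round(critical_r(44), 2), 0.30)
  expect_identical(round(critical_r(25), 2), 0.40)
  expect_error(critical_r(2), "n must be")
})

test_that("critical r decreases with n and increases with alpha", {
  ns <- c(5, 10, 25, 44, 100, 500)
  expect_true(all(diff(critical_r(ns)) < 0))
  alphas <- c(0.001, 0.01, 0.05, 0.1)
  r_by_alpha <- vapply(alphas, function(a) critical_r(30, a), 0)
  expect_true(all(diff(r_by_alpha) < 0))  # smaller alpha, stricter cutoff
})

test_that("correlation loadings agree with the textbook Pearson formula", {
  s <- structured_xy(n = 20, p = 12, seed = 41)
  m <- fit_oplsda(s$X, s$y, n_ortho = 1)
  rep_ <- correlation_loadings(m, s$X)
  # direct two-pass formula, independent of cor()
  direct <- vapply(seq_len(ncol(s$X)), function(j) {
    x <- s$X[, j]; t <- m$t
    sum((x - mean(x)) * (t - mean(t))) /
      sqrt(sum((x - mean(x))^2) * sum((t - mean(t))^2))
  }, 0)
  expect_equal(rep_$table$r, direct, tolerance = 1e-10)
  expect_true(all(abs(rep_$table$r) <= 1 + 1e-12))
  # coefficient and r share sign; both vanish together
  expect_true(all(sign(rep_$table$coefficient) == sign(rep_$table$r) |
                    abs(rep_$table$r) < 1e-12))
  expect_identical(rep_$r_crit, critical_r(20))
  expect_identical(rep_$table$significant,
                   abs(rep_$table$r) > rep_$r_crit & !rep_$table$zero_variance)
})

test_that("a bucket equal to the predictive score has r = 1", {
  s <- structured_xy(n = 16, p = 8, seed = 42)
  m <- fit_oplsda(s$X, s$y, n_ortho = 0)
  X2 <- cbind(s$X, m$t)
  rep_ <- correlation_loadings(m, X2)
  expect_equal(rep_$table$r[ncol(X2)], 1, tolerance = 1e-10)
})

test_that("zero-variance buckets are flagged, not propagated as NaN", {
  s <- structured_xy(n = 16, p = 6, seed = 43)
  X2 <- cbind(s$X, 7)   # constant bucket
  m <- suppressWarnings(fit_oplsda(X2, s$y, n_ortho = 0))
  rep_ <- correlation_loadings(m, X2)
  last <- nrow(rep_$table)
  expect_true(rep_$table$zero_variance[last])
  expect_identical(rep_$table$r[last], 0)
  expect_identical(rep_$table$coefficient[last], 0)
  expect_false(rep_$table$significant[last])
})

test_that("change tables report direction, ns, and non-evaluable regions", {
  sim <- small_cohort(n_per = 12, seed = 44)
  tab <- preprocess_spectra(sim$spectra)
  y <- lesion_labels(tab$groups)
  m <- fit_oplsda(tab, y, n_ortho = 1, positive = "lesion")
  rep_ <- correlation_loadings(m, tab)
  regions <- rbind(
    metabolite_regions(metabolite_templates("extract")),
    data.frame(metabolite = "water-window-only", low = 4.5, high = 4.9))
  ct <- build_change_table(rep_, regions, "lesion-vs-healthy")
  expect_identical(ct$direction[ct$metabolite == "water-window-only"],
                   "not_evaluable")
  expect_identical(ct$direction[ct$metabolite == "lactate"], "up")
  expect_true(all(ct$direction %in% c("up", "down", "ns", "not_evaluable")))
  expect_error(build_change_table(
    rep_, data.frame(metabolite = "x", low = 2, high = 2)), "empty region")
})

test_that("all-ns reports produce all-ns change tables", {
  rep_ <- structure(list(table = data.frame(center = c(1.0, 2.0),
                                            coefficient = c(0.1, -0.1),
                                            r = c(0.05, -0.02),
                                            significant = c(FALSE, FALSE),
                                            zero_variance = c(FALSE, FALSE)),
                         n = 20, alpha = 0.05, r_crit = critical_r(20)),
                    class = "loadings_report")
  ct <- build_change_table(rep_, data.frame(metabolite = c("a", "b"),
                                            low = c(0.9, 1.9),
                                            high = c(1.1, 2.1)))
  expect_identical(ct$direction, c("ns", "ns"))
})

test_that("the two-sample t-test matches pooled-variance arithmetic", {
  g1 <- c(5, 6, 7, 8, 9)          # mean 7, var 2.5
  g2 <- c(1, 2, 3, 4, 10)         # mean 4, var 12.5
  out <- univariate_ttest(c(g1, g2), rep(c("A", "B"), each = 5))
  sp2 <- (4 * var(g1) + 4 * var(g2)) / 8
  t_manual <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(out$t, t_manual, tolerance = 1e-12)
  expect_equal(out$df, 8)
  expect_equal(out$p, 2 * pt(-abs(t_manual), 8), tolerance = 1e-12)
  expect_false(out$significant)
  expect_equal(unname(out$means), c(7, 4))

  same <- univariate_ttest(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(univariate_ttest(1:3, c("A", "A", "B")), ">= 2")
})

test_that("planted glutathione elevation reproduces the expected pattern", {
  hits <- vapply(1:100, function(r) {
    cfg <- simulation_config(seed = 600 + r, resolution = 200)
    gt <- generate_gsh_table(cfg)
    p_hb <- univariate_ttest(gt$GSH[gt$group != "malignant"],
                             gt$group[gt$group != "malignant"])
    p_hm <- univariate_ttest(gt$GSH[gt$group != "benign"],
                             gt$group[gt$group != "benign"])
    p_bm <- univariate_ttest(gt$GSH[gt$group != "healthy"],
                             gt$group[gt$group != "healthy"])
    p_hb$significant && p_hm$significant && !p_bm$significant
  }, NA)
  expect_gte(mean(hits), 0.9)
})
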