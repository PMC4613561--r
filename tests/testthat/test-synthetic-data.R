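test_that("identical seeds give bit-identical spectra and tables", {
  cfg <- simulation_config(c(healthy = 4, benign = 4, malignant = 0),
                           seed = 7, resolution = 200)
  s1 <- generate_spectra(cfg)
  s2 <- generate_spectra(cfg)
  expect_identical(lapply(s1$spectra, `[[`, "intensity"),
                   lapply(s2$spectra, `[[`, "intensity"))
  expect_identical(s1$truth$samples, s2$truth$samples)

  f1 <- generate_fatty_acid_table(cfg)
  f2 <- generate_fatty_acid_table(cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  g1 <- generate_gsh_table(cfg)
  expect_identical(g1, generate_gsh_table(cfg))

  s3 <- generate_spectra(simulation_config(
    c(healthy = 4, benign = 4, malignant = 0), seed = 8, resolution = 200))
  expect_false(identical(s1$spectra[[1]]$intensity,
                         s3$spectra[[1]]$intensity))
})

test_that("invalid configurations and effect tables are rejected", {
  expect_error(simulation_config(c(healthy = 1, benign = 4, malignant = 0)),
               ">= 2 samples")
  expect_error(simulation_config(c(healthy = 4, benign = 4, malignant = 0),
                                 noise_sd = -1), "noise_sd")
  cfg <- simulation_config(c(healthy = 4, benign = 4, malignant = 0),
                           resolution = 200)
  bad <- data.frame(metabolite = "unobtainium",
                    comparison = "lesion-vs-healthy",
                    direction = 1, magnitude = 0.5)
  expect_error(generate_spectra(cfg, effects = bad), "unknown metabolite")
  incons <- data.frame(metabolite = "lactate",
                       comparison = "lesion-vs-healthy",
                       direction = 1, magnitude = -0.5)
  expect_error(generate_spectra(cfg, effects = incons), "disagree")
})

test_that("extract mode drops lipid and carries wet weights", {
  cfg <- simulation_config(c(healthy = 3, benign = 3, malignant = 0),
                           tissue_mode = "extract", resolution = 200)
  sim <- generate_spectra(cfg)
  expect_false("lipid" %in% names(metabolite_templates("extract")))
  ww <- vapply(sim$spectra, `[[`, 0, "wet_weight")
  expect_true(all(ww > 40 & ww < 60))

  cfg_i <- simulation_config(c(healthy = 3, benign = 3, malignant = 0),
                             tissue_mode = "intact", resolution = 200)
  sim_i <- generate_spectra(cfg_i)
  expect_null(sim_i$spectra[[1]]$wet_weight)
})

# Narrow-window cohorts keep the replicate loops cheap: only the lactate /
# threonine resonances around 1.3 ppm are simulated.
narrow_cfg <- function(seed, n = 20) {
  simulation_config(c(healthy = n, benign = n, malignant = 0), seed = seed,
                    ppm_range = c(1.2, 1.5), resolution = 400,
                    tissue_mode = "extract")
}
narrow_templates <- metabolite_templates("extract")[c("lactate", "threonine")]

test_that("zero planted effects leave the groups exchangeable", {
  null_eff <- data.frame(metabolite = "lactate",
                         comparison = "lesion-vs-healthy",
                         direction = 0, magnitude = 0)
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    sim <- generate_spectra(narrow_cfg(1000 + r),
                            templates = narrow_templates,
                            effects = null_eff)
    tab <- bucket_table(sim$spectra, range = c(1.2, 1.5))
    v <- tab$matrix[, which.min(abs(tab$centers - 1.332))]
    stats::t.test(v[tab$groups == "healthy"],
                  v[tab$groups == "benign"])$p.value
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)   # ~ alpha, with binomial slack at 200 replicates
  expect_lt(rate, 0.12)
})

test_that("a planted lactate increase is detected at the lactate bucket", {
  eff <- data.frame(metabolite = "lactate",
                    comparison = "lesion-vs-healthy",
                    direction = 1, magnitude = 0.5)
  reps <- 200
  hits <- vapply(seq_len(reps), function(r) {
    sim <- generate_spectra(narrow_cfg(2000 + r),
                            templates = narrow_templates, effects = eff)
    tab <- bucket_table(sim$spectra, range = c(1.2, 1.5))
    v <- tab$matrix[, which.min(abs(tab$centers - 1.332))]
    up <- mean(v[tab$groups == "benign"]) > mean(v[tab$groups == "healthy"])
    p <- stats::t.test(v[tab$groups == "healthy"],
                       v[tab$groups == "benign"])$p.value
    up && p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("planted fatty-acid class shifts are recovered in sign", {
  eff <- data.frame(target = "SFA", comparison = "lesion-vs-healthy",
                    shift = 0.2)
  reps <- 200
  hits <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(c(healthy = 20, benign = 20, malignant = 0),
                             seed = 3000 + r, resolution = 200)
    tab <- generate_fatty_acid_table(cfg, effects = eff)
    cp <- composition_summary(tab)$class_percent
    mean(cp$SFA[cp$group == "benign"]) > mean(cp$SFA[cp$group == "healthy"])
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("fatty-acid generator validates shifts and stays positive", {
  cfg <- simulation_config(c(healthy = 5, benign = 5, malignant = 0),
                           resolution = 200)
  expect_error(generate_fatty_acid_table(
    cfg, effects = data.frame(target = "SFA",
                              comparison = "lesion-vs-healthy",
                              shift = -1)), "non-positive")
  tab <- generate_fatty_acid_table(cfg)
  expect_true(all(as.matrix(tab[, -(1:2)]) > 0))
})

test_that("spectrum round trip through the wide CSV preserves data", {
  sim <- small_cohort(n_per = 3, seed = 5, resolution = 150)
  dir <- withr::local_tempdir()
  paths <- write_spectra(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_spectra_wide(paths[["wide"]], tissue_mode = "extract")
  expect_equal(back[[2]]$intensity, sim$spectra[[2]]$intensity,
               tolerance = 1e-6)
  expect_identical(back[[2]]$group, sim$spectra[[2]]$group)
})
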