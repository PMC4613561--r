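#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Two synthetic cohorts mirror the clinical design (46 healthy adjacent
# tissues, 25 benign nodules, 28 malignant nodules): an intact-tissue
# (HRMAS-like) cohort with lipid envelopes, and an aqueous-extract cohort
# with per-sample wet weights. Planted effects follow the published
# direction pattern at a uniform 50% median shift. Ground truth (group
# membership and affected ppm regions) is written alongside for the
# downstream recovery checks.

library(thyrometab)

seed <- 20260920L
out <- "results/simulated"

for (mode in c("intact", "extract")) {
  cfg <- simulation_config(seed = seed, tissue_mode = mode)
  sim <- generate_spectra(cfg)
  dir <- file.path(out, mode)
  paths <- write_spectra(sim, dir)
  cat(sprintf("[01] %s cohort: %d spectra, %d grid points -> %s\n",
              mode, length(sim$spectra), length(sim$spectra[[1]]$ppm), dir))
}

cat("[01] done; ground truth stored next to each cohort\n")
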