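#!/usr/bin/env Rscript
# Stage 3: PCA overview, then OPLS-DA per comparison with 7-fold
# cross-validation, CV-ANOVA significance and ROC from the cross-validated
# predicted Y — the model-quality surface of the analysis.

library(thyrometab)

seed <- 20260920L
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

for (mode in c("intact", "extract")) {
  tab <- read_bucket_table(file.path("results",
                                     paste0("buckets_", mode, ".csv")))
  pca <- fit_pca(tab, 3)
  cat(sprintf("[03] %s PCA: %.1f%% / %.1f%% / %.1f%% variance on PC1-3\n",
              mode, 100 * pca$explained_variance[1],
              100 * pca$explained_variance[2],
              100 * pca$explained_variance[3]))
  utils::write.csv(data.frame(sample_id = tab$sample_ids,
                              group = tab$groups, pca$scores),
                   sprintf("results/models/pca_scores_%s.csv", mode),
                   row.names = FALSE)
  grDevices::png(sprintf("results/figures/pca_%s.png", mode), 900, 700,
                 res = 110)
  plot_scores(pca$scores, tab$groups,
              xlab = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
              ylab = sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2]),
              main = sprintf("PCA scores, %s tissue", mode))
  grDevices::dev.off()

  cfg <- pipeline_config(sim = NULL, seed = seed)
  for (cmp in c("lesion-vs-healthy", "malignant-vs-benign")) {
    res <- run_comparison(tab, cmp, cfg,
                          region_map = metabolite_regions(
                            metabolite_templates(mode)))
    slug <- paste0(gsub("[^a-z]+", "_", cmp), "_", mode)
    write_json <- function(x, f) jsonlite::write_json(
      x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_json(res$summary, sprintf("results/models/summary_%s.json", slug))
    utils::write.csv(res$loadings$table,
                     sprintf("results/models/loadings_%s.csv", slug),
                     row.names = FALSE)
    utils::write.csv(res$changes,
                     sprintf("results/models/changes_%s.csv", slug),
                     row.names = FALSE)
    grDevices::png(sprintf("results/figures/roc_%s.png", slug), 700, 700,
                   res = 110)
    plot_roc(res$roc, main = sprintf("%s (%s)", cmp, mode))
    grDevices::dev.off()
    grDevices::png(sprintf("results/figures/coefficients_%s.png", slug),
                   1200, 500, res = 110)
    plot_coefficients(res$loadings,
                      main = sprintf("%s (%s)", cmp, mode))
    grDevices::dev.off()
    s <- res$summary
    cat(sprintf("[03] %s %s: R2X %.2f R2Y %.2f Q2 %.2f | CV-ANOVA p %.2g | AUC %.3f (sens %.2f spec %.2f)\n",
                mode, cmp, s$R2X, s$R2Y, s$Q2, s$cv_anova_p, s$auc,
                s$sensitivity, s$specificity))
  }
}
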