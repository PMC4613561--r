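#' Pipeline configuration
#'
#' Assembles the full run configuration with defaults equal to the standard
#' analysis parameters: 0.004 ppm buckets over 0.5-9.0 ppm, water exclusion
#' 4.20-5.20 ppm, normalization by tissue mode, unit-variance scaled OPLS-DA
#' with one orthogonal component, stratified 7-fold cross-validation,
#' alpha = 0.05, and the pairwise comparisons lesion-vs-healthy and
#' malignant-vs-benign.
#'
#' @param sim A [simulation_config()] describing the synthetic cohort (or
#'   NULL if `spectra` are supplied to [run_pipeline()] directly).
#' @param bucket_width,bucket_range,exclusion Preprocessing parameters (ppm).
#' @param n_ortho Orthogonal components for OPLS-DA.
#' @param K Cross-validation folds.
#' @param alpha Significance level used throughout.
#' @param seed Seed for fold assignment (simulation seeds live in `sim`).
#' @param comparisons Character vector naming the pairwise models to fit.
#' @param fatty_acids,gsh Include the synthetic fatty-acid / GSH analyses.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            bucket_width = 0.004,
                            bucket_range = c(0.5, 9.0),
                            exclusion = c(4.20, 5.20),
                            n_ortho = 1,
                            K = 7,
                            alpha = 0.05,
                            seed = 1L,
                            comparisons = c("lesion-vs-healthy",
                                            "malignant-vs-benign"),
                            fatty_acids = TRUE,
                            gsh = TRUE) {
  assert_that(all(comparisons %in% c("lesion-vs-healthy",
                                     "malignant-vs-benign")),
              "unknown comparison name")
  structure(list(sim = sim, bucket_width = bucket_width,
                 bucket_range = bucket_range, exclusion = exclusion,
                 n_ortho = n_ortho, K = K, alpha = alpha,
                 seed = as.integer(seed), comparisons = comparisons,
                 fatty_acids = fatty_acids, gsh = gsh),
            class = "pipeline_config")
}

# y labels and sample subset for a named comparison on a 3-group cohort.
comparison_design <- function(groups, comparison) {
  if (comparison == "lesion-vs-healthy") {
    idx <- seq_along(groups)
    y <- ifelse(groups == "healthy", "healthy", "lesion")
    positive <- "lesion"
  } else if (comparison == "malignant-vs-benign") {
    idx <- which(groups %in% c("benign", "malignant"))
    y <- groups[idx]
    positive <- "malignant"
  } else {
    stop2("unknown comparison: ", comparison)
  }
  list(idx = idx, y = y, positive = positive)
}

#' Run one OPLS-DA comparison end to end
#'
#' Fits the model, cross-validates it, and derives the CV-ANOVA p, ROC from
#' the cross-validated predictions, the correlation-loadings report and the
#' per-metabolite change table.
#'
#' @param table A normalized `bucket_table` containing the full cohort.
#' @param comparison `"lesion-vs-healthy"` or `"malignant-vs-benign"`.
#' @param config A [pipeline_config()].
#' @param region_map Metabolite region map for the change table.
#' @return List: `comparison`, `model`, `cv`, `anova`, `roc`, `loadings`,
#'   `changes`, `summary`.
#' @export
run_comparison <- function(table, comparison, config = pipeline_config(),
                           region_map = metabolite_regions()) {
  des <- comparison_design(table$groups, comparison)
  sub <- subset_samples(table, des$idx)
  model <- fit_oplsda(sub, des$y, n_ortho = config$n_ortho,
                      positive = des$positive)
  cv <- cross_validate(sub, des$y, n_ortho = config$n_ortho, K = config$K,
                       seed = config$seed, positive = des$positive)
  roc <- roc_curve(des$y, cv$y_pred_cv, positive = des$positive)
  loadings <- correlation_loadings(model, sub, alpha = config$alpha)
  changes <- build_change_table(loadings, region_map, comparison)
  list(comparison = comparison, model = model, cv = cv,
       anova = cv_anova(cv), roc = roc, loadings = loadings,
       changes = changes, summary = model_summary(model, cv, roc))
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> PCA -> per-comparison OPLS-DA with 7-fold CV,
#' CV-ANOVA, ROC, correlation loadings and change tables -> fatty-acid and
#' GSH analyses. When `out_dir` is given, every artifact is written (CSV for
#' tables, JSON for summaries) and a manifest JSON records the configuration,
#' its hash, the seed and every artifact path; reruns with the same
#' configuration and seed are identical apart from the manifest timestamp.
#'
#' @param config A [pipeline_config()].
#' @param spectra Optional list of `nmr_spectrum` objects; by default they
#'   are simulated from `config$sim`.
#' @param out_dir Output directory, or NULL to skip writing.
#' @return List: `pca`, `comparisons` (per-comparison results), `fatty_acids`,
#'   `gsh`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL,
                         out_dir = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  artifacts <- list()
  emit <- function(name, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(path)
      artifacts[[name]] <<- path
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  truth <- NULL
  if (is.null(spectra)) {
    assert_that(!is.null(config$sim), "config$sim required to simulate")
    sim <- generate_spectra(config$sim)
    spectra <- sim$spectra
    truth <- sim$truth
    emit("ground_truth.json", function(p) {
      t <- truth; t$config <- unclass(t$config); write_json_file(t, p)
    })
  }

  tab <- preprocess_spectra(spectra, width = config$bucket_width,
                            range = config$bucket_range,
                            exclusion = config$exclusion)
  emit("bucket_table.csv", function(p) write_bucket_table(tab, p))

  pca <- fit_pca(tab, n_components = 3)
  emit("pca_scores.csv", function(p) {
    utils::write.csv(data.frame(sample_id = tab$sample_ids,
                                group = tab$groups, pca$scores),
                     p, row.names = FALSE)
  })

  # drop comparisons whose groups are absent from the cohort
  comparisons <- Filter(function(cmp) {
    des <- comparison_design(tab$groups, cmp)
    length(unique(des$y)) == 2L
  }, config$comparisons)

  region_map <- metabolite_regions(metabolite_templates(tab$tissue_mode))
  results <- lapply(comparisons, function(cmp) {
    res <- run_comparison(tab, cmp, config, region_map)
    slug <- gsub("[^a-z0-9]+", "_", cmp)
    emit(paste0("summary_", slug, ".json"),
         function(p) write_json_file(res$summary, p))
    emit(paste0("loadings_", slug, ".csv"),
         function(p) utils::write.csv(res$loadings$table, p,
                                      row.names = FALSE))
    emit(paste0("changes_", slug, ".csv"),
         function(p) utils::write.csv(res$changes, p, row.names = FALSE))
    emit(paste0("roc_", slug, ".csv"),
         function(p) utils::write.csv(res$roc$curve, p, row.names = FALSE))
    emit(paste0("cv_", slug, ".csv"),
         function(p) utils::write.csv(
           data.frame(sample_id = tab$sample_ids[comparison_design(
             tab$groups, cmp)$idx],
             y = res$cv$y, y_pred_cv = res$cv$y_pred_cv,
             fold = res$cv$fold_assignment), p, row.names = FALSE))
    res
  })
  names(results) <- comparisons

  fa <- gsh <- NULL
  if (isTRUE(config$fatty_acids) && !is.null(config$sim)) {
    fa_tab <- generate_fatty_acid_table(config$sim)
    fa_sum <- composition_summary(fa_tab)
    fa_pairs <- Filter(function(p) all(p %in% fa_tab$group),
                       list(c("healthy", "benign"),
                            c("benign", "malignant")))
    fa_cmp <- compare_groups(fa_sum, comparisons = fa_pairs,
                             alpha = config$alpha)
    fa <- list(table = fa_tab, summary = fa_sum, comparisons = fa_cmp)
    emit("fatty_acids.csv", function(p) utils::write.csv(fa_tab, p,
                                                         row.names = FALSE))
    emit("fatty_acid_comparisons.csv",
         function(p) utils::write.csv(fa_cmp, p, row.names = FALSE))
    emit("fatty_acid_classes.json", function(p) {
      agg <- stats::aggregate(
        fa_sum$class_percent[, -(1:2)],
        by = list(group = fa_sum$class_percent$group),
        function(v) c(mean = mean(v), sd = stats::sd(v)))
      write_json_file(agg, p)
    })
  }
  if (isTRUE(config$gsh) && !is.null(config$sim)) {
    gt <- generate_gsh_table(config$sim)
    pairs <- list(c("healthy", "benign"), c("healthy", "malignant"),
                  c("benign", "malignant"))
    pairs <- Filter(function(p) all(p %in% gt$group), pairs)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      sel <- gt$group %in% p
      do.call(rbind, lapply(c("GSH", "GSSG"), function(an) {
        tt <- univariate_ttest(gt[[an]][sel], gt$group[sel],
                               alpha = config$alpha)
        data.frame(analyte = an, comparison = paste(p[2], "vs", p[1]),
                   t = tt$t, p = tt$p, significant = tt$significant)
      }))
    }))
    gsh <- list(table = gt, tests = tests)
    emit("gsh_tests.csv", function(p) utils::write.csv(tests, p,
                                                       row.names = FALSE))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("thyrometab")),
    seed = config$seed,
    config = config_as_list(config),
    config_hash = config_hash(config),
    comparisons = comparisons,
    artifacts = artifacts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  emit("manifest.json", function(p) write_json_file(manifest, p))

  list(bucket_table = tab, pca = pca, comparisons = results,
       fatty_acids = fa, gsh = gsh, truth = truth, manifest = manifest)
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out
}

# Stable hash of the configuration: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
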