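# Base-graphics plots for the standard figures: scores plots, coefficient
# (back-scaled loadings) plots colored by |r|, ROC curves, fatty-acid class
# bars. Kept dependency-free; drivers write them to PNG/SVG devices.

#' Scores plot
#'
#' @param scores Samples x >=2 score matrix (PCA scores, or cbind of the
#'   OPLS-DA predictive and first orthogonal score).
#' @param groups Group label per sample.
#' @param xlab,ylab,main Plot annotation.
#' @return Invisibly, NULL.
#' @export
plot_scores <- function(scores, groups, xlab = "component 1",
                        ylab = "component 2", main = "scores") {
  groups <- factor(groups)
  pal <- c("#2166ac", "#b2182b", "#1a9850", "#762a83")
  col <- pal[as.integer(groups)]
  plot(scores[, 1], scores[, 2], col = col, pch = 19, xlab = xlab,
       ylab = ylab, main = main)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::legend("topright", legend = levels(groups),
                   col = pal[seq_along(levels(groups))], pch = 19, bty = "n")
  invisible(NULL)
}

#' Coefficient plot with |r| colormap
#'
#' Back-scaled loading coefficients against chemical shift, colored warm
#' (red) for buckets whose correlation with the predictive score is strong
#' and cold (blue) for weak ones, with the ppm axis reversed as in spectra.
#'
#' @param report A `loadings_report`.
#' @param main Title.
#' @return Invisibly, NULL.
#' @export
plot_coefficients <- function(report, main = "back-scaled loadings") {
  tab <- report$table
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  z <- abs(tab$r)
  col <- grDevices::rgb(ramp(z), maxColorValue = 255)
  plot(tab$center, tab$coefficient, type = "h", col = col,
       xlim = rev(range(tab$center)), xlab = "chemical shift (ppm)",
       ylab = "coefficient", main = main)
  graphics::abline(h = 0, col = "grey60")
  graphics::mtext(sprintf("|r| > %.2f significant (n = %d)",
                          trunc_digits(report$r_crit), report$n),
                  side = 3, cex = 0.8)
  invisible(NULL)
}

#' ROC curve plot
#'
#' @param roc A `roc_curve`.
#' @param main Title.
#' @return Invisibly, NULL.
#' @export
plot_roc <- function(roc, main = "ROC") {
  plot(1 - roc$curve$specificity, roc$curve$sensitivity, type = "s",
       lwd = 2, col = "#b2182b", xlab = "1 - specificity",
       ylab = "sensitivity", main = main, xlim = c(0, 1), ylim = c(0, 1))
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright", sprintf("AUC = %.3f", roc$auc), bty = "n")
  invisible(NULL)
}

#' Fatty-acid class bar plot
#'
#' Group means with SD error bars for each class mol% feature.
#'
#' @param summary A `composition_summary`.
#' @param main Title.
#' @return Invisibly, NULL.
#' @export
plot_fatty_acid_classes <- function(summary, main = "fatty-acid classes") {
  cp <- summary$class_percent
  feats <- setdiff(names(cp), c("sample_id", "group"))
  mu <- t(sapply(feats, function(f) tapply(cp[[f]], cp$group, mean)))
  sdv <- t(sapply(feats, function(f) tapply(cp[[f]], cp$group, stats::sd)))
  bp <- graphics::barplot(t(mu), beside = TRUE, ylab = "mol %",
                          legend.text = colnames(mu), main = main,
                          ylim = c(0, max(mu + sdv) * 1.1))
  graphics::arrows(bp, t(mu) - t(sdv), bp, t(mu) + t(sdv), angle = 90,
                   code = 3, length = 0.02)
  invisible(NULL)
}
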