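#' Metabolite peak templates for the thyroid tissue metabonome
#'
#' Returns the built-in library of 1D 1H resonance templates used by
#' [generate_spectra()]. Each template describes one metabolite as a set of
#' Lorentzian peaks (center in ppm, relative area, half-width in ppm) plus a
#' baseline concentration-scale level. Chemical shifts are standard literature
#' values for aqueous tissue extracts at pH ~7.4; relative areas approximate
#' proton counts of the main resolved multiplets. The set covers the amino
#' acids, choline metabolites (choline, phosphocholine, glycerophosphocholine,
#' phosphoethanolamine), TCA intermediates, lactate, glutathione, taurine,
#' inositols, purine/pyrimidine metabolites, formate and a lipid component
#' typical of thyroid tissue spectra.
#'
#' @param tissue_mode `"intact"` or `"extract"`. Intact tissue keeps broad
#'   lipid envelopes (methyl/methylene/allylic/olefinic resonances with widths
#'   20x the sharp-line default); aqueous extracts lack lipid signals, so the
#'   lipid template is dropped.
#' @param width Default Lorentzian half-width at half-maximum in ppm for sharp
#'   metabolite lines.
#' @return A named list of templates, each a list with `name`, `peaks` (a
#'   data.frame with columns `center`, `relative_area`, `width`) and
#'   `base_level`.
#' @export
metabolite_templates <- function(tissue_mode = c("intact", "extract"),
                                 width = 0.003) {
  tissue_mode <- match.arg(tissue_mode)
  assert_that(is.numeric(width) && width > 0, "width must be > 0")
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], relative_area = m[, 2], width = m[, 3] * width)
  }
  tmpl <- function(name, base_level, peaks) {
    list(name = name, peaks = peaks, base_level = base_level)
  }
  # lipid widths x20: broad macromolecule envelopes survive CPMG only partially
  templates <- list(
    tmpl("lipid", 8, pk(0.90, 3, 20,  1.30, 10, 20,  2.02, 2, 20,  5.32, 1, 20)),
    tmpl("isoleucine", 0.6, pk(0.94, 3, 1,  1.01, 3, 1)),
    tmpl("leucine", 0.8, pk(0.96, 6, 1,  1.71, 3, 1)),
    tmpl("valine", 0.7, pk(0.99, 3, 1,  1.04, 3, 1)),
    tmpl("lactate", 3.0, pk(1.33, 3, 1,  4.12, 1, 1)),
    tmpl("threonine", 0.5, pk(1.32, 3, 1,  3.58, 1, 1)),
    tmpl("alanine", 1.2, pk(1.48, 3, 1,  3.78, 1, 1)),
    tmpl("lysine", 0.8, pk(1.72, 2, 1,  1.91, 2, 1,  3.03, 2, 1)),
    tmpl("arginine", 0.6, pk(1.68, 2, 1,  1.92, 2, 1,  3.24, 2, 1)),
    tmpl("acetate", 0.8, pk(1.92, 3, 1)),
    tmpl("glutamate", 1.5, pk(2.08, 2, 1,  2.35, 2, 1)),
    tmpl("methionine", 0.4, pk(2.14, 3, 1,  2.64, 2, 1)),
    tmpl("glutamine", 1.2, pk(2.14, 2, 1,  2.45, 2, 1)),
    tmpl("aspartate", 0.8, pk(2.68, 1, 1,  2.81, 1, 1)),
    tmpl("glutathione", 1.0, pk(2.17, 2, 1,  2.55, 2, 1,  2.95, 2, 1)),
    tmpl("choline", 1.0, pk(3.20, 9, 1)),
    tmpl("phosphocholine", 1.2, pk(3.22, 9, 1)),
    tmpl("glycerophosphocholine", 1.2, pk(3.23, 9, 1)),
    tmpl("taurine", 1.8, pk(3.26, 2, 1,  3.42, 2, 1)),
    tmpl("scyllo-inositol", 0.6, pk(3.35, 6, 1)),
    tmpl("myo-inositol", 1.6, pk(3.28, 1, 1,  3.54, 2, 1,  3.62, 2, 1,  4.06, 1, 1)),
    tmpl("glycine", 1.0, pk(3.56, 2, 1)),
    tmpl("phosphoethanolamine", 0.9, pk(3.22, 2, 1,  3.98, 2, 1)),
    tmpl("inosine", 0.4, pk(6.10, 1, 1,  8.24, 1, 1,  8.34, 1, 1)),
    tmpl("tyrosine", 0.4, pk(6.90, 2, 1,  7.19, 2, 1)),
    tmpl("phenylalanine", 0.4, pk(7.33, 2, 1,  7.42, 3, 1)),
    tmpl("histidine", 0.3, pk(7.09, 1, 1,  7.91, 1, 1)),
    tmpl("fumarate", 0.3, pk(6.52, 2, 1)),
    tmpl("uracil", 0.3, pk(5.80, 1, 1,  7.54, 1, 1)),
    tmpl("guanosine", 0.2, pk(5.92, 1, 1,  8.00, 1, 1)),
    tmpl("hypoxanthine", 0.3, pk(8.19, 1, 1,  8.21, 1, 1)),
    tmpl("xanthine", 0.2, pk(7.90, 1, 1)),
    tmpl("formate", 0.3, pk(8.46, 1, 1)),
    tmpl("acetamide", 0.4, pk(2.01, 3, 1)),
    tmpl("succinate", 0.7, pk(2.41, 4, 1)),
    tmpl("citrate", 0.9, pk(2.54, 2, 1,  2.67, 2, 1)),
    tmpl("uridine", 0.3, pk(5.90, 1, 1,  7.87, 1, 1)),
    tmpl("U1", 0.3, pk(7.68, 1, 1))
  )
  names(templates) <- vapply(templates, `[[`, "", "name")
  if (tissue_mode == "extract") {
    templates <- templates[names(templates) != "lipid"]
  }
  for (t in templates) validate_template(t)
  templates
}

validate_template <- function(template) {
  assert_that(is.character(template$name) && nzchar(template$name),
              "template needs a non-empty name")
  p <- template$peaks
  assert_that(is.data.frame(p) && nrow(p) >= 1L,
              sprintf("template '%s' needs at least one peak", template$name))
  assert_that(all(p$center >= 0.5 & p$center <= 9.0),
              sprintf("template '%s': peak centers must lie in 0.5-9.0 ppm",
                      template$name))
  assert_that(all(p$width > 0) && all(p$relative_area >= 0),
              sprintf("template '%s': widths must be > 0, areas >= 0",
                      template$name))
  assert_that(is.numeric(template$base_level) && template$base_level >= 0,
              sprintf("template '%s': base_level must be >= 0", template$name))
  invisible(template)
}

#' Default planted group effects
#'
#' The default effect specification planted by [generate_spectra()]: the
#' direction each metabolite moves in the lesion-vs-healthy and the
#' malignant-vs-benign comparison, as fractional changes in the group median
#' level. Directions follow the published pattern for thyroid lesions
#' (elevated lactate, amino acids, choline metabolites, taurine, inositols and
#' glutathione with depleted lipid in lesions; elevated lactate, choline
#' phosphometabolites and amino acids with depleted citrate, inositols,
#' inosine and uridine in malignant vs benign nodules). Magnitudes are a
#' uniform 0.5 (50% median shift), chosen for testability — the source data
#' report only signs and correlation coefficients, not effect sizes.
#'
#' @param magnitude Absolute fractional change applied in the stated
#'   direction; default 0.5.
#' @return A data.frame with columns `metabolite`, `comparison`
#'   (`"lesion-vs-healthy"` or `"malignant-vs-benign"`), `direction`
#'   (+1/-1/0) and `magnitude` (signed fractional change).
#' @export
default_effect_specs <- function(magnitude = 0.5) {
  assert_that(is.numeric(magnitude) && magnitude > -1,
              "magnitude must be a number > -1")
  lh_up <- c("isoleucine", "leucine", "valine", "alanine", "lysine",
             "arginine", "glutamate", "methionine", "glutamine", "glycine",
             "tyrosine", "phenylalanine", "choline", "phosphocholine",
             "glycerophosphocholine", "phosphoethanolamine", "lactate",
             "glutathione", "taurine", "myo-inositol", "inosine", "fumarate",
             "U1")
  lh_down <- "lipid"
  mb_up <- c("isoleucine", "leucine", "valine", "alanine", "lysine",
             "arginine", "glutamate", "methionine", "phenylalanine",
             "phosphocholine", "glycerophosphocholine",
             "phosphoethanolamine", "lactate")
  mb_down <- c("citrate", "scyllo-inositol", "myo-inositol", "inosine",
               "uridine")
  spec <- rbind(
    data.frame(metabolite = lh_up, comparison = "lesion-vs-healthy",
               direction = 1),
    data.frame(metabolite = lh_down, comparison = "lesion-vs-healthy",
               direction = -1),
    data.frame(metabolite = mb_up, comparison = "malignant-vs-benign",
               direction = 1),
    data.frame(metabolite = mb_down, comparison = "malignant-vs-benign",
               direction = -1)
  )
  spec$magnitude <- spec$direction * abs(magnitude)
  spec
}

validate_effects <- function(effects, templates) {
  needed <- c("metabolite", "comparison", "direction", "magnitude")
  assert_that(is.data.frame(effects) && all(needed %in% names(effects)),
              "effects must be a data.frame with metabolite/comparison/direction/magnitude")
  unknown <- setdiff(effects$metabolite, names(templates))
  if (length(unknown) > 0L) {
    stop2("effects reference unknown metabolites: ",
          paste(unknown, collapse = ", "))
  }
  assert_that(all(effects$comparison %in%
                    c("lesion-vs-healthy", "malignant-vs-benign")),
              "comparison must be lesion-vs-healthy or malignant-vs-benign")
  ok <- (effects$direction == 0 & effects$magnitude == 0) |
    (sign(effects$magnitude) == effects$direction)
  assert_that(all(ok),
              "effect direction and magnitude signs disagree (magnitude 0 iff direction 0)")
  invisible(effects)
}

#' Metabolite chemical-shift region map
#'
#' ppm regions associated with each metabolite, used by
#' [build_change_table()] to roll bucket-level correlation loadings up to a
#' per-metabolite change report. The shipped map is derived from the peak
#' templates (each peak center +/- `pad`); an edited map can be supplied as a
#' CSV with columns `metabolite`, `low`, `high`.
#'
#' @param templates Template list, as from [metabolite_templates()].
#' @param pad Half-width of the region around each peak center, ppm.
#' @return data.frame with columns `metabolite`, `low`, `high` (ppm).
#' @export
metabolite_regions <- function(templates = metabolite_templates("intact"),
                               pad = 0.01) {
  do.call(rbind, lapply(templates, function(t) {
    data.frame(metabolite = t$name,
               low = t$peaks$center - pad,
               high = t$peaks$center + pad,
               row.names = NULL)
  }))
}
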