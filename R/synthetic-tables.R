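# Baseline fatty-acid concentrations, umol per g tissue. Plausible human
# soft-tissue values covering every species reported for thyroid tissue
# (C14:0 ... C22:6n3) plus the D6D index precursor/product pair.
fatty_acid_baselines <- function() {
  c("C14:0" = 2.0, "C16:0" = 25, "C16:1n7" = 3.0, "C18:0" = 12,
    "C18:1n9" = 20, "C18:2n6" = 15, "C18:3n6" = 0.3, "C18:3n3" = 0.5,
    "C20:1n9" = 0.5, "C20:3n6" = 1.5, "C20:4n6" = 8.0, "C20:5n3" = 0.8,
    "C22:6n3" = 2.5)
}

#' Default planted fatty-acid effects
#'
#' Fractional shifts planted by [generate_fatty_acid_table()], mirroring the
#' reported composition changes: benign lesions carry more saturated and
#' fewer mono-/unsaturated fatty acids than healthy tissue (with the
#' individual species moves C14:0/C16:1n7/C18:1n9/C20:1n9/C18:3n3 down and
#' C16:0/C18:0/C20:3n6/C20:4n6/C22:6n3 up), and malignant nodules carry more
#' C14:0, C16:0 and C18:3n3 but less C20:3n6 than benign ones; the D6D
#' product C18:3n6 is elevated in lesions.
#'
#' @param magnitude Base fractional shift magnitude (default 0.2, i.e. 20%).
#' @return data.frame with columns `target` (species name or class name among
#'   SFA/MUFA/PUFA/n3/n6), `comparison`, `shift` (signed fraction).
#' @export
default_fatty_acid_effects <- function(magnitude = 0.2) {
  rbind(
    data.frame(target = c("C14:0", "C16:1n7", "C18:1n9", "C20:1n9", "C18:3n3"),
               comparison = "lesion-vs-healthy", shift = -magnitude),
    data.frame(target = c("C16:0", "C18:0", "C20:3n6", "C20:4n6", "C22:6n3",
                          "C18:3n6"),
               comparison = "lesion-vs-healthy", shift = magnitude),
    data.frame(target = c("C14:0", "C16:0", "C18:3n3"),
               comparison = "malignant-vs-benign", shift = magnitude),
    data.frame(target = "C20:3n6",
               comparison = "malignant-vs-benign", shift = -magnitude)
  )
}

#' Generate a synthetic fatty-acid concentration table
#'
#' Draws per-sample fatty-acid concentrations (umol/g tissue) log-normally
#' around group medians, with planted fractional shifts applied per species
#' or per class (a class-level target shifts every member species). Species
#' names use the Cx:yn-z convention parsed by [classify_species()].
#'
#' @param config A [simulation_config()] (group sizes, seed and `level_sdlog`
#'   are used).
#' @param effects Planted shift table, as [default_fatty_acid_effects()].
#' @param baselines Named vector of healthy-group median concentrations.
#' @return A `fatty_acid_table`: data.frame with `sample_id`, `group`, then
#'   one column per species; ground truth attached as attribute `"truth"`.
#' @export
generate_fatty_acid_table <- function(config,
                                      effects = default_fatty_acid_effects(),
                                      baselines = fatty_acid_baselines()) {
  assert_that(inherits(config, "sim_config"),
              "config must come from simulation_config()")
  assert_that(all(c("target", "comparison", "shift") %in% names(effects)),
              "effects must have target/comparison/shift columns")
  assert_that(all(effects$shift > -1),
              "a shift <= -100% would make a mean concentration non-positive")
  species <- names(baselines)
  cls <- lapply(species, classify_species)  # validates names

  # expand class-level targets to member species
  class_of <- vapply(cls, `[[`, "", "saturation")
  family_of <- vapply(cls, `[[`, "", "family")
  expand <- function(target) {
    if (target %in% species) return(target)
    hit <- switch(target,
                  SFA = species[class_of == "SFA"],
                  MUFA = species[class_of == "MUFA"],
                  PUFA = species[class_of == "PUFA"],
                  UFA = species[class_of != "SFA"],
                  n3 = species[family_of == "n3"],
                  n6 = species[family_of == "n6"],
                  n9 = species[family_of == "n9"],
                  stop2("unknown effect target: ", target))
    hit
  }

  mult <- matrix(1, nrow = length(species), ncol = 3,
                 dimnames = list(species, c("healthy", "benign", "malignant")))
  for (i in seq_len(nrow(effects))) {
    sp <- expand(effects$target[i])
    f <- 1 + effects$shift[i]
    if (effects$comparison[i] == "lesion-vs-healthy") {
      mult[sp, c("benign", "malignant")] <- mult[sp, c("benign", "malignant")] * f
    } else if (effects$comparison[i] == "malignant-vs-benign") {
      mult[sp, "malignant"] <- mult[sp, "malignant"] * f
    } else {
      stop2("unknown comparison: ", effects$comparison[i])
    }
  }

  set.seed(config$seed + 1L)  # distinct stream from the spectrum generator
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  med <- t(mult[, groups, drop = FALSE]) * rep(baselines, each = n)
  conc <- med * exp(matrix(stats::rnorm(n * length(species),
                                        sd = config$level_sdlog), nrow = n))
  dimnames(conc) <- NULL
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = groups,
                    conc, check.names = FALSE)
  names(out)[-(1:2)] <- species
  structure(out, class = c("fatty_acid_table", "data.frame"),
            truth = list(effects = effects, multipliers = mult))
}

#' Generate a synthetic glutathione (GSH/GSSG) concentration table
#'
#' Emulates the reduced/oxidized glutathione assay: GSH elevated in both
#' lesion groups relative to healthy tissue (default +60%) with no
#' benign-malignant difference, GSSG flat across groups.
#'
#' @param config A [simulation_config()].
#' @param gsh_lesion_shift Fractional GSH elevation in lesion groups.
#' @return data.frame with columns `sample_id`, `group`, `GSH`, `GSSG`
#'   (umol/g).
#' @export
generate_gsh_table <- function(config, gsh_lesion_shift = 0.6) {
  assert_that(inherits(config, "sim_config"),
              "config must come from simulation_config()")
  assert_that(gsh_lesion_shift > -1, "shift must be > -100%")
  set.seed(config$seed + 2L)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  gsh_med <- ifelse(groups == "healthy", 1.0, 1.0 * (1 + gsh_lesion_shift))
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = groups,
             GSH = gsh_med * exp(stats::rnorm(n, sd = config$level_sdlog)),
             GSSG = 0.2 * exp(stats::rnorm(n, sd = config$level_sdlog)))
}
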