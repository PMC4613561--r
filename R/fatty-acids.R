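#' Parse and classify a fatty-acid species name
#'
#' Names follow the Cx:y or Cx:ynZ convention (chain length, double-bond
#' count, omega family): 0 double bonds is saturated (SFA), 1 is
#' monounsaturated (MUFA), 2+ polyunsaturated (PUFA); the `nZ` suffix gives
#' the omega family (n3/n6/n7/n9...).
#'
#' @param name Species name, e.g. `"C18:1n9"`.
#' @return List with `carbons`, `double_bonds`, `saturation`
#'   (`SFA`/`MUFA`/`PUFA`) and `family` (`n3`, `n6`, ..., or `"none"`).
#' @examples
#' classify_species("C16:0")    # SFA, none
#' classify_species("C22:6n3")  # PUFA, n3
#' @export
classify_species <- function(name) {
  m <- regmatches(name, regexec("^C([0-9]+):([0-9]+)(n([0-9]+))?$", name))[[1]]
  if (length(m) == 0L) {
    stop2("unparseable fatty-acid name: '", name,
          "' (expected Cx:y or Cx:ynZ)")
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  family <- if (nzchar(m[4])) paste0("n", m[5]) else "none"
  if (db == 0L && family != "none") {
    stop2("saturated species '", name, "' cannot carry an omega family")
  }
  list(carbons = carbons, double_bonds = db,
       saturation = if (db == 0L) "SFA" else if (db == 1L) "MUFA" else "PUFA",
       family = family)
}

#' Per-sample composition summary of a fatty-acid table
#'
#' Converts concentrations (umol/g) to molar percentages per sample, rolls
#' them up into class percentages (SFA, UFA, MUFA, PUFA, and the n3/n6
#' families), and computes desaturase indices. The delta-6 desaturase (D6D)
#' activity index is the product/precursor concentration ratio
#' C18:3n6 / C18:2n6 — the standard estimated-desaturase-activity convention;
#' `d6d_alternative = TRUE` uses C20:3n6 / C18:2n6 (product one elongation
#' step downstream) instead. The index is NA where the precursor is absent.
#'
#' @param table A `fatty_acid_table` (data.frame with `sample_id`, `group`,
#'   then one column per species).
#' @param d6d_alternative Use the C20:3n6-based D6D index.
#' @return A `composition_summary`: `mol_percent` (per-sample species mol%),
#'   `class_percent` (per-sample SFA/UFA/MUFA/PUFA/n3/n6 mol%),
#'   `concentrations` (the input umol/g species levels), `class_conc`
#'   (umol/g class roll-ups) and `indices` (per-sample D6D), each carrying
#'   `sample_id` and `group` columns.
#' @export
composition_summary <- function(table, d6d_alternative = FALSE) {
  assert_that(all(c("sample_id", "group") %in% names(table)),
              "table needs sample_id and group columns")
  species <- setdiff(names(table), c("sample_id", "group"))
  assert_that(length(species) >= 1, "no species columns found")
  conc <- as.matrix(table[, species, drop = FALSE])
  assert_that(all(conc >= 0), "concentrations must be >= 0")
  tot <- rowSums(conc)
  if (any(tot <= 0)) stop2("zero total concentration in sample(s): ",
                           paste(table$sample_id[tot <= 0], collapse = ", "))
  molp <- 100 * conc / tot

  cls <- lapply(species, classify_species)
  sat <- vapply(cls, `[[`, "", "saturation")
  fam <- vapply(cls, `[[`, "", "family")
  roll <- function(mask) if (any(mask)) rowSums(molp[, mask, drop = FALSE])
  else rep(0, nrow(molp))
  class_percent <- data.frame(
    sample_id = table$sample_id, group = table$group,
    SFA = roll(sat == "SFA"),
    UFA = roll(sat != "SFA"),
    MUFA = roll(sat == "MUFA"),
    PUFA = roll(sat == "PUFA"),
    n3 = roll(fam == "n3"),
    n6 = roll(fam == "n6")
  )

  roll_conc <- function(mask) if (any(mask))
    rowSums(conc[, mask, drop = FALSE]) else rep(0, nrow(conc))
  class_conc <- data.frame(
    sample_id = table$sample_id, group = table$group,
    SFA = roll_conc(sat == "SFA"),
    UFA = roll_conc(sat != "SFA"),
    MUFA = roll_conc(sat == "MUFA"),
    PUFA = roll_conc(sat == "PUFA"),
    n3 = roll_conc(fam == "n3"),
    n6 = roll_conc(fam == "n6")
  )

  product <- if (d6d_alternative) "C20:3n6" else "C18:3n6"
  d6d <- if (all(c(product, "C18:2n6") %in% species)) {
    denom <- conc[, "C18:2n6"]
    ifelse(denom > 0, conc[, product] / denom, NA_real_)
  } else {
    rep(NA_real_, nrow(conc))
  }
  structure(list(mol_percent = data.frame(sample_id = table$sample_id,
                                          group = table$group, molp,
                                          check.names = FALSE),
                 class_percent = class_percent,
                 concentrations = data.frame(sample_id = table$sample_id,
                                             group = table$group, conc,
                                             check.names = FALSE),
                 class_conc = class_conc,
                 indices = data.frame(sample_id = table$sample_id,
                                      group = table$group, D6D = d6d)),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %d samples, %d species; classes: SFA/UFA/MUFA/PUFA/n3/n6; D6D index\n",
              nrow(x$class_percent), ncol(x$mol_percent) - 2L))
  invisible(x)
}

#' Pairwise group comparisons of fatty-acid features
#'
#' Per-feature two-sided Student's t-tests for the two clinically relevant
#' contrasts (benign vs healthy, malignant vs benign by default). Features
#' are the reported fatty-acid levels — species concentrations (umol/g) and
#' class concentration roll-ups — plus the D6D index; molar percentages stay
#' descriptive in the summary. Flags use a per-feature alpha with no
#' multiplicity correction, matching the per-feature p < 0.05 reporting
#' convention; Benjamini-Hochberg adjusted flags are available via
#' `adjust = "BH"`.
#'
#' @param summary A `composition_summary`.
#' @param comparisons List of 2-vectors `c(reference, case)` of group names.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param var_equal Student (TRUE, default) or Welch (FALSE) t-test.
#' @return data.frame with `feature`, `comparison`, `mean_ref`, `mean_case`,
#'   `difference`, `t`, `p`, `significant`.
#' @export
compare_groups <- function(summary,
                           comparisons = list(c("healthy", "benign"),
                                              c("benign", "malignant")),
                           alpha = 0.05, adjust = "none", var_equal = TRUE) {
  assert_that(inherits(summary, "composition_summary"),
              "summary must come from composition_summary()")
  feats <- cbind(summary$concentrations[, -(1:2), drop = FALSE],
                 summary$class_conc[, -(1:2), drop = FALSE],
                 D6D = summary$indices$D6D)
  group <- summary$class_percent$group
  rows <- list()
  for (cmp in comparisons) {
    assert_that(length(cmp) == 2L, "each comparison must name two groups")
    missing <- setdiff(cmp, unique(group))
    if (length(missing)) stop2("group(s) absent from table: ",
                               paste(missing, collapse = ", "))
    sel <- group %in% cmp
    for (f in names(feats)) {
      v <- feats[[f]][sel]
      g <- group[sel]
      if (anyNA(v)) { g <- g[!is.na(v)]; v <- v[!is.na(v)] }
      if (length(unique(g)) < 2L || min(table(g)) < 2L) next
      v1 <- v[g == cmp[1]]; v2 <- v[g == cmp[2]]
      # essentially-constant features carry no evidence unless their
      # constants differ
      ht <- tryCatch(stats::t.test(v2, v1, var.equal = var_equal),
                     error = function(e) {
                       same <- isTRUE(all.equal(mean(v1), mean(v2)))
                       list(statistic = c(t = if (same) 0 else Inf),
                            p.value = if (same) 1 else 0)
                     })
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, comparison = paste(cmp[2], "vs", cmp[1]),
        mean_ref = mean(v[g == cmp[1]]), mean_case = mean(v[g == cmp[2]]),
        difference = mean(v[g == cmp[2]]) - mean(v[g == cmp[1]]),
        t = unname(ht$statistic), p = ht$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- stats::p.adjust(out$p, method = adjust) < alpha
  out
}
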