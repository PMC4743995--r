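# End-to-end driver: annotation -> differential analysis -> screens.

#' Compound-level fold-change matrix
#'
#' The differential table has one row per metabolite ion (a compound may be
#' measured by several features — the 13C isotopologue or nearby features).
#' For the screens, which operate per metabolite, rows of one compound are
#' averaged.
#'
#' @param fc A [differential_analysis()] result.
#' @param level Stress level (default `"IC50"`, the high-stress condition
#'   used by both screens).
#' @return Compound-by-organism matrix of log2 fold-changes.
#' @export
compound_fc_matrix <- function(fc, level = "IC50") {
  fc <- fc[fc$stress_level == level, , drop = FALSE]
  comps <- unique(fc$compound_id); orgs <- unique(fc$organism_id)
  m <- matrix(NA_real_, length(comps), length(orgs),
              dimnames = list(comps, orgs))
  agg <- tapply(fc$log2fc, list(fc$compound_id, fc$organism_id),
                function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  m[rownames(agg), colnames(agg)] <- agg
  m
}

#' Run the full metabolomics pipeline on a pair of ion tables
#'
#' Annotates both phase tables against the library, merges extracts by logP,
#' runs the differential analysis, and applies both screens to the
#' compound-level IC50 fold-change matrix.
#'
#' @param polar,nonpolar [ion_table()]s of the two extract phases.
#' @param lib A [compound_library()].
#' @param meta Organism metadata with `organism_id`, `taxonomy_group`,
#'   `habitat`, `cell_wall`, `ic50`.
#' @param tolerance Annotation mass tolerance in Da (default 0.005).
#' @param fc_threshold,alpha Differential-call thresholds.
#' @param min_species,r_cut,x_cut Tolerance-screen thresholds.
#' @param anova_p_cut,anova_fc_cut,top_k ANOVA-screen thresholds.
#' @return List of class `salt_screens`: `metab` (merged metabolite table),
#'   `fc` (differential table), `fc_ic50` (compound-level matrix), `anova`,
#'   `anova_hits`, `tolerance` (screen results).
#' @export
run_salt_screens <- function(polar, nonpolar, lib, meta, tolerance = 0.005,
                             fc_threshold = 1, alpha = 0.05,
                             min_species = 10, r_cut = 0.5, x_cut = 1,
                             anova_p_cut = 0.01, anova_fc_cut = 1,
                             top_k = 40) {
  metab <- suppressMessages(
    merge_extracts(polar, nonpolar, lib = lib, tolerance = tolerance))
  fc <- differential_analysis(metab, fc_threshold = fc_threshold,
                              alpha = alpha)
  fc_ic50 <- compound_fc_matrix(fc, level = "IC50")
  fc_ic50 <- fc_ic50[, intersect(colnames(fc_ic50), meta$organism_id),
                     drop = FALSE]
  anova <- fourway_anova(fc_ic50, meta)
  hits <- select_anova_hits(anova, p_cut = anova_p_cut, fc_cut = anova_fc_cut,
                            top_k = top_k)
  ic50 <- stats::setNames(meta$ic50, meta$organism_id)
  tol <- tolerance_screen(fc_ic50, ic50, min_species = min_species,
                          r_cut = r_cut, x_cut = x_cut)
  structure(list(metab = metab, fc = fc, fc_ic50 = fc_ic50, anova = anova,
                 anova_hits = hits, tolerance = tol),
            class = "salt_screens")
}

#' @export
print.salt_screens <- function(x, ...) {
  cat("salt-stress metabolomics screens\n")
  print(x$metab)
  cat(sprintf("  differential records: %d (%d called differential)\n",
              nrow(x$fc), sum(x$fc$differential, na.rm = TRUE)))
  cat(sprintf("  ANOVA hit union: %d metabolites\n", x$anova_hits$n_union))
  print(x$tolerance)
  invisible(x)
}
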