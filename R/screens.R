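# Hit-finding screens: four-way ANOVA factor screen and the salt-tolerance
# correlation screen.

screen_factors <- c("taxonomy_group", "habitat", "cell_wall", "tolerance")

#' Four-way ANOVA factor screen
#'
#' Per metabolite, fits a main-effects-only linear model of the IC50-level
#' log2 fold-changes across organisms on four categorical factors —
#' taxonomic group, habitat, cell-wall class and tolerance class (the
#' [tolerance_class()] binning of IC50) — and tests each factor by the
#' partial (added-last) sum of squares with an F test. Organisms missing the
#' metabolite are dropped per metabolite (complete-case); a factor left with
#' fewer than two levels, or aliased with the others, is marked untestable
#' (`NA`) for that metabolite. Group means and standard errors are computed
#' directly from member organisms.
#'
#' @param fc_ic50 Metabolite-by-organism matrix of log2 fold-changes at IC50
#'   (rows named by metabolite, columns by organism id).
#' @param meta Organism metadata data frame with columns `organism_id`,
#'   `taxonomy_group`, `habitat`, `cell_wall` and `ic50` (mM).
#' @return List of class `anova_screen`: `results` (one row per metabolite:
#'   `p_<factor>` and `maxfc_<factor>`, the largest absolute group-mean
#'   fold-change of that factor, plus `n_organisms`), and `group_means`
#'   (long data frame of per-group means and standard errors).
#' @export
fourway_anova <- function(fc_ic50, meta) {
  stopifnot(is.matrix(fc_ic50),
            all(c("organism_id", "taxonomy_group", "habitat", "cell_wall",
                  "ic50") %in% names(meta)))
  orgs <- colnames(fc_ic50)
  if (is.null(orgs) || !all(orgs %in% meta$organism_id)) {
    stop("every fc_ic50 column must have a metadata row")
  }
  meta <- meta[match(orgs, meta$organism_id), , drop = FALSE]
  fac <- data.frame(taxonomy_group = factor(meta$taxonomy_group),
                    habitat = factor(meta$habitat),
                    cell_wall = factor(meta$cell_wall),
                    tolerance = tolerance_class(meta$ic50))
  res <- list(); gm <- list()
  for (mi in seq_len(nrow(fc_ic50))) {
    y <- fc_ic50[mi, ]
    keep <- is.finite(y)
    met <- rownames(fc_ic50)[mi]
    row <- data.frame(metabolite = met, n_organisms = sum(keep))
    d <- droplevels(data.frame(y = y[keep], fac[keep, , drop = FALSE]))
    testable <- vapply(screen_factors, function(f) nlevels(d[[f]]) >= 2L,
                       logical(1))
    pvals <- stats::setNames(rep(NA_real_, length(screen_factors)),
                             screen_factors)
    if (any(testable) && stats::var(d$y) == 0) {
      # constant response: no factor explains anything (F = 0)
      pvals[testable] <- 1
    } else if (any(testable) &&
        sum(keep) > sum(vapply(screen_factors[testable],
                               function(f) nlevels(d[[f]]) - 1L,
                               integer(1))) + 1L) {
      fml <- stats::reformulate(screen_factors[testable], response = "y")
      fit <- stats::lm(fml, data = d)
      if (stats::df.residual(fit) >= 1L) {
        dr <- stats::drop1(fit, test = "F")
        for (f in screen_factors[testable]) {
          if (f %in% rownames(dr) && !is.na(dr[f, "Df"]) && dr[f, "Df"] >= 1) {
            pvals[f] <- dr[f, "Pr(>F)"]
          }
        }
      }
    }
    for (f in screen_factors) {
      means <- tapply(d$y, d[[f]], mean)
      ses <- tapply(d$y, d[[f]], function(v) stats::sd(v) / sqrt(length(v)))
      row[[paste0("p_", f)]] <- pvals[[f]]
      row[[paste0("maxfc_", f)]] <- if (length(means)) max(abs(means)) else NA_real_
      gm[[paste(met, f)]] <- data.frame(metabolite = met, factor = f,
                                        group = names(means),
                                        mean_log2fc = as.numeric(means),
                                        se = as.numeric(ses),
                                        n = as.numeric(table(d[[f]])),
                                        stringsAsFactors = FALSE)
    }
    res[[mi]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  gmeans <- do.call(rbind, gm)
  rownames(gmeans) <- NULL
  structure(list(results = out, group_means = gmeans,
                 factors = screen_factors),
            class = "anova_screen")
}

#' @method print anova_screen
#' @export
print.anova_screen <- function(x, ...) {
  cat(sprintf("four-way ANOVA screen: %d metabolites x factors (%s)\n",
              nrow(x$results), paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' Select ANOVA screen hits
#'
#' A metabolite is a hit for a factor when that factor's ANOVA p-value is
#' below `p_cut` and the largest absolute group-mean log2 fold-change of the
#' factor exceeds `fc_cut`. Per factor, hits are sorted by ascending p-value
#' and the reported list truncated to `top_k`; the union across factors is
#' counted before truncation.
#'
#' @param screen A [fourway_anova()] result.
#' @param p_cut ANOVA p-value cut-off (default 0.01).
#' @param fc_cut Group-mean absolute log2 fold-change cut-off (default 1).
#' @param top_k Hits reported per factor (default 40).
#' @return List with `per_factor` (named list of data frames, ranked,
#'   truncated), `n_per_factor` (untruncated counts), `union` (metabolite
#'   ids) and `n_union`.
#' @export
select_anova_hits <- function(screen, p_cut = 0.01, fc_cut = 1, top_k = 40) {
  res <- screen$results
  per_factor <- list(); union_ids <- character(0); n_pf <- integer(0)
  for (f in screen$factors) {
    p <- res[[paste0("p_", f)]]
    mf <- res[[paste0("maxfc_", f)]]
    pass <- which(!is.na(p) & p < p_cut & !is.na(mf) & mf > fc_cut)
    pass <- pass[order(p[pass])]
    union_ids <- union(union_ids, res$metabolite[pass])
    n_pf[f] <- length(pass)
    per_factor[[f]] <- data.frame(metabolite = res$metabolite[pass],
                                  p = p[pass], max_abs_group_fc = mf[pass],
                                  stringsAsFactors = FALSE)[
                                    seq_len(min(length(pass), top_k)), ,
                                    drop = FALSE]
  }
  list(per_factor = per_factor, n_per_factor = n_pf,
       union = union_ids, n_union = length(union_ids))
}

#' Salt-tolerance correlation screen
#'
#' Per metabolite, correlates the high-stress (IC50-level) log2 fold-changes
#' across organisms with the organisms' IC50 values (Pearson's R) and
#' summarizes the response magnitude by the upper quartile x0.75 of the
#' absolute fold-changes over the same organisms (linear interpolation
#' between order statistics, position `1 + 0.75 (n - 1)`). A metabolite is a
#' hit when it is detected in more than `min_species` organisms, `x0.75 >
#' x_cut` and `|R| > r_cut`; hits are classed `anticorrelating` (R < -r_cut)
#' or `correlating` (R > r_cut). Metabolites detected in fewer than 3
#' organisms have undefined R and are excluded from correlation.
#'
#' @param fc_ic50 Metabolite-by-organism matrix of IC50-level log2
#'   fold-changes.
#' @param ic50 Named vector of organism IC50 values (mM); every organism
#'   contributing a fold-change must have one.
#' @param min_species Detection threshold, strict (default 10: detected in
#'   more than 10, i.e. at least 11, organisms).
#' @param r_cut Absolute Pearson-R threshold (default 0.5).
#' @param x_cut x0.75 threshold (default 1).
#' @return Data frame of class `tolerance_screen`: `metabolite`,
#'   `n_detected`, `r`, `x075`, `hit`, `direction`.
#' @export
tolerance_screen <- function(fc_ic50, ic50, min_species = 10, r_cut = 0.5,
                             x_cut = 1) {
  stopifnot(is.matrix(fc_ic50))
  orgs <- colnames(fc_ic50)
  if (is.null(names(ic50)) || !all(orgs %in% names(ic50))) {
    stop("every organism needs an ic50 value")
  }
  if (any(is.na(ic50[orgs]))) stop("missing ic50 value(s)")
  ic <- ic50[orgs]
  out <- lapply(seq_len(nrow(fc_ic50)), function(mi) {
    y <- fc_ic50[mi, ]
    keep <- is.finite(y)
    n <- sum(keep)
    r <- if (n >= 3L) suppressWarnings(stats::cor(y[keep], ic[keep])) else NA_real_
    x075 <- if (n >= 1L) {
      stats::quantile(abs(y[keep]), 0.75, type = 7, names = FALSE)
    } else NA_real_
    hit <- !is.na(r) & n > min_species & x075 > x_cut & abs(r) > r_cut
    data.frame(metabolite = rownames(fc_ic50)[mi], n_detected = n,
               r = r, x075 = x075, hit = hit,
               direction = if (!hit) "none" else
                 if (r < 0) "anticorrelating" else "correlating",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tolerance_screen", "data.frame")
  res
}

#' @method print tolerance_screen
#' @export
print.tolerance_screen <- function(x, ...) {
  cat(sprintf("tolerance screen: %d metabolites, %d hits (%d anticorrelating, %d correlating)\n",
              nrow(x), sum(x$hit), sum(x$direction == "anticorrelating"),
              sum(x$direction == "correlating")))
  invisible(x)
}

#' @method plot tolerance_screen
#' @export
plot.tolerance_screen <- function(x, r_cut = 0.5, x_cut = 1, ...) {
  col <- ifelse(x$direction == "anticorrelating", "dodgerblue3",
                ifelse(x$direction == "correlating", "deeppink3", "grey60"))
  graphics::plot(x$r, x$x075, col = col, pch = 16,
                 xlab = "Pearson R (log2 FC vs IC50)",
                 ylab = expression(x[0.75] ~ "of |log2 FC|"), ...)
  graphics::abline(v = c(-r_cut, r_cut), h = x_cut, lty = 3, col = "grey40")
  invisible(x)
}
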