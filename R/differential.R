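# Normalization, fold-changes, testing and FDR.
#
# Intensities are quantile-normalized per organism and extract phase (the
# normalization corrects biomass differences between samples of one
# experiment), technical replicates are averaged into their biological
# replicate, and each metabolite/organism/stress level is summarized by the
# log2 fold-change of mean biological-replicate intensity versus the
# unstressed control, with a pooled-variance two-sample t-test on the log2
# replicate values. Multiple testing is controlled per organism (all ions x
# all stress levels) by Storey-Tibshirani q-values.

#' Quantile-normalize an intensity matrix
#'
#' Forces all sample columns to share the same intensity distribution:
#' each column's sorted values are replaced by the across-column mean of
#' order statistics, preserving within-column rank order; ties receive the
#' average of their target values. Missing values are tolerated (columns are
#' normalized over their non-missing quantiles).
#'
#' @param x Numeric matrix, features in rows and samples in columns (>= 2).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    stop("column(s) with all-missing values: ",
         paste(colnames(x)[all_na], collapse = ", "))
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Pooled-variance two-sample t-test
#'
#' Student's unpaired two-sided t-test with pooled variance. When both
#' groups have zero variance and equal means, `p = 1` by convention (`t = 0`);
#' zero pooled variance with unequal means yields `p = 0` (infinite t).
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @return Named vector `c(t = , p = )`.
#' @export
two_sample_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) return(c(t = 0, p = 1))
    return(c(t = sign(delta) * Inf, p = 0))
  }
  tt <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  c(t = tt, p = 2 * stats::pt(-abs(tt), df))
}

# Vectorized pooled t over matrix rows: A, B have replicates in columns.
row_t_pooled <- function(A, B) {
  na <- rowSums(is.finite(A)); nb <- rowSums(is.finite(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  va <- apply(A, 1, stats::var, na.rm = TRUE)
  vb <- apply(B, 1, stats::var, na.rm = TRUE)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tt), df)
  p[is.finite(sp2) & sp2 == 0 & ma == mb] <- 1
  tt[is.finite(sp2) & sp2 == 0 & ma == mb] <- 0
  p[na < 2 | nb < 2] <- NA
  list(t = tt, p = p, df = df)
}

#' Storey-Tibshirani q-values
#'
#' Positive false discovery rate adjusted significance. The null proportion
#' pi0 is estimated by fitting a smoothing spline to
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over
#' `lambda = 0, 0.05, ..., 0.90` and evaluating it at `lambda = 0.90`,
#' clamped to (0, 1]. Then `q_(i) = pi0 * m * p_(i) / i` with monotonicity
#' enforced from the largest p-value downward.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (missing values are
#'   carried through). At least 10 non-missing values are required for the
#'   spline estimate of pi0.
#' @param pi0 Optional fixed null proportion; `pi0 = 1` reproduces the
#'   Benjamini-Hochberg adjustment.
#' @param lambda Tuning grid for the pi0 spline.
#' @return Vector of q-values, with the estimated pi0 in `attr(, "pi0")`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0, 0.90, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 10L) stop("need at least 10 p-values to estimate pi0 (or supply pi0)")
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(pv)
  q <- pi0 * m * pv[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  qv <- numeric(m)
  qv[o] <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- qv
  attr(out, "pi0") <- pi0
  out
}

# Average technical replicates into biological replicates.
# Returns list(intensities, design) where design has one row per
# (organism, stress, bio) and no tech_replicate column.
collapse_tech_reps <- function(intensities, design) {
  key <- paste(design$organism_id, design$stress_level, design$bio_replicate,
               sep = "|")
  groups <- split(seq_len(nrow(design)), key)
  ukey <- names(groups)
  m <- vapply(groups, function(j) {
    rowMeans(intensities[, j, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(intensities)))
  if (nrow(intensities) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, ukey))
  m[is.nan(m)] <- NA_real_
  d <- design[match(ukey, key), c("organism_id", "stress_level", "bio_replicate")]
  d$sample_id <- ukey
  rownames(d) <- NULL
  list(intensities = m, design = d)
}

#' Differential analysis of a metabolite table
#'
#' Runs the full per-organism differential pipeline: quantile normalization
#' (per organism; the input table already carries one phase per metabolite),
#' technical-replicate averaging, log2 fold-changes of mean
#' biological-replicate intensity at each stress level versus the unstressed
#' control (IC0), pooled-variance t-tests on log2 replicate intensities, and
#' Storey-Tibshirani q-values with the FDR family being all ions and stress
#' levels within one organism. Differential calls are made by
#' [call_differential()].
#'
#' @param metab A [merge_extracts()] metabolite table, or a list with
#'   `intensities` (matrix), `design`, and `rows` (data frame with a
#'   `row_id` column).
#' @param normalize Quantile-normalize per organism first (default TRUE).
#' @param fc_threshold,alpha Differential-call thresholds, see
#'   [call_differential()].
#' @return Data frame of class `fc_table` with columns `row_id`,
#'   `compound_id`, `organism_id`, `stress_level`, `log2fc`, `t`, `p`, `q`,
#'   `differential`, `any_level`.
#' @export
differential_analysis <- function(metab, normalize = TRUE, fc_threshold = 1,
                                  alpha = 0.05) {
  X <- metab$intensities
  design <- metab$design
  rows <- metab$rows
  res <- list()
  for (org in unique(design$organism_id)) {
    j <- which(design$organism_id == org)
    xo <- X[, j, drop = FALSE]
    present <- rowSums(is.finite(xo)) > 0L
    if (!any(present)) next
    xo <- xo[present, , drop = FALSE]
    if (normalize) xo <- quantile_normalize(xo)
    cb <- collapse_tech_reps(xo, design[j, , drop = FALSE])
    lx <- log2(cb$intensities)
    lx[!is.finite(lx)] <- NA_real_  # zero/negative after normalization
    ctrl <- cb$design$stress_level == "IC0"
    if (!any(ctrl)) stop("organism '", org, "' has no IC0 control samples")
    ctrl_mean <- rowMeans(cb$intensities[, ctrl, drop = FALSE], na.rm = TRUE)
    for (lev in setdiff(stress_levels, "IC0")) {
      sel <- cb$design$stress_level == lev
      if (!any(sel)) next
      str_mean <- rowMeans(cb$intensities[, sel, drop = FALSE], na.rm = TRUE)
      l2fc <- log2(str_mean) - log2(ctrl_mean)
      l2fc[!is.finite(l2fc)] <- NA_real_
      tst <- row_t_pooled(lx[, sel, drop = FALSE], lx[, ctrl, drop = FALSE])
      res[[paste(org, lev)]] <- data.frame(
        row_id = rows$row_id[present],
        compound_id = rows$compound_id[present],
        organism_id = org, stress_level = lev,
        log2fc = l2fc, t = tst$t, p = tst$p,
        stringsAsFactors = FALSE)
    }
  }
  fc <- do.call(rbind, res)
  rownames(fc) <- NULL
  fc$q <- NA_real_
  for (org in unique(fc$organism_id)) {
    i <- fc$organism_id == org
    # spline pi0 needs a reasonably sized family; tiny tables fall back to BH
    fc$q[i] <- if (sum(!is.na(fc$p[i])) >= 10L) qvalues(fc$p[i]) else
      qvalues(fc$p[i], pi0 = 1)
  }
  fc <- call_differential(fc, fc_threshold = fc_threshold, alpha = alpha)
  class(fc) <- c("fc_table", "data.frame")
  fc
}

#' Flag differential records
#'
#' A record is differential when its absolute log2 fold-change reaches
#' `fc_threshold` and its multiple-testing-corrected significance (q-value)
#' is below `alpha`. The per-(metabolite, organism) `any_level` flag is true
#' when the metabolite is differential at at least one stress level.
#'
#' @param records Data frame with columns `row_id`, `organism_id`, `log2fc`,
#'   `q`.
#' @param fc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Corrected significance threshold (default 0.05).
#' @return `records` with `differential` and `any_level` columns.
#' @export
call_differential <- function(records, fc_threshold = 1, alpha = 0.05) {
  records$differential <- !is.na(records$log2fc) & !is.na(records$q) &
    abs(records$log2fc) >= fc_threshold & records$q < alpha
  key <- paste(records$row_id, records$organism_id)
  any_lev <- tapply(records$differential, key, any)
  records$any_level <- as.vector(any_lev[key])
  records
}

#' Cross-species baseline Z-scores
#'
#' Compares basal (unstressed, IC0) metabolite abundances between organisms:
#' per metabolite, the organism-mean log2 normalized IC0 abundance is
#' standardized across organisms (abundance minus across-organism mean,
#' divided by the across-organism sample standard deviation). Metabolites
#' present in fewer than 3 organisms are dropped; zero-variance metabolites
#' get Z = 0 and are flagged.
#'
#' @param metab A metabolite table (see [differential_analysis()]).
#' @param normalize Quantile-normalize per organism first (default TRUE).
#' @param log2_scale Standardize log2 intensities (default) rather than raw.
#' @return List of class `zscore_table` with `z` (metabolite x organism
#'   matrix), `small` (logical matrix, |Z| < 1), and `zero_variance`
#'   (logical vector).
#' @export
baseline_zscores <- function(metab, normalize = TRUE, log2_scale = TRUE) {
  design <- metab$design
  orgs <- unique(design$organism_id)
  ab <- matrix(NA_real_, nrow(metab$intensities), length(orgs),
               dimnames = list(metab$rows$row_id, orgs))
  for (org in orgs) {
    j <- which(design$organism_id == org)
    xo <- metab$intensities[, j, drop = FALSE]
    keep <- rowSums(is.finite(xo)) > 0L
    if (normalize && sum(keep) > 1L) {
      xo[keep, ] <- quantile_normalize(xo[keep, , drop = FALSE])
    }
    ctrl <- design$stress_level[j] == "IC0"
    v <- rowMeans(xo[, ctrl, drop = FALSE], na.rm = TRUE)
    ab[, org] <- ifelse(is.nan(v), NA_real_, v)
  }
  if (log2_scale) {
    ab <- log2(ab)
    ab[!is.finite(ab)] <- NA_real_
  }
  n_org <- rowSums(!is.na(ab))
  ab <- ab[n_org >= 3L, , drop = FALSE]
  mu <- rowMeans(ab, na.rm = TRUE)
  sdv <- apply(ab, 1, stats::sd, na.rm = TRUE)
  zero_var <- sdv == 0
  sdv[zero_var] <- 1  # Z = 0 by convention for constant metabolites
  z <- (ab - mu) / sdv
  structure(list(z = z, small = abs(z) < 1, zero_variance = zero_var),
            class = "zscore_table")
}
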