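# Global response comparison: PCA, Cityblock cladograms, Jukes-Cantor
# sequence distances and correlation of the two distance structures.

#' Fold-change matrix from a fc_table
#'
#' Arranges log2 fold-changes as a (organism x stress level) by metabolite
#' matrix, the input of the PCA and distance stages.
#'
#' @param fc A [differential_analysis()] result.
#' @param levels Stress levels to include (default IC10/IC25/IC50).
#' @param by `"organism_level"` (default; rows are organism:level
#'   combinations) or `"organism"` (rows are organisms, one chosen level).
#' @return Numeric matrix with dimnames.
#' @export
fc_matrix <- function(fc, levels = c("IC10", "IC25", "IC50"),
                      by = c("organism_level", "organism")) {
  by <- match.arg(by)
  fc <- fc[fc$stress_level %in% levels, , drop = FALSE]
  rk <- if (by == "organism") fc$organism_id else
    paste(fc$organism_id, fc$stress_level, sep = ":")
  rows <- unique(rk); cols <- unique(fc$row_id)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(rk, rows), match(fc$row_id, cols))] <- fc$log2fc
  m
}

#' Principal component analysis of a fold-change matrix
#'
#' Column-centers the matrix (missing fold-changes imputed to 0, i.e.
#' unchanged versus control) and decomposes it by singular value
#' decomposition. Explained variance fractions sum to 1.
#'
#' @param x Numeric matrix, observations in rows.
#' @return List of class `pca_result`: `scores`, `loadings`, `explained`
#'   (fraction per component), `center`.
#' @export
pca_scores <- function(x) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (all(x == 0)) stop("all-zero matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = ev / sum(ev), center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d observations, first components explain %s of variance\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 3)),
                    collapse = " / ")))
  invisible(x)
}

#' Cityblock (Manhattan) distance matrix
#'
#' Pairwise distances `d(x, y) = sum |x_i - y_i|` between matrix rows, taken
#' over the entries non-missing in both rows (pairwise complete, without
#' rescaling for missingness).
#'
#' @param x Numeric matrix, observations in rows.
#' @return A `dist` object with `attr(, "metric") = "cityblock"`.
#' @export
cityblock_distances <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- is.finite(x[i, ]) & is.finite(x[j, ])
    if (!any(ok)) stop(sprintf("rows %d and %d share no non-missing entries",
                               i, j))
    d[i, j] <- d[j, i] <- sum(abs(x[i, ok] - x[j, ok]))
  }
  rownames(d) <- rownames(x)
  out <- stats::as.dist(d)
  attr(out, "metric") <- "cityblock"
  out
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (default average linkage) of a distance matrix,
#' e.g. for the cladogram of species metabolic responses. Ties are broken
#' deterministically by input label order (the behaviour of
#' [stats::hclust()]).
#'
#' @param d A `dist` object.
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return An `hclust` tree (merge heights non-decreasing from the leaves).
#' @seealso [as_newick()]
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "single",
                                                "complete", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(d, method = method)
}

#' Newick serialization of a cluster tree
#'
#' @param tree An `hclust` object.
#' @param file Optional path; when given the Newick string is also written
#'   there.
#' @return Newick string with branch lengths derived from merge heights.
#' @export
as_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  s <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(s, file)
  s
}

#' Jukes-Cantor distances from an alignment
#'
#' For every sequence pair the mismatch fraction p is computed over alignment
#' columns where both sequences carry an unambiguous base (gaps and Ns are
#' excluded pairwise), and corrected to the expected number of substitutions
#' per site, `d = -(3/4) log(1 - (4/3) p)`. Saturated pairs (p >= 3/4, where
#' the correction is undefined) are returned as `NA` and listed in
#' `attr(, "undefined")`.
#'
#' @param seqs Named character vector of aligned sequences (see
#'   [read_alignment()]).
#' @return A `dist` object with `attr(, "metric") = "jukes-cantor"`.
#' @export
jukes_cantor_distances <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  valid <- chars %in% c("A", "C", "G", "T", "U")
  dim(valid) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) {
      stop(sprintf("sequences '%s' and '%s' share no comparable columns",
                   names(seqs)[i], names(seqs)[j]))
    }
    p <- mean(chars[i, ok] != chars[j, ok])
    if (p >= 0.75) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(names(seqs)[i], names(seqs)[j], sep = "-"))
    } else {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- "jukes-cantor"
  attr(out, "undefined") <- undef
  out
}

#' Correlation between two distance matrices (Mantel test)
#'
#' Pearson correlation R between the upper triangles of two distance
#' matrices over matched labels, with a one-sided (positive association)
#' permutation p-value from a Mantel test relabeling one matrix. A t-based
#' p-value treating the n(n-1)/2 pairs as independent observations
#' (`df = n(n-1)/2 - 2`) is reported alongside; it is approximate because
#' distance pairs are not independent, and the permutation p is primary.
#'
#' @param d1,d2 `dist` objects over the same labels (order may differ).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed for the permutation null.
#' @return List of class `mantel_result`: `r`, `p_perm`, `p_t`
#'   (approximate), `n`, `n_perm`.
#' @export
distance_correlation_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (is.null(l1) || is.null(l2) || !setequal(l1, l2) ||
      length(l1) != length(l2)) {
    stop("distance matrices must share the same labels")
  }
  if (length(l1) < 4L) stop("need at least 4 labels")
  m2 <- m2[l1, l1]
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      method = "pearson", permutations = n_perm,
                      na.rm = TRUE)
  r <- unname(mt$statistic)
  npairs <- sum(!is.na(m1[upper.tri(m1)] + m2[upper.tri(m2)]))
  tt <- r * sqrt((npairs - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p_perm = unname(mt$signif),
                 p_t = stats::pt(tt, npairs - 2, lower.tail = FALSE),
                 n = length(l1), n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel distance correlation: R = %.3f, permutation p = %.4g (%d permutations), approximate t-based p = %.4g, n = %d labels\n",
              x$r, x$p_perm, x$n_perm, x$p_t, x$n))
  invisible(x)
}
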