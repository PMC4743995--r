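# Accurate-mass ion annotation and polar/nonpolar extract merging.
#
# Centroided negative-mode features are matched within an absolute tolerance
# (default 0.005 Da) against the expected m/z of deprotonated ([M-H]-) and
# one-carbon 13C isotopologue species of an organism-restricted compound
# library. Annotation by accurate mass alone can be ambiguous; ambiguity is
# propagated (every candidate kept, flagged), never auto-resolved.

#' Annotate ions by accurate mass
#'
#' Matches every feature m/z against the expected m/z of the `[M-H]-` and
#' `[M-H]+13C` species of each library compound, keeping all candidates
#' within `tolerance` (absolute Da). When `organism_id` is given, only
#' compounds associated with that organism are considered (compounds with an
#' empty association list match every organism).
#'
#' @param x An [ion_table()] or a numeric vector of feature m/z values (Da).
#' @param lib A [compound_library()].
#' @param organism_id Optional organism id restricting the library.
#' @param tolerance Absolute mass tolerance in Da (default 0.005).
#' @return Object of class `ion_annotation`: a data frame with columns
#'   `mz`, `compound_id`, `name`, `species`, `expected_mz`, `mass_error`
#'   (observed minus expected) and `ambiguous` (the feature matches two or
#'   more distinct compounds). Per feature, candidates are sorted by absolute
#'   mass error. Features without any candidate are available via
#'   `attr(, "unannotated")`.
#' @export
annotate_ions <- function(x, lib, organism_id = NULL, tolerance = 0.005) {
  stopifnot(inherits(lib, "compound_library"), tolerance > 0)
  mz <- if (inherits(x, "ion_table")) x$mz else as.numeric(x)
  if (!is.null(organism_id)) {
    known <- library_organisms(lib)
    if (length(known) && !organism_id %in% known &&
        all(nzchar(lib$organism_ids))) {
      stop("organism '", organism_id, "' absent from library associations")
    }
    lib <- lib[compound_matches_organism(lib, organism_id), , drop = FALSE]
    if (nrow(lib) == 0L) {
      stop("organism '", organism_id, "' absent from library associations")
    }
  }
  # expected m/z table: one row per (compound, species), sorted for window query
  exp_tab <- data.frame(
    compound_id = rep(lib$compound_id, length(ion_species)),
    name = rep(lib$name, length(ion_species)),
    species = rep(ion_species, each = nrow(lib)),
    expected_mz = c(expected_mz(lib$mass, ion_species[1]),
                    expected_mz(lib$mass, ion_species[2])),
    stringsAsFactors = FALSE)
  ord <- order(exp_tab$expected_mz)
  exp_tab <- exp_tab[ord, , drop = FALSE]
  lo <- findInterval(mz - tolerance, exp_tab$expected_mz) + 1L
  hi <- findInterval(mz + tolerance, exp_tab$expected_mz)
  nhit <- pmax(hi - lo + 1L, 0L)
  feat_idx <- rep(seq_along(mz), nhit)
  cand_idx <- unlist(lapply(which(nhit > 0L), function(i) lo[i]:hi[i]),
                     use.names = FALSE)
  ann <- data.frame(mz = mz[feat_idx],
                    exp_tab[cand_idx, , drop = FALSE],
                    stringsAsFactors = FALSE)
  ann$mass_error <- ann$mz - ann$expected_mz
  ann <- ann[order(feat_idx, abs(ann$mass_error)), , drop = FALSE]
  feat_idx <- sort(feat_idx)
  n_comp <- tapply(ann$compound_id, feat_idx, function(z) length(unique(z)))
  ann$ambiguous <- as.vector(n_comp[as.character(feat_idx)] >= 2L)
  rownames(ann) <- NULL
  attr(ann, "unannotated") <- mz[nhit == 0L]
  attr(ann, "tolerance") <- tolerance
  class(ann) <- c("ion_annotation", "data.frame")
  ann
}

#' @export
print.ion_annotation <- function(x, ...) {
  cat(sprintf("ion_annotation: %d candidate matches for %d features (%d ambiguous, %d unannotated), tolerance %.4g Da\n",
              nrow(x), length(unique(x$mz)), length(unique(x$mz[x$ambiguous])),
              length(attr(x, "unannotated")), attr(x, "tolerance")))
  NextMethod()
}

#' Extract phase of a compound
#'
#' Routes compounds between the two extraction phases by the octanol/water
#' partition coefficient: `logp <= 0` (hydrophilic) uses the polar extract,
#' `logp > 0` the nonpolar extract.
#'
#' @param logp Numeric vector of logP(O/W) values (a [compound_library()] is
#'   also accepted).
#' @return Factor with levels `polar`, `nonpolar`.
#' @export
select_phase <- function(logp) {
  if (inherits(logp, "compound_library")) logp <- logp$logp
  if (!is.numeric(logp) || any(is.na(logp))) {
    stop("logp must be numeric with no missing values")
  }
  factor(ifelse(logp <= 0, "polar", "nonpolar"), levels = extract_phases)
}

#' Merge polar and nonpolar extracts into a metabolite table
#'
#' Builds the metabolite-by-sample intensity table from the two phase tables:
#' per metabolite, intensities are taken from the phase selected by
#' [select_phase()] of its logP. When several features annotate the same
#' metabolite in its selected phase (e.g. the 13C isotopologue, or distinct
#' nearby features), each is kept as a separate row keyed by
#' (compound, species, feature m/z) — duplicate names then represent
#' different ions of the same metabolite. Intensities for organisms not
#' associated with a compound are set to missing. Metabolites annotated in
#' neither phase are excluded (reported via a message).
#'
#' @param polar,nonpolar [ion_table()]s of the two phases (same organisms).
#' @param annotations List with elements `polar` and `nonpolar`, each an
#'   [annotate_ions()] result for the corresponding table; computed from
#'   `lib` when omitted.
#' @param lib The [compound_library()].
#' @param tolerance Mass tolerance passed to [annotate_ions()] when
#'   `annotations` is not supplied.
#' @return Object of class `metabolite_table`: list with `rows` (data frame:
#'   `compound_id`, `name`, `species`, `feature_mz`, `phase`, `ambiguous`),
#'   `intensities` (matrix, one row per `rows` entry), and `design`.
#' @export
merge_extracts <- function(polar, nonpolar, annotations = NULL, lib,
                           tolerance = 0.005) {
  stopifnot(inherits(polar, "ion_table"), inherits(nonpolar, "ion_table"),
            inherits(lib, "compound_library"))
  if (is.null(annotations)) {
    annotations <- list(polar = annotate_ions(polar, lib, tolerance = tolerance),
                        nonpolar = annotate_ions(nonpolar, lib, tolerance = tolerance))
  }
  phase_of <- stats::setNames(as.character(select_phase(lib)), lib$compound_id)
  tabs <- list(polar = polar, nonpolar = nonpolar)
  design <- rbind(polar$design, nonpolar$design)
  # One merged sample axis: (organism, stress, bio, tech); intensities for a
  # metabolite come only from its selected phase.
  key <- function(d) paste(d$organism_id, d$stress_level, d$bio_replicate,
                           d$tech_replicate, sep = "|")
  skey <- unique(key(design))
  sdesign <- design[match(skey, key(design)), , drop = FALSE]
  sdesign$extract_phase <- NULL
  sdesign$sample_id <- skey
  rownames(sdesign) <- NULL

  rows <- list(); mats <- list()
  for (ph in extract_phases) {
    ann <- annotations[[ph]]
    ann <- ann[phase_of[ann$compound_id] == ph, , drop = FALSE]
    if (nrow(ann) == 0L) next
    tab <- tabs[[ph]]
    fidx <- match(ann$mz, tab$mz)
    m <- tab$intensities[fidx, , drop = FALSE]
    # map phase samples onto the merged sample axis
    out <- matrix(NA_real_, nrow(ann), length(skey),
                  dimnames = list(NULL, skey))
    out[, key(tab$design)] <- m
    # mask organisms not associated with the compound
    for (i in seq_len(nrow(ann))) {
      assoc <- lib$organism_ids[match(ann$compound_id[i], lib$compound_id)]
      if (nzchar(assoc)) {
        ok_org <- strsplit(assoc, ";", fixed = TRUE)[[1]]
        out[i, !(sdesign$organism_id %in% ok_org)] <- NA_real_
      }
    }
    rows[[ph]] <- data.frame(compound_id = ann$compound_id, name = ann$name,
                             species = ann$species, feature_mz = ann$mz,
                             phase = ph, ambiguous = ann$ambiguous,
                             stringsAsFactors = FALSE)
    mats[[ph]] <- out
  }
  if (!length(rows)) stop("no metabolite annotated in either phase")
  rows <- do.call(rbind, rows)
  intensities <- do.call(rbind, mats)
  rownames(rows) <- rownames(intensities) <- NULL
  dropped <- setdiff(lib$compound_id, rows$compound_id)
  if (length(dropped)) {
    message(length(dropped), " library compound(s) annotated in neither phase: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...")
  }
  rows$row_id <- paste(rows$compound_id, rows$species,
                       sprintf("%.4f", rows$feature_mz), sep = "@")
  structure(list(rows = rows, intensities = intensities, design = sdesign),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d metabolite ion rows (%d compounds) x %d samples\n",
              nrow(x$rows), length(unique(x$rows$compound_id)),
              nrow(x$design)))
  invisible(x)
}
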