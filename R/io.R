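# Data containers and file I/O.
#
# All tabular files are tab-separated UTF-8 with one header row and "NA" for
# missing values. Numeric values are written at full precision ("%.17g") so
# that reader/writer pairs round-trip bit-identically.

.design_cols <- c("sample_id", "organism_id", "stress_level", "extract_phase",
                  "bio_replicate", "tech_replicate")

#' Stress levels and extract phases
#'
#' Every organism is profiled at its unstressed control (IC0) and at salt
#' concentrations inhibiting its growth rate by 10, 25 and 50 percent
#' (IC10/IC25/IC50), in a polar and a nonpolar extract.
#' @name design-levels
NULL

#' @rdname design-levels
#' @export
stress_levels <- c("IC0", "IC10", "IC25", "IC50")

#' @rdname design-levels
#' @export
extract_phases <- c("polar", "nonpolar")

validate_design <- function(design) {
  missing <- setdiff(.design_cols, names(design))
  if (length(missing)) {
    stop("design table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design table")
  }
  bad <- setdiff(unique(design$stress_level), stress_levels)
  if (length(bad)) stop("unknown stress level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(design$extract_phase), extract_phases)
  if (length(bad)) stop("unknown extract phase(s): ", paste(bad, collapse = ", "))
  key <- do.call(paste, design[c("organism_id", "stress_level", "extract_phase",
                                 "bio_replicate", "tech_replicate")])
  if (anyDuplicated(key)) {
    stop("duplicate (organism, stress, phase, bio, tech) tuples in design")
  }
  design$stress_level <- factor(design$stress_level, levels = stress_levels)
  design$extract_phase <- factor(design$extract_phase, levels = extract_phases)
  design
}

#' Construct an ion table
#'
#' An ion table pairs a feature-by-sample intensity matrix with the m/z of
#' each feature and the sample design (organism, stress level, extract phase,
#' biological and technical replicate).
#'
#' @param mz Numeric vector of feature m/z values (Da), strictly positive.
#' @param intensities Non-negative numeric matrix, one row per feature and one
#'   column per sample; `NA` marks a feature not detected in a sample.
#' @param design Data frame with columns `sample_id`, `organism_id`,
#'   `stress_level`, `extract_phase`, `bio_replicate`, `tech_replicate`; its
#'   rows must match the matrix columns one-to-one by `sample_id`.
#' @return Object of class `ion_table`: a list with elements `mz`,
#'   `intensities` and `design`.
#' @export
ion_table <- function(mz, intensities, design) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(mz) || any(!is.finite(mz)) || any(mz <= 0)) {
    stop("feature m/z values must be positive and finite")
  }
  if (nrow(intensities) != length(mz)) {
    stop("nrow(intensities) must equal length(mz)")
  }
  design <- validate_design(design)
  if (is.null(colnames(intensities))) {
    if (ncol(intensities) != nrow(design)) {
      stop("intensity columns do not match design rows")
    }
    colnames(intensities) <- design$sample_id
  }
  extra <- setdiff(colnames(intensities), design$sample_id)
  if (length(extra)) {
    stop("intensity column(s) without a design row: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(design$sample_id, colnames(intensities))
  if (length(missing)) {
    stop("design sample(s) without an intensity column: ",
         paste(missing, collapse = ", "))
  }
  intensities <- intensities[, design$sample_id, drop = FALSE]
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensities")
  rownames(intensities) <- NULL
  structure(list(mz = as.numeric(mz), intensities = intensities,
                 design = design),
            class = "ion_table")
}

#' @export
print.ion_table <- function(x, ...) {
  cat(sprintf("ion_table: %d m/z features x %d samples (%d organisms)\n",
              length(x$mz), nrow(x$design), length(unique(x$design$organism_id))))
  cat(sprintf("  m/z range %.4f - %.4f Da; %.1f%% missing values\n",
              min(x$mz), max(x$mz),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read / write an ion table
#'
#' The intensity file is tab-separated with an `mz` column followed by one
#' numeric column per sample; the design file carries the sample annotations.
#' Every intensity column must have a design row (a column without one is a
#' hard error naming the column); design rows without an intensity column are
#' likewise an error. Non-numeric intensity cells are an error reporting the
#' offending row and column.
#'
#' @param path Path of the intensity table.
#' @param design_path Path of the sample design table.
#' @return [read_ion_table()] returns an [ion_table()].
#' @export
read_ion_table <- function(path, design_path) {
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!"mz" %in% names(raw)) stop("intensity table lacks an 'mz' column")
  samp_cols <- setdiff(names(raw), "mz")
  num <- lapply(c("mz", samp_cols), function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(v %in% c("NA", "", NA)))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                   v[bad[1]], bad[1], col))
    }
    out
  })
  mz <- num[[1]]
  mat <- do.call(cbind, num[-1])
  colnames(mat) <- samp_cols
  ion_table(mz, mat, design)
}

#' @param x An `ion_table`.
#' @rdname read_ion_table
#' @export
write_ion_table <- function(x, path, design_path) {
  stopifnot(inherits(x, "ion_table"))
  df <- data.frame(mz = fmt_num(x$mz), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$intensities))) {
    df[[colnames(x$intensities)[j]]] <- fmt_num(x$intensities[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Construct a compound library
#'
#' @param records Data frame with columns `compound_id`, `name`, `formula`,
#'   `logp` and optionally `organism_ids` (semicolon-separated organism ids;
#'   empty means associated with every organism) and `is_osmoprotectant`
#'   (logical). A `mass` column is always (re)computed from the formula.
#' @return Object of class `compound_library`: the record data frame sorted by
#'   neutral monoisotopic mass, which supports fast tolerance-window queries.
#' @export
compound_library <- function(records) {
  need <- c("compound_id", "name", "formula", "logp")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("library lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$compound_id)) {
    dup <- records$compound_id[duplicated(records$compound_id)][1]
    stop("duplicate compound_id: ", dup)
  }
  mass <- vapply(seq_len(nrow(records)), function(i) {
    tryCatch(monoisotopic_mass(records$formula[i]),
             error = function(e) stop(sprintf("record '%s': %s",
                                              records$compound_id[i],
                                              conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(1))
  records$mass <- mass
  if (is.null(records$organism_ids)) records$organism_ids <- ""
  records$organism_ids[is.na(records$organism_ids)] <- ""
  if (is.null(records$is_osmoprotectant)) records$is_osmoprotectant <- FALSE
  records$is_osmoprotectant <- as.logical(records$is_osmoprotectant) %in% TRUE
  records <- records[order(records$mass), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("compound_library", "data.frame")
  records
}

#' Read a compound library from a tab-separated file
#'
#' @param path TSV file with columns `compound_id`, `name`, `formula`, `logp`,
#'   optionally `organism_ids` and `is_osmoprotectant`.
#' @return A [compound_library()].
#' @export
read_compound_library <- function(path) {
  compound_library(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("compound_library: %d compounds, mass %.4f - %.4f Da, %d osmoprotectants\n",
              nrow(x), min(x$mass), max(x$mass), sum(x$is_osmoprotectant)))
  invisible(x)
}

# Compound ids associated with an organism; "" associates with all.
library_organisms <- function(lib) {
  unique(unlist(strsplit(lib$organism_ids[nzchar(lib$organism_ids)], ";",
                         fixed = TRUE)))
}

compound_matches_organism <- function(lib, organism_id) {
  !nzchar(lib$organism_ids) |
    vapply(strsplit(lib$organism_ids, ";", fixed = TRUE),
           function(o) organism_id %in% o, logical(1))
}

#' Read an aligned FASTA file
#'
#' All sequences must have equal length (gap characters count); the offending
#' sequence is named otherwise.
#'
#' @param path FASTA file of aligned sequences.
#' @return Named character vector of aligned sequences (upper case, gaps
#'   preserved).
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("alignment file is empty: ", path)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    off <- names(seqs)[which(w != w[1])[1]]
    stop(sprintf("sequences are not aligned: '%s' has length %d, expected %d",
                 off, nchar(seqs[off]), w[1]))
  }
  seqs
}

#' Write an aligned FASTA file
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param path Output path.
#' @export
write_alignment <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(seqs)
}

#' Salt-tolerance class from IC50
#'
#' Bins organisms by their half-inhibitory NaCl concentration:
#' IC50 < 500 mM is `low`, 500 <= IC50 <= 1000 mM is `medium` (both
#' boundaries inclusive to medium), IC50 > 1000 mM is `high`.
#'
#' @param ic50 Numeric vector of IC50 values in mM NaCl.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' tolerance_class(c(150, 500, 1000, 1500))
#' @export
tolerance_class <- function(ic50) {
  if (!is.numeric(ic50) || any(is.na(ic50))) {
    stop("ic50 must be numeric with no missing values")
  }
  factor(ifelse(ic50 < 500, "low", ifelse(ic50 <= 1000, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Bundled organism panel
#'
#' Metadata for the sixteen cell systems of the study panel (twelve bacteria,
#' two yeasts, two human cell lines): taxonomic group, typical habitat,
#' cell-wall class and number of biological replicates. Habitat and cell-wall
#' assignments are reconstructed from standard microbiology; the IC columns
#' are `NA` except the two extremes quoted in the text (MCF7 150 mM,
#' Z. mobilis 1500 mM), since per-organism tolerances are not part of the
#' extracted tables.
#'
#' @return Data frame with one row per organism.
#' @export
study_organisms <- function() {
  utils::read.delim(system.file("extdata", "organisms.tsv",
                                package = "saltmet"),
                    stringsAsFactors = FALSE)
}

#' Bundled example compound library
#'
#' A small metabolite library (osmoprotectants from curated compendia plus
#' common central metabolites) with elemental formulas, approximate
#' octanol/water logP values and osmoprotectant flags. The logP values are
#' literature-typical assignments used to route metabolites between the polar
#' and nonpolar extract; they are not measured constants.
#'
#' @return A [compound_library()].
#' @export
example_compound_library <- function() {
  read_compound_library(system.file("extdata", "compounds.tsv",
                                    package = "saltmet"))
}
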