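# Shared fixture builders. Everything is generated in code; no binary files.

toy_design <- function(organisms = "eco", levels = c("IC0", "IC50"),
                       phases = "polar", n_bio = 2, n_tech = 1) {
  d <- expand.grid(tech_replicate = seq_len(n_tech),
                   bio_replicate = seq_len(n_bio),
                   stress_level = levels, extract_phase = phases,
                   organism_id = organisms,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- paste(d$organism_id, d$stress_level, d$bio_replicate,
                       d$tech_replicate, substr(d$extract_phase, 1, 3),
                       sep = "_")
  d[c("sample_id", "organism_id", "stress_level", "extract_phase",
      "bio_replicate", "tech_replicate")]
}

toy_library <- function() {
  compound_library(data.frame(
    compound_id = c("glu", "pro", "q8"),
    name = c("L-glutamate", "L-proline", "ubiquinone-8"),
    formula = c("C5H9NO4", "C5H9NO2", "C49H74O4"),
    logp = c(-3.69, -2.54, 10.2),
    organism_ids = c("", "", "eco;bsu"),
    is_osmoprotectant = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

# Brute-force annotation oracle: all-pairs window scan.
brute_force_annotate <- function(mz, lib, tolerance) {
  out <- list()
  for (i in seq_along(mz)) {
    for (j in seq_len(nrow(lib))) {
      for (sp in ion_species) {
        emz <- expected_mz(lib$mass[j], sp)
        if (abs(mz[i] - emz) <= tolerance) {
          out[[length(out) + 1L]] <- data.frame(
            mz = mz[i], compound_id = lib$compound_id[j], species = sp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(mz = numeric(0),
                                      compound_id = character(0),
                                      species = character(0)))
  do.call(rbind, out)
}

ann_key <- function(df) sort(paste(format(df$mz, digits = 12),
                                   df$compound_id, df$species))
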