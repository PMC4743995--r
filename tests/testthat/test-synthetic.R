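test_that("generators are pure functions of their seed", {
  p1 <- simulate_panel(seed = 3); p2 <- simulate_panel(seed = 3)
  expect_identical(p1$meta, p2$meta)
  expect_identical(p1$truth$k, p2$truth$k)
  expect_identical(ape::write.tree(p1$truth$tree),
                   ape::write.tree(p2$truth$tree))
  lib <- simulate_library(p1, n_null = 20, seed = 3)
  i1 <- simulate_ion_tables(p1, lib, seed = 3, decoy_ratio = 1)
  i2 <- simulate_ion_tables(p1, lib, seed = 3, decoy_ratio = 1)
  expect_identical(i1$polar$intensities, i2$polar$intensities)
  expect_identical(i1$polar$mz, i2$polar$mz)
  expect_identical(i1$truth, i2$truth)
  a1 <- simulate_alignment(p1$truth$tree, length = 100, seed = 3)
  expect_identical(a1, simulate_alignment(p1$truth$tree, length = 100,
                                          seed = 3))
  expect_false(identical(a1, simulate_alignment(p1$truth$tree, length = 100,
                                                seed = 4)))
})

test_that("panel defaults mirror the study conditions", {
  p <- simulate_panel(seed = 5)
  expect_equal(nrow(p$meta), 16)
  expect_true(all(p$meta$ic50 >= 150 & p$meta$ic50 <= 1500))
  expect_equal(eval(formals(simulate_panel)$ic50_range), c(150, 1500))
  expect_true(all(p$meta$ic10 <= p$meta$ic25 & p$meta$ic25 <= p$meta$ic50))
  expect_equal(p$meta$n_bio_replicates,
               ifelse(p$meta$taxonomy_group == "human", 3L, 4L))
  expect_equal(sum(p$meta$taxonomy_group == "human"), 2)
  # degenerate two-organism panel still valid
  p2 <- simulate_panel(n_organisms = 2, seed = 5)
  expect_equal(nrow(p2$meta), 2)
  expect_equal(length(p2$truth$tree$tip.label), 2)
})

test_that("replicate structure of the ion tables matches the design", {
  p <- simulate_panel(seed = 6)
  lib <- simulate_library(p, n_null = 10, seed = 6)
  ions <- simulate_ion_tables(p, lib, seed = 6, decoy_ratio = 0)
  for (tab in list(ions$polar, ions$nonpolar)) {
    d <- tab$design
    expect_setequal(unique(as.character(d$stress_level)),
                    c("IC0", "IC10", "IC25", "IC50"))
    counts <- table(d$organism_id) / (4 * 2)  # levels x tech replicates
    human <- p$meta$organism_id[p$meta$taxonomy_group == "human"]
    expect_true(all(counts[human] == 3))
    expect_true(all(counts[setdiff(names(counts), human)] == 4))
  }
})

test_that("noiseless growth data recovers true IC50 to numerical precision", {
  p <- simulate_panel(n_organisms = 4, seed = 8)
  curves <- simulate_growth(p, noise_sd = 0, seed = 8)
  ics <- ic_from_growth(curves)
  rel_err <- abs(ics$ic50 - p$truth$k[ics$organism_id]) /
    p$truth$k[ics$organism_id]
  expect_lt(max(rel_err), 1e-6)
  # unstressed rate equals the organism's true maximum rate
  one <- curves[curves$organism_id == ics$organism_id[1] &
                  curves$conc == 0 & curves$replicate == 1, ]
  expect_equal(max_growth_rate(one$time, one$value),
               unname(p$truth$r_max[ics$organism_id[1]]), tolerance = 1e-9)
})

test_that("planted m/z jitter stays within the annotation window", {
  p <- simulate_panel(seed = 10)
  lib <- simulate_library(p, n_null = 30, seed = 10)
  ions <- simulate_ion_tables(p, lib, seed = 10, decoy_ratio = 0)
  for (tab in list(ions$polar, ions$nonpolar)) {
    ann <- annotate_ions(tab, lib, tolerance = 0.005)
    # every emitted feature is a true feature here: recall must be 100%
    expect_length(attr(ann, "unannotated"), 0)
    expect_true(all(abs(ann$mass_error) <= 0.005))
  }
})

test_that("decoy features never annotate", {
  p <- simulate_panel(seed = 11)
  lib <- simulate_library(p, n_null = 20, seed = 11)
  with_decoys <- simulate_ion_tables(p, lib, seed = 11, decoy_ratio = 3)
  no_decoys <- simulate_ion_tables(p, lib, seed = 11, decoy_ratio = 0)
  n_true <- length(no_decoys$polar$mz) + length(no_decoys$nonpolar$mz)
  ann_p <- annotate_ions(with_decoys$polar, lib)
  ann_n <- annotate_ions(with_decoys$nonpolar, lib)
  annotated <- length(unique(ann_p$mz)) + length(unique(ann_n$mz))
  expect_equal(annotated, n_true)
})

test_that("planted effects are recovered exactly in the noiseless limit", {
  p <- simulate_panel(seed = 12)
  lib <- simulate_library(p, n_null = 30, seed = 12)
  ions <- simulate_ion_tables(p, lib, seed = 12, decoy_ratio = 0,
                              cv_bio = 0, cv_tech = 0)
  E <- attr(ions$truth, "planted_fc")
  metab <- suppressMessages(merge_extracts(ions$polar, ions$nonpolar,
                                           lib = lib))
  fc <- differential_analysis(metab, normalize = FALSE)
  m <- compound_fc_matrix(fc, level = "IC50")
  planted <- ions$truth$compound_id[ions$truth$effect_class != "null"]
  # restrict to compounds measured without isobaric interference
  clean <- planted[vapply(planted, function(cc) {
    rows <- metab$rows[metab$rows$compound_id == cc, ]
    !any(rows$ambiguous)
  }, logical(1))]
  expect_gt(length(clean), 10)
  for (cc in clean) {
    got <- m[cc, colnames(E)]
    det <- !is.na(got)  # organisms carrying the compound
    expect_gt(sum(det), 0)
    expect_equal(got[det], E[cc, det], tolerance = 1e-9)
  }
})

test_that("zero branch lengths give identical sequences and long alignments
           recover tree distances", {
  tree <- ape::rcoal(5)
  flat <- tree; flat$edge.length <- rep(0, length(flat$edge.length))
  seqs <- simulate_alignment(flat, length = 200, seed = 13)
  expect_equal(length(unique(seqs)), 1)
  # consistency is exercised at longer lengths in the acceptance suite
  seqs2 <- simulate_alignment(tree, length = 50, seed = 13)
  expect_equal(unname(nchar(seqs2)), rep(50, 5))
  expect_setequal(names(seqs2), tree$tip.label)
})

test_that("phylogenetic fold-changes covary along the tree", {
  set.seed(14)
  tree <- ape::rcoal(10)
  x <- simulate_phylo_foldchanges(tree, n_metabolites = 2000,
                                  sigma_phylo = 1, sigma_ind = 0, seed = 14)
  emp <- cov(t(x))
  expect_equal(as.numeric(emp), as.numeric(ape::vcv(tree)), tolerance = 0.15)
})

test_that("ground truth registry covers every planted class", {
  study <- simulate_study(seed = 15, n_null = 60, decoy_ratio = 1)
  tr <- study$ions$truth
  expect_setequal(tr$compound_id, study$lib$compound_id)
  expect_true(all(tr$effect_class %in%
                    c("null", "osmoprotectant-accumulation",
                      "species-specific", "factor-specific",
                      "tolerance-correlated-positive",
                      "tolerance-correlated-negative")))
  expect_equal(sum(tr$effect_class == "tolerance-correlated-positive"), 10)
  expect_equal(sum(tr$effect_class == "tolerance-correlated-negative"), 10)
  # every non-null effect names its target organisms or factor level
  eff <- tr[tr$effect_class != "null", ]
  expect_true(all(nzchar(eff$organisms)))
})
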