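test_that("quantile normalization forces shared order-statistic means", {
  out <- quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are left unchanged
  same <- cbind(x = c(2, 9, 4), y = c(2, 9, 4))
  expect_equal(quantile_normalize(same), same)
  expect_error(quantile_normalize(cbind(a = 1:3, b = rep(NA_real_, 3))),
               "all-missing")
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "at least 2")
})

test_that("quantile normalization is idempotent and equalizes column sums", {
  set.seed(5)
  for (i in 1:5) {
    x <- matrix(rlnorm(200), 40, 5)
    q1 <- quantile_normalize(x)
    expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
    expect_lt(diff(range(colSums(q1))), 1e-8)
    # rank order preserved within columns
    for (j in 1:5) expect_equal(order(q1[, j]), order(x[, j]))
  }
})

test_that("pooled t-test matches the explicit formula", {
  expect_equal(two_sample_test(c(1, 2, 3), c(1, 2, 3)),
               c(t = 0, p = 1))
  res <- two_sample_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res[["t"]], -3.674, tolerance = 1e-3)
  expect_equal(res[["p"]], 0.02131, tolerance = 1e-4)
  # symmetry: swapping groups negates t, keeps p
  swapped <- two_sample_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped[["t"]], -res[["t"]])
  expect_equal(swapped[["p"]], res[["p"]])
  # degenerate: both groups constant and equal -> p = 1 by convention
  expect_equal(two_sample_test(c(2, 2), c(2, 2))[["p"]], 1)
  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is forced to 1", {
  set.seed(19)
  p <- c(runif(300), runif(50, 0, 1e-3))
  q <- qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("q-values are order-preserving and respect the pi0 estimate", {
  set.seed(20)
  p <- runif(5000)
  q <- qvalues(p)
  o <- order(p)
  expect_true(!is.unsorted(q[o]))
  expect_true(attr(q, "pi0") > 0 && attr(q, "pi0") <= 1)
  expect_equal(as.numeric(qvalues(rep(1, 20), pi0 = 1)), rep(1, 20))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(qvalues(runif(5)), "at least 10")
})

test_that("pi0 estimate is near 1 for uniform p-values", {
  set.seed(21)
  q <- qvalues(runif(1e4))
  expect_gte(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1.0)
})

test_that("differential calls require both fold-change and significance", {
  rec <- data.frame(row_id = c("m1", "m1", "m2", "m2"),
                    organism_id = "eco",
                    stress_level = c("IC10", "IC50", "IC10", "IC50"),
                    log2fc = c(1.2, 0.2, 0.9, 0.9),
                    q = c(0.01, 0.5, 0.001, 0.001))
  out <- call_differential(rec)
  expect_equal(out$differential, c(TRUE, FALSE, FALSE, FALSE))
  # m1 differential at IC10 only -> any-level flag true at every level
  expect_equal(out$any_level, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("fold-changes versus control come out on the log2 scale", {
  lib <- toy_library()
  design <- toy_design(organisms = "eco", levels = c("IC0", "IC50"),
                       n_bio = 3, n_tech = 2)
  glu_mono <- expected_mz(lib$mass[lib$compound_id == "glu"], "[M-H]-")
  # stressed mean 8, control mean 2 -> log2 fc = 2 (no normalization)
  vals <- ifelse(design$stress_level == "IC0", 2, 8)
  metab <- list(intensities = matrix(vals, 1,
                                     dimnames = list(NULL, design$sample_id)),
                design = design,
                rows = data.frame(row_id = "glu@x", compound_id = "glu"))
  fc <- differential_analysis(metab, normalize = FALSE)
  expect_equal(fc$log2fc[fc$stress_level == "IC50"], 2)
  # technical replicates are averaged first: perturbing one tech rep within
  # a bio replicate moves the bio mean, not the replicate count
  metab$intensities[1, 1] <- 4  # IC0 bio 1 becomes mean(4, 2) = 3
  fc2 <- differential_analysis(metab, normalize = FALSE)
  expect_equal(fc2$log2fc, log2(8) - log2(mean(c(3, 2, 2))))
})

test_that("baseline Z-scores standardize organism means at IC0", {
  design <- toy_design(organisms = c("o1", "o2", "o3"),
                       levels = c("IC0", "IC50"), n_bio = 2)
  # organism means at IC0: 2, 4, 8 -> log2: 1, 2, 3 -> Z = -1, 0, 1
  base <- c(o1 = 2, o2 = 4, o3 = 8)
  vals <- ifelse(design$stress_level == "IC0",
                 base[design$organism_id], 99)
  metab <- list(intensities = rbind(vals, rep(5, length(vals))),
                design = design,
                rows = data.frame(row_id = c("m1", "m2"),
                                  compound_id = c("m1", "m2")))
  rownames(metab$intensities) <- NULL
  z <- baseline_zscores(metab, normalize = FALSE, log2_scale = TRUE)
  expect_equal(unname(z$z["m1", c("o1", "o2", "o3")]), c(-1, 0, 1))
  # constant metabolite: Z = 0 by convention, flagged, and |Z| < 1 is "small"
  expect_equal(unname(z$z["m2", ]), c(0, 0, 0))
  expect_true(z$zero_variance[["m2"]])
  expect_true(all(z$small["m2", ]))
  expect_false(any(z$small["m1", c("o1", "o3")]))
})

test_that("Z-scores have zero mean and unit sample SD across organisms", {
  set.seed(33)
  design <- toy_design(organisms = paste0("o", 1:5),
                       levels = c("IC0", "IC50"), n_bio = 2)
  m <- matrix(rlnorm(10 * nrow(design), 5), 10,
              dimnames = list(NULL, design$sample_id))
  metab <- list(intensities = m, design = design,
                rows = data.frame(row_id = paste0("m", 1:10),
                                  compound_id = paste0("m", 1:10)))
  z <- baseline_zscores(metab)
  expect_equal(unname(rowMeans(z$z)), rep(0, nrow(z$z)), tolerance = 1e-12)
  expect_equal(unname(apply(z$z, 1, sd)), rep(1, nrow(z$z)),
               tolerance = 1e-12)
})

test_that("planted 4-fold osmoprotectant accumulation is recovered in
           4-replicate organisms", {
  panel <- simulate_panel(seed = 61)
  lib <- simulate_library(panel, n_null = 300, seed = 61)
  ions <- simulate_ion_tables(panel, lib, seed = 61, decoy_ratio = 2,
                              osmo_fc_range = c(2, 2))
  metab <- suppressMessages(merge_extracts(ions$polar, ions$nonpolar,
                                           lib = lib))
  fc <- differential_analysis(metab)
  planted <- ions$truth[ions$truth$effect_class ==
                          "osmoprotectant-accumulation", ]
  four_rep <- panel$meta$organism_id[panel$meta$n_bio_replicates == 4]
  found <- total <- 0
  for (i in seq_len(nrow(planted))) {
    orgs <- intersect(strsplit(planted$organisms[i], ";")[[1]], four_rep)
    sub <- fc[fc$compound_id == planted$compound_id[i], ]
    for (o in orgs) {
      total <- total + 1
      found <- found + any(sub$any_level[sub$organism_id == o], na.rm = TRUE)
    }
  }
  expect_gt(total, 100)
  expect_gte(found / total, 0.95)
})
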