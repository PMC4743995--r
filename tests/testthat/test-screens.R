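meta_two_groups <- function() {
  # six organisms in two taxonomy groups; other factors deliberately
  # uninformative (habitat/wall constant, tolerance split mirrors taxonomy)
  data.frame(organism_id = paste0("o", 1:6),
             taxonomy_group = rep(c("g1", "g2"), each = 3),
             habitat = "free-living", cell_wall = "thin",
             ic50 = rep(600, 6), stringsAsFactors = FALSE)
}

test_that("single-factor ANOVA equals the squared two-sample t-test", {
  meta <- meta_two_groups()
  fc <- matrix(c(1, 2, 3, 4, 5, 6), 1,
               dimnames = list("m1", meta$organism_id))
  res <- fourway_anova(fc, meta)$results
  # F = t^2 = 13.5, p identical to the pooled t-test p = 0.02131
  expect_equal(res$p_taxonomy_group, 0.02131, tolerance = 1e-4)
  expect_equal(res$p_taxonomy_group,
               two_sample_test(c(1, 2, 3), c(4, 5, 6))[["p"]],
               tolerance = 1e-10)
  # constant factors are untestable, group means reported regardless
  expect_true(is.na(res$p_habitat))
  expect_equal(res$maxfc_taxonomy_group, 5)  # |mean(4,5,6)| = 5
})

test_that("constant responses yield no explanatory factor", {
  meta <- meta_two_groups()
  fc <- matrix(rep(1.3, 6), 1, dimnames = list("m1", meta$organism_id))
  res <- fourway_anova(fc, meta)$results
  expect_equal(res$p_taxonomy_group, 1)
})

test_that("missing organisms trigger complete-case analysis and untestable
           factors are marked", {
  meta <- meta_two_groups()
  fc <- matrix(c(1, 2, 3, NA, NA, NA), 1,
               dimnames = list("m1", meta$organism_id))
  res <- fourway_anova(fc, meta)$results
  expect_equal(res$n_organisms, 3)
  expect_true(is.na(res$p_taxonomy_group))  # only one group left
})

test_that("ANOVA group means and standard errors come from member organisms", {
  meta <- meta_two_groups()
  fc <- matrix(c(1, 2, 3, 4, 5, 6), 1,
               dimnames = list("m1", meta$organism_id))
  gm <- fourway_anova(fc, meta)$group_means
  g <- gm[gm$factor == "taxonomy_group", ]
  expect_equal(g$mean_log2fc[g$group == "g1"], 2)
  expect_equal(g$se[g$group == "g1"], sd(1:3) / sqrt(3))
})

test_that("hit selection applies both cuts, ranks by p and counts the union
           once", {
  screen <- list(results = data.frame(
    metabolite = c("a", "b", "c"),
    p_taxonomy_group = c(0.001, 0.5, 0.004),
    maxfc_taxonomy_group = c(2, 3, 0.5),
    p_habitat = c(0.002, 0.2, 0.9),
    maxfc_habitat = c(1.5, 2, 2),
    p_cell_wall = NA_real_, maxfc_cell_wall = NA_real_,
    p_tolerance = NA_real_, maxfc_tolerance = NA_real_),
    factors = c("taxonomy_group", "habitat", "cell_wall", "tolerance"))
  class(screen) <- "anova_screen"
  hits <- select_anova_hits(screen, p_cut = 0.01, fc_cut = 1, top_k = 40)
  # a passes both factors, c fails the fold cut
  expect_equal(hits$per_factor$taxonomy_group$metabolite, "a")
  expect_equal(hits$per_factor$habitat$metabolite, "a")
  expect_equal(hits$n_union, 1)
  none <- select_anova_hits(screen, p_cut = 1e-9)
  expect_equal(none$n_union, 0)
  expect_equal(nrow(none$per_factor$taxonomy_group), 0)
})

test_that("top_k truncates reporting but not the union", {
  res <- data.frame(metabolite = paste0("m", 1:30),
                    p_taxonomy_group = seq(1e-6, 1e-3, length.out = 30),
                    maxfc_taxonomy_group = 2,
                    p_habitat = 1, maxfc_habitat = 0,
                    p_cell_wall = 1, maxfc_cell_wall = 0,
                    p_tolerance = 1, maxfc_tolerance = 0)
  screen <- structure(list(results = res,
                           factors = c("taxonomy_group", "habitat",
                                       "cell_wall", "tolerance")),
                      class = "anova_screen")
  hits <- select_anova_hits(screen, top_k = 10)
  expect_equal(nrow(hits$per_factor$taxonomy_group), 10)
  expect_equal(hits$n_per_factor[["taxonomy_group"]], 30)
  expect_equal(hits$n_union, 30)
  # ranked by ascending p
  expect_equal(hits$per_factor$taxonomy_group$metabolite[1], "m1")
})

test_that("tolerance screen computes R, the upper quartile and the hit rule", {
  ic50 <- c(o1 = 100, o2 = 200, o3 = 300)
  fc <- matrix(c(1, 2, 3), 1, dimnames = list("m", names(ic50)))
  scr <- tolerance_screen(fc, ic50)
  expect_equal(scr$r, 1)
  expect_equal(scr$n_detected, 3)
  expect_false(scr$hit)  # detected in only 3 species
  # x0.75 by linear interpolation at position 1 + 0.75 (n - 1)
  ic4 <- setNames(c(100, 200, 300, 400), paste0("o", 1:4))
  fc4 <- matrix(c(0.5, -1.5, 2.5, -3.5), 1,
                dimnames = list("m", names(ic4)))
  expect_equal(tolerance_screen(fc4, ic4)$x075, 2.75)
})

test_that("detection in more than 10 species is read strictly", {
  ic <- setNames(seq(100, 1500, length.out = 12), paste0("o", 1:12))
  fc10 <- matrix(c(0.002 * ic[1:10], NA, NA), 1,
                 dimnames = list("m", names(ic)))
  fc11 <- matrix(c(0.002 * ic[1:11], NA), 1,
                 dimnames = list("m", names(ic)))
  expect_false(tolerance_screen(fc10, ic)$hit)  # exactly 10: excluded
  expect_true(tolerance_screen(fc11, ic)$hit)   # 11 > 10
  expect_equal(tolerance_screen(fc11, ic)$direction, "correlating")
  neg <- tolerance_screen(-fc11, ic)
  expect_true(neg$hit)
  expect_equal(neg$direction, "anticorrelating")
})

test_that("tolerance screen is invariant to organism order and IC50 units", {
  set.seed(51)
  ic <- setNames(runif(12, 150, 1500), paste0("o", 1:12))
  fc <- matrix(rnorm(5 * 12, 0, 1.2), 5,
               dimnames = list(paste0("m", 1:5), names(ic)))
  base <- tolerance_screen(fc, ic)
  perm <- sample(12)
  shuffled <- tolerance_screen(fc[, perm], ic)
  expect_equal(shuffled$r, base$r)
  expect_equal(shuffled$x075, base$x075)
  rescaled <- tolerance_screen(fc, ic * 58.44)  # mM -> mg/L scaling
  expect_equal(rescaled$r, base$r)
  expect_equal(rescaled$hit, base$hit)
})

test_that("metabolites detected in under 3 organisms are excluded from R", {
  ic <- setNames(c(100, 700, 1500), paste0("o", 1:3))
  fc <- matrix(c(1, 2, NA), 1, dimnames = list("m", names(ic)))
  scr <- tolerance_screen(fc, ic)
  expect_true(is.na(scr$r))
  expect_false(scr$hit)
  expect_error(tolerance_screen(fc, ic[1:2]), "ic50")
})
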