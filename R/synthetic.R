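# Synthetic study generator.
#
# Emits a complete synthetic study — organism panel with true dose-response
# parameters, growth curves, compound library, two-phase ion tables with the
# full replicate structure, and an aligned sequence set evolved along a known
# tree — together with a machine-readable ground-truth registry, so that
# every pipeline stage can be verified by parameter recovery. All outputs are
# pure functions of (arguments, seed).
#
# Study conditions mirrored by the defaults: 16 organisms/cell systems, four
# stress levels (IC0/IC10/IC25/IC50), two extract phases, four (microbes) or
# three (human lines) biological replicates with two technical replicates
# each, log-normal intensity noise, and IC50 values spanning 150-1500 mM.

# sample() expands a length-1 numeric to 1:n; this indexer never does
sample_of <- function(x, n) x[sample.int(length(x), n)]

taxonomy_groups <- c("alpha-proteobacteria", "gamma-proteobacteria",
                     "firmicutes", "actinobacteria", "fungi", "human")
habitats <- c("free-living", "plant-associated", "animal-associated")
.level_scale <- c(IC10 = 0.4, IC25 = 0.7, IC50 = 1)

# Canonical cell-wall class per taxonomic group. The draw keeps 15% mass on
# the non-canonical classes (see vignette): a fully deterministic map would
# make the wall factor a coarsening of taxonomy and alias the ANOVA screen.
.canonical_wall <- c("alpha-proteobacteria" = "thin",
                     "gamma-proteobacteria" = "thin",
                     "firmicutes" = "thick", "actinobacteria" = "thick",
                     "fungi" = "thick", "human" = "none")

#' Simulate an organism panel
#'
#' Draws `n_organisms` cell systems with taxonomic group, habitat and
#' cell-wall labels, true dose-response parameters (IC50 = k drawn
#' log-uniformly over `ic50_range`, Hill slope h uniform in `[1.5, 3.5]`,
#' unstressed growth rate uniform in `[0.3, 1.0]` per hour), derived
#' IC10/IC25 values, and a random coalescent tree over the panel used for
#' sequence simulation.
#'
#' @param n_organisms Number of organisms (default 16; the default panel has
#'   two human cell lines with 3 biological replicates, all others 4).
#' @param seed RNG seed.
#' @param ic50_range Range of true IC50 values in mM (default 150-1500).
#' @param tree_depth Root-to-tip depth of the true tree in expected
#'   substitutions per site (default 0.3).
#' @return List of class `synthetic_panel`: `meta` (organism metadata data
#'   frame including the true IC values) and `truth` (list with `k`, `h`,
#'   `r_max` vectors and the `tree`, an `ape::phylo`).
#' @export
simulate_panel <- function(n_organisms = 16, seed = 1,
                           ic50_range = c(150, 1500), tree_depth = 0.3) {
  stopifnot(n_organisms >= 2, ic50_range[1] > 0,
            ic50_range[2] > ic50_range[1])
  set.seed(seed)
  ids <- sprintf("org%02d", seq_len(n_organisms))
  # default 16-system composition mirrors the study panel
  # (5 alpha, 3 gamma, 2 firmicutes, 2 actinobacteria, 2 fungi, 2 human)
  template <- rep(taxonomy_groups, times = c(5, 3, 2, 2, 2, 2))
  tax <- if (n_organisms == length(template)) template else
    sample(taxonomy_groups, n_organisms, replace = TRUE)
  wall <- vapply(tax, function(g) {
    if (g %in% c("human", "fungi")) return(.canonical_wall[[g]])
    if (stats::runif(1) < 0.85) .canonical_wall[[g]] else
      sample(setdiff(c("thin", "thick"), .canonical_wall[[g]]), 1)
  }, character(1))
  hab <- ifelse(tax == "human", "animal-associated",
                sample(habitats, n_organisms, replace = TRUE))
  k <- exp(stats::runif(n_organisms, log(ic50_range[1]), log(ic50_range[2])))
  h <- stats::runif(n_organisms, 1.5, 3.5)
  r_max <- stats::runif(n_organisms, 0.3, 1.0)
  ic <- function(f) k * (f / (1 - f))^(1 / h)
  meta <- data.frame(organism_id = ids, display_name = ids,
                     taxonomy_group = tax, habitat = hab, cell_wall = wall,
                     ic10 = ic(0.10), ic25 = ic(0.25), ic50 = k,
                     n_bio_replicates = ifelse(tax == "human", 3L, 4L),
                     stringsAsFactors = FALSE)
  tree <- ape::rcoal(n_organisms, tip.label = ids)
  tree$edge.length <- tree$edge.length *
    (tree_depth / max(ape::node.depth.edgelength(tree)))
  structure(list(meta = meta,
                 truth = list(k = stats::setNames(k, ids),
                              h = stats::setNames(h, ids),
                              r_max = stats::setNames(r_max, ids),
                              tree = tree)),
            class = "synthetic_panel")
}

#' Simulate growth curves
#'
#' Exponential growth at the Hill-inhibited rate
#' `r(c) = r_max / (1 + (c/k)^h)` of each organism, observed every 10
#' minutes with multiplicative log-normal noise, capped at a carrying
#' capacity. With `noise_sd = 0` the observed curves follow the model
#' exactly, so the dose-response stage recovers the true IC values to
#' numerical precision.
#'
#' @param panel A [simulate_panel()] result.
#' @param conc NaCl concentrations in mM (default: control plus 12
#'   concentrations spanning 50-2500 mM).
#' @param n_replicates Replicate curves per concentration (default 2).
#' @param noise_sd Standard deviation of log observation noise (default
#'   0.02).
#' @param times Observation times in h (default 0-24 h every 10 min).
#' @param od0 Inoculation density (default 0.01).
#' @param capacity Carrying capacity cap on the observed values (default 2).
#' @param seed RNG seed.
#' @return Data frame with columns `organism_id`, `conc`, `replicate`,
#'   `time`, `value`.
#' @export
simulate_growth <- function(panel, conc = c(0, 50, 100, 200, 300, 450, 600,
                                            800, 1000, 1300, 1700, 2100, 2500),
                            n_replicates = 2, noise_sd = 0.02,
                            times = seq(0, 24, by = 1 / 6), od0 = 0.01,
                            capacity = 2, seed = 1) {
  stopifnot(inherits(panel, "synthetic_panel"))
  set.seed(seed)
  tr <- panel$truth
  grid <- expand.grid(organism_id = panel$meta$organism_id, conc = conc,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    o <- grid$organism_id[i]
    r <- tr$r_max[o] / (1 + (grid$conc[i] / tr$k[o])^tr$h[o])
    v <- pmin(od0 * exp(r * times), capacity)
    if (noise_sd > 0) v <- v * exp(stats::rnorm(length(v), 0, noise_sd))
    data.frame(organism_id = o, conc = grid$conc[i],
               replicate = grid$replicate[i], time = times, value = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Random elemental formula with mass in a metabolite-like range.
random_formula <- function() {
  repeat {
    nc <- sample(3:30, 1)
    nh <- sample(seq(max(2, nc - 4), 2 * nc + 2), 1)
    nn <- sample(0:4, 1); no <- sample(1:10, 1)
    np <- sample(0:2, 1, prob = c(0.8, 0.15, 0.05))
    ns <- sample(0:1, 1, prob = c(0.9, 0.1))
    f <- paste0("C", nc, "H", nh, if (nn) paste0("N", nn) else "",
                "O", no, if (np) paste0("P", np) else "",
                if (ns) paste0("S", ns) else "")
    m <- monoisotopic_mass(f)
    if (m >= 80 && m <= 900) return(f)
  }
}

#' Simulate a compound library
#'
#' Extends the bundled metabolite library (see [example_compound_library()])
#' with `n_null` generated compounds of random elemental formula, logP drawn
#' from N(-2, 1.5) and random organism associations (each organism with
#' probability `assoc_prob`, at least 3 per compound). Generated compounds
#' carry no planted effects unless [simulate_ion_tables()] assigns them one.
#'
#' @param panel A [simulate_panel()] result.
#' @param n_null Number of generated compounds (default 150).
#' @param assoc_prob Per-organism association probability (default 0.85).
#' @param seed RNG seed.
#' @return A [compound_library()].
#' @export
simulate_library <- function(panel, n_null = 150, assoc_prob = 0.85,
                             seed = 1) {
  stopifnot(inherits(panel, "synthetic_panel"))
  set.seed(seed)
  base <- example_compound_library()
  orgs <- panel$meta$organism_id
  base$organism_ids <- ""  # fixture associations name the real panel, not ours
  if (n_null > 0) {
    extra <- data.frame(
      compound_id = sprintf("null%03d", seq_len(n_null)),
      name = sprintf("synthetic compound %03d", seq_len(n_null)),
      formula = vapply(seq_len(n_null), function(i) random_formula(),
                       character(1)),
      logp = stats::rnorm(n_null, -2, 1.5),
      organism_ids = vapply(seq_len(n_null), function(i) {
        assoc <- orgs[stats::runif(length(orgs)) < assoc_prob]
        if (length(assoc) < 3) assoc <- sample(orgs, 3)
        paste(assoc, collapse = ";")
      }, character(1)),
      is_osmoprotectant = FALSE, stringsAsFactors = FALSE)
    base <- rbind(base[names(extra)], extra)
  }
  compound_library(base)
}

#' Simulate two-phase ion tables with planted effects
#'
#' Generates the metabolomics measurement of a synthetic study. Baseline
#' log2 abundances are normal per (metabolite, organism); planted effects
#' shift the stress-level means on the log2 scale, graded over levels
#' (IC10/IC25/IC50 scaled 0.4/0.7/1):
#'
#' * `osmoprotectant-accumulation` — every library osmoprotectant
#'   accumulates in each organism with probability `p_osmo`, with an
#'   IC50-level log2 fold-change drawn uniformly from `osmo_fc_range`;
#' * `tolerance-correlated-positive` / `-negative` — `n_tol_pos` /
#'   `n_tol_neg` metabolites whose IC50-level log2 fold-change is
#'   `beta * ic50 + eps`, `eps ~ N(0, sigma_tol)`, with `beta = +-tol_beta`;
#' * `factor-specific` — `n_factor` metabolites sharing a common offset
#'   (magnitude uniform in `factor_fc_range`, random sign) within one random
#'   level of one of the four screen factors;
#' * `species-specific` — `n_species` metabolites responding (magnitude
#'   uniform in `factor_fc_range`, random sign) in one or two organisms only;
#' * `null` — everything else.
#'
#' Each metabolite emits its `[M-H]-` and `[M-H]+13C` features (the
#' isotopologue at `c13_ratio` of the parent intensity) in the extract phase
#' selected by its logP, at the expected m/z plus a uniform jitter within
#' `mass_jitter` Da; `decoy_ratio` times as many decoy features matching no
#' library mass are added per phase. Replicate noise is multiplicative
#' log-normal (`cv_bio` between biological replicates, `cv_tech` between
#' technical re-draws). Organisms not associated with a compound have
#' missing intensities at its features.
#'
#' @param panel A [simulate_panel()] result.
#' @param lib A [compound_library()] (e.g. [simulate_library()]).
#' @param seed RNG seed.
#' @param p_osmo,osmo_fc_range Osmoprotectant accumulation probability and
#'   IC50-level log2 fold-change range.
#' @param n_tol_pos,n_tol_neg,tol_beta,sigma_tol Tolerance-correlated
#'   plantings: counts, slope (log2 FC per mM IC50) and organism-level
#'   scatter. Slope and scatter default to `NULL`, meaning they are
#'   calibrated to the realized panel so that planted metabolites sit at
#'   `x0.75 = tol_x075_target` and expected Pearson `|R| = tol_r_target`;
#'   a slope/noise combination whose expected `|R|` falls below 0.5 draws a
#'   warning (the screen is then unrecoverable by construction).
#' @param tol_x075_target,tol_r_target Calibration targets for the planted
#'   tolerance-correlated relationship (defaults 1.5 and 0.8).
#' @param n_factor,n_species,factor_fc_range Factor- and species-specific
#'   plantings.
#' @param cv_bio,cv_tech Coefficients of variation of biological and
#'   technical replicate noise.
#' @param mass_jitter Half-width of the uniform m/z jitter in Da.
#' @param decoy_ratio Decoy features per true feature.
#' @param c13_ratio Isotopologue-to-parent intensity ratio.
#' @param baseline_mean,baseline_sd,organism_sd Baseline log2 abundance
#'   model.
#' @return List of class `synthetic_ions`: `polar` and `nonpolar`
#'   [ion_table()]s, and `truth` (data frame: `compound_id`, `effect_class`,
#'   `param`, `organisms`).
#' @export
simulate_ion_tables <- function(panel, lib, seed = 1,
                                p_osmo = 0.6, osmo_fc_range = c(1, 3),
                                n_tol_pos = 10, n_tol_neg = 10,
                                tol_beta = NULL, sigma_tol = NULL,
                                tol_x075_target = 1.5, tol_r_target = 0.8,
                                n_factor = 8, n_species = 10,
                                factor_fc_range = c(2.5, 5),
                                cv_bio = 0.2, cv_tech = 0.1,
                                mass_jitter = 0.004, decoy_ratio = 10,
                                c13_ratio = 0.3,
                                baseline_mean = 14, baseline_sd = 1.5,
                                organism_sd = 0.5) {
  stopifnot(inherits(panel, "synthetic_panel"),
            inherits(lib, "compound_library"))
  set.seed(seed)
  meta <- panel$meta
  orgs <- meta$organism_id
  n_org <- length(orgs)
  n_comp <- nrow(lib)
  assoc <- vapply(orgs, function(o) compound_matches_organism(lib, o),
                  logical(n_comp))  # n_comp x n_org
  dimnames(assoc) <- list(lib$compound_id, orgs)

  # --- effect registry -------------------------------------------------
  E <- matrix(0, n_comp, n_org, dimnames = dimnames(assoc))
  class_of <- stats::setNames(rep("null", n_comp), lib$compound_id)
  param <- stats::setNames(rep(NA_real_, n_comp), lib$compound_id)
  affected <- stats::setNames(rep("", n_comp), lib$compound_id)

  osmo <- which(lib$is_osmoprotectant)
  for (i in osmo) {
    hit <- which(assoc[i, ] & stats::runif(n_org) < p_osmo)
    if (!length(hit)) next
    E[i, hit] <- stats::runif(length(hit), osmo_fc_range[1], osmo_fc_range[2])
    class_of[i] <- "osmoprotectant-accumulation"
    affected[i] <- paste(orgs[hit], collapse = ";")
  }

  # Non-osmoprotectant planted effects go on compounds whose measured ion
  # species collide with no other library compound (neither isobaric nor
  # offset by the 13C isotopologue spacing, within 0.02 Da), so that the
  # planted truth is identifiable despite accurate-mass ambiguity: a
  # colliding partner's features would dilute the compound-level fold-change
  # of a planted metabolite with null signal. Ambiguity handling itself is
  # exercised by the remaining isobaric pairs.
  mass_unique <- vapply(seq_len(n_comp), function(i) {
    dm <- abs(lib$mass[-i] - lib$mass[i])
    all(pmin(dm, abs(dm - c13_delta)) > 0.02)
  }, logical(1))

  universal <- which(class_of == "null" & rowSums(assoc) == n_org & mass_unique)
  n_tol <- n_tol_pos + n_tol_neg
  if (length(universal) < n_tol) {
    stop("library has too few universally associated compounds for the ",
         "requested tolerance-correlated plantings")
  }
  # Calibrate the planted linear IC50 relationship to the panel actually
  # drawn: the slope puts the expected realized x0.75 of |log2 FC| of a
  # planted metabolite at tol_x075_target, and the organism-level scatter is
  # set so the expected Pearson R is tol_r_target once measurement noise
  # (replicate averaging at cv_bio) is accounted for. The x0.75 expectation
  # is evaluated by Monte Carlo under the generator's own noise model, since
  # noise biases the sample quantile of the skewed |beta * ic50| profile.
  sd_bio <- sqrt(log(1 + cv_bio^2)) / log(2)
  var_meas <- 2 * sd_bio^2 / mean(meta$n_bio_replicates)
  exp_x075 <- function(beta, sig) {
    stats::median(vapply(seq_len(200), function(i) {
      stats::quantile(abs(beta * meta$ic50 +
                            stats::rnorm(n_org, 0, sqrt(sig^2 + var_meas))),
                      0.75, names = FALSE)
    }, numeric(1)))
  }
  fixed_beta <- !is.null(tol_beta)
  fixed_sigma <- !is.null(sigma_tol)
  if (!fixed_beta) {
    tol_beta <- tol_x075_target /
      stats::quantile(meta$ic50, 0.75, names = FALSE)
  }
  for (it in 1:3) {
    if (!fixed_sigma) {
      var_tot <- (tol_beta * stats::sd(meta$ic50))^2 *
        (1 / tol_r_target^2 - 1)
      sigma_tol <- sqrt(max(var_tot - var_meas, 1e-4))
    }
    if (fixed_beta) break
    tol_beta <- tol_beta * tol_x075_target / exp_x075(tol_beta, sigma_tol)
  }
  signal_sd <- tol_beta * stats::sd(meta$ic50)
  exp_r <- signal_sd / sqrt(signal_sd^2 + sigma_tol^2 + var_meas)
  if (exp_r < 0.5) {
    warning(sprintf(paste0("planted tolerance-correlated effects are not ",
                           "recoverable by construction: expected |R| = %.2f ",
                           "< 0.5 at this slope/noise"), exp_r))
  }
  tol_idx <- sample_of(universal, n_tol)
  betas <- rep(c(tol_beta, -tol_beta), c(n_tol_pos, n_tol_neg))
  for (j in seq_along(tol_idx)) {
    i <- tol_idx[j]
    E[i, ] <- betas[j] * meta$ic50 + stats::rnorm(n_org, 0, sigma_tol)
    class_of[i] <- if (betas[j] > 0) "tolerance-correlated-positive" else
      "tolerance-correlated-negative"
    param[i] <- betas[j]
    affected[i] <- paste(orgs, collapse = ";")
  }

  fac <- data.frame(taxonomy_group = meta$taxonomy_group,
                    habitat = meta$habitat, cell_wall = meta$cell_wall,
                    tolerance = as.character(tolerance_class(meta$ic50)),
                    stringsAsFactors = FALSE)
  # Factor-specific effects are planted only on identifiable factor levels:
  # a level whose organism set is (nearly) reproducible from the other three
  # factors — e.g. cell wall "none", which coincides with the human group —
  # carries no unique added-last variance, so the planted truth would be
  # unattributable by construction. Identifiability is checked by regressing
  # the level indicator on the other factors' design matrix.
  identifiable_level <- function(f, lev) {
    z <- as.numeric(fac[[f]] == lev)
    if (sum(z) < 2 || sum(z) > n_org - 2) return(FALSE)
    others <- stats::model.matrix(
      stats::reformulate(setdiff(screen_factors, f)),
      data.frame(lapply(fac, factor)))
    res <- stats::lm.fit(others, z)$residuals
    r2 <- 1 - sum(res^2) / sum((z - mean(z))^2)
    is.finite(r2) && r2 < 0.6
  }
  pool <- which(class_of == "null" & rowSums(assoc) >= n_org - 2 & mass_unique)
  fs_idx <- sample_of(pool, min(n_factor, length(pool)))
  for (j in seq_along(fs_idx)) {
    i <- fs_idx[j]
    f <- lev <- NULL
    for (try in 1:25) {
      f_try <- if (try == 1)
        screen_factors[1 + (j - 1) %% length(screen_factors)] else
          sample(screen_factors, 1)
      lev_try <- sample(unique(fac[[f_try]]), 1)
      if (identifiable_level(f_try, lev_try)) {
        f <- f_try; lev <- lev_try
        break
      }
    }
    if (is.null(f)) next  # no identifiable level found; leave as null
    members <- which(fac[[f]] == lev)
    eff <- sample(c(-1, 1), 1) * stats::runif(1, factor_fc_range[1],
                                              factor_fc_range[2])
    E[i, members] <- eff
    class_of[i] <- "factor-specific"
    param[i] <- eff
    affected[i] <- paste0(f, "=", lev)
  }

  pool <- setdiff(which(class_of == "null" & mass_unique), fs_idx)
  sp_idx <- sample_of(pool, min(n_species, length(pool)))
  for (i in sp_idx) {
    cand <- which(assoc[i, ])
    hit <- sample_of(cand, min(sample(1:2, 1), length(cand)))
    eff <- sample(c(-1, 1), 1) * stats::runif(1, factor_fc_range[1],
                                              factor_fc_range[2])
    E[i, hit] <- eff
    class_of[i] <- "species-specific"
    param[i] <- eff
    affected[i] <- paste(orgs[hit], collapse = ";")
  }

  # --- intensities ------------------------------------------------------
  sd_tech <- sqrt(log(1 + cv_tech^2)) / log(2)
  mu <- stats::rnorm(n_comp, baseline_mean, baseline_sd)
  delta <- matrix(stats::rnorm(n_comp * n_org, 0, organism_sd), n_comp, n_org)
  phase <- as.character(select_phase(lib))
  jit <- function(n) stats::runif(n, -mass_jitter, mass_jitter)
  mz_mono <- expected_mz(lib$mass, "[M-H]-") + jit(n_comp)
  mz_c13 <- expected_mz(lib$mass, "[M-H]+13C") + jit(n_comp)

  tabs <- list()
  truth_levels <- setdiff(stress_levels, "IC0")
  for (ph in extract_phases) {
    in_ph <- which(phase == ph)
    design <- do.call(rbind, lapply(seq_len(n_org), function(oi) {
      nb <- meta$n_bio_replicates[oi]
      d <- expand.grid(tech_replicate = 1:2, bio_replicate = seq_len(nb),
                       stress_level = stress_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      d$organism_id <- orgs[oi]
      d$extract_phase <- ph
      d
    }))
    design$sample_id <- paste(design$organism_id, design$stress_level,
                              design$bio_replicate, design$tech_replicate,
                              substr(ph, 1, 3), sep = "_")
    n_samp <- nrow(design)
    scale <- c(IC0 = 0, .level_scale)[design$stress_level]
    # log2 mean per (compound-in-phase, sample) before replicate noise
    V <- matrix(NA_real_, length(in_ph), n_samp)
    oi_of <- match(design$organism_id, orgs)
    bio_key <- paste(design$organism_id, design$stress_level,
                     design$bio_replicate)
    ubio <- unique(bio_key)
    Bnoise <- matrix(stats::rnorm(length(in_ph) * length(ubio), 0, sd_bio),
                     length(in_ph), length(ubio))
    bcol <- match(bio_key, ubio)
    for (s in seq_len(n_samp)) {
      oi <- oi_of[s]
      V[, s] <- mu[in_ph] + delta[in_ph, oi] + E[in_ph, oi] * scale[s] +
        Bnoise[, bcol[s]]
    }
    mono <- V + matrix(stats::rnorm(length(V), 0, sd_tech), nrow(V))
    c13 <- V + log2(c13_ratio) +
      matrix(stats::rnorm(length(V), 0, sd_tech), nrow(V))
    absent <- !assoc[in_ph, oi_of, drop = FALSE]
    mono[absent] <- NA_real_
    c13[absent] <- NA_real_
    intens <- rbind(2^mono, 2^c13)
    mz <- c(mz_mono[in_ph], mz_c13[in_ph])
    # decoys: features matching no expected library m/z
    n_decoy <- round(decoy_ratio * length(mz))
    if (n_decoy > 0) {
      all_exp <- sort(c(expected_mz(lib$mass, "[M-H]-"),
                        expected_mz(lib$mass, "[M-H]+13C")))
      dmz <- numeric(0)
      while (length(dmz) < n_decoy) {
        cand <- stats::runif(2 * n_decoy, 50, 1000)
        near <- findInterval(cand, all_exp)
        dist_lo <- cand - all_exp[pmax(near, 1)]
        dist_hi <- all_exp[pmin(near + 1, length(all_exp))] - cand
        ok <- pmin(abs(dist_lo), abs(dist_hi)) > 0.006
        dmz <- c(dmz, cand[ok])
      }
      dmz <- dmz[seq_len(n_decoy)]
      dmu <- stats::rnorm(n_decoy, baseline_mean, baseline_sd)
      dint <- 2^(matrix(dmu, n_decoy, n_samp) +
                   matrix(stats::rnorm(n_decoy * n_samp, 0, sd_bio + sd_tech),
                          n_decoy, n_samp))
      mz <- c(mz, dmz)
      intens <- rbind(intens, dint)
    }
    ord <- order(mz)
    tabs[[ph]] <- ion_table(mz[ord], intens[ord, , drop = FALSE], design)
  }

  truth <- data.frame(compound_id = lib$compound_id,
                      effect_class = unname(class_of),
                      param = unname(param),
                      organisms = unname(affected),
                      stringsAsFactors = FALSE)
  attr(truth, "planted_fc") <- E  # IC50-level log2 effects, compound x organism
  attr(truth, "tol_beta") <- tol_beta
  attr(truth, "sigma_tol") <- sigma_tol
  structure(list(polar = tabs$polar, nonpolar = tabs$nonpolar, truth = truth),
            class = "synthetic_ions")
}

#' Simulate an alignment along a tree
#'
#' Evolves equal-rate four-state (Jukes-Cantor) sequences along a tree with
#' branch lengths in expected substitutions per site.
#'
#' @param tree An `ape::phylo` tree.
#' @param length Alignment length in columns (default 2000).
#' @param seed RNG seed.
#' @return Named character vector of aligned sequences (one per tip).
#' @export
simulate_alignment <- function(tree, length = 2000, seed = 1) {
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA")
  chars <- toupper(as.character(sim))
  stats::setNames(apply(chars, 1, paste, collapse = ""), rownames(chars))
}

#' Simulate fold-changes diverging along a tree
#'
#' Draws organism response profiles with phylogenetic covariance: each
#' metabolite's fold-change vector is Brownian motion along the tree
#' (covariance `sigma_phylo^2 * vcv(tree)`) plus independent noise
#' `N(0, sigma_ind^2)`. Used to verify that the cladogram and the
#' distance-correlation test recover tree-structured signal.
#'
#' @param tree An `ape::phylo` tree.
#' @param n_metabolites Number of metabolite columns (default 150).
#' @param sigma_phylo,sigma_ind Phylogenetic and independent noise scales.
#' @param seed RNG seed.
#' @return Organism-by-metabolite matrix (rows named by tip label).
#' @export
simulate_phylo_foldchanges <- function(tree, n_metabolites = 150,
                                       sigma_phylo = 1, sigma_ind = 0.3,
                                       seed = 1) {
  set.seed(seed)
  C <- ape::vcv(tree)
  L <- chol(C + diag(1e-10, nrow(C)))
  n <- nrow(C)
  X <- sigma_phylo * t(L) %*% matrix(stats::rnorm(n * n_metabolites), n) +
    matrix(stats::rnorm(n * n_metabolites, 0, sigma_ind), n)
  rownames(X) <- rownames(C)
  X
}

#' Simulate a complete study
#'
#' Convenience wrapper generating the organism panel, compound library,
#' two-phase ion tables and aligned sequences in one call, with all
#' randomness derived from one seed.
#'
#' @param seed RNG seed.
#' @param n_organisms,n_null Panel and library sizes.
#' @param alignment_length Columns in the simulated alignment.
#' @param ... Passed to [simulate_ion_tables()].
#' @return List of class `synthetic_study` with `panel`, `lib`, `ions`
#'   (polar/nonpolar tables plus effect truth) and `alignment`.
#' @export
simulate_study <- function(seed = 1, n_organisms = 16, n_null = 150,
                           alignment_length = 2000, ...) {
  panel <- simulate_panel(n_organisms = n_organisms, seed = seed)
  lib <- simulate_library(panel, n_null = n_null, seed = seed + 1L)
  ions <- simulate_ion_tables(panel, lib, seed = seed + 2L, ...)
  aln <- simulate_alignment(panel$truth$tree, length = alignment_length,
                            seed = seed + 3L)
  structure(list(panel = panel, lib = lib, ions = ions, alignment = aln),
            class = "synthetic_study")
}
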