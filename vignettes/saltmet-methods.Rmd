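---
title: "Methods: cross-species salt-stress metabolomics with saltmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species salt-stress metabolomics with saltmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmet)
```

`saltmet` analyzes nontargeted flow-injection mass-spectrometry (FIA-MS)
metabolomics of organisms under sustained hyperosmotic salt stress. The
design of such a study: a panel of diverse cell systems (bacteria, yeasts,
human cell lines) is each grown at its own unstressed control (IC0) and at
salt concentrations inhibiting its growth rate by 10, 25 and 50 percent
(IC10/IC25/IC50), so that stress *severity* is comparable across organisms
whose absolute tolerances differ by an order of magnitude. Intracellular
metabolites are extracted in a polar and a nonpolar phase and measured by
negative-mode FIA-TOF MS as centroided accurate-mass ion tables. This
vignette documents the models, the parameter choices and their rationale,
the synthetic-data generator, and the numerical decisions.

## Dose-response stage

Growth curves are reduced to a maximum exponential growth rate: the largest
slope of a least-squares line through log(OD) over a sliding window of
consecutive points. The window defaults to 8 points (80 minutes at the
usual 10-minute sampling); it is long enough to suppress plate-reader
noise and short enough to sit inside the exponential phase. It is an
argument of `max_growth_rate()` and `ic_from_growth()`.

Rates normalized to the unstressed control are fitted with a
three-parameter Hill inhibition curve

$$ r(c) = \frac{top}{1 + (c/k)^h}, \qquad top \in [0.8, 1.2],\; k > 0,\; h > 0 $$

with the bottom fixed at 0. This is the fewest-parameter sigmoid
consistent with control-normalized rates: the top is a free parameter near
1 to absorb normalization error, and complete growth arrest at saturating
salt fixes the bottom. Fitting is nonlinear least squares
(Levenberg–Marquardt) with multi-start initialization over a grid of
plausible $(k, h)$ values; the best converged start wins. Inhibitory
concentrations come from the closed-form inverse
$IC_f = k\,(f/(1-f))^{1/h}$, so $IC_{50} = k$ exactly. When the fitted $k$
exceeds the largest tested concentration the IC values are extrapolations
and the fit is flagged `determined = FALSE` rather than silently reported.

Replicate handling: a dose-response curve is fitted per replicate series and
IC values are reported as mean ± SD across replicates (`ic_from_growth()`).
Pooling replicates into one fit would be equally defensible; the
per-replicate route also yields the dispersion estimate. For adherent cell
lines, endpoint cell counts (via a linear fluorescence calibration fitted
in its unsaturated range, `fluorescence_calibration()`) replace growth
rates in the same sigmoid.

## Annotation stage

Features are matched by accurate mass within an **absolute** tolerance,
default 0.005 Da (not ppm — FIA-TOF calibration error is roughly constant
across the 50–1000 m/z range), against the expected m/z of two ion
species per library compound: the deprotonated ion
$[M-H]^-$ at neutral mass − 1.0072765 Da (the proton mass, so the electron
mass is treated correctly — at a 0.005 Da tolerance the ~0.0005 Da electron
mass is not negligible across a window), and the one-¹³C isotopologue at
+1.0033548 Da. Monoisotopic masses are computed from a bundled constant
table (`atomic_masses`) so mass arithmetic never depends on an external
chemistry library and is bit-reproducible.

Accurate mass cannot separate isobaric compounds; every candidate within
the window is kept and the feature flagged ambiguous. When several features
annotate one metabolite in its selected phase, each is kept as a separate
row of the metabolite table — duplicate names then denote different ions of
the same metabolite, and the ¹³C isotopologue is deliberately *not* summed
into the monoisotopic row.

Phase routing uses the octanol/water partition coefficient: logP ≤ 0 reads
the polar extract, logP > 0 the nonpolar extract. The bundled library's
logP values are literature-typical assignments whose only role is this
routing.

## Differential stage

Quantile normalization (via `limma::normalizeQuantiles`, ties averaged) is
applied separately per organism — its purpose is correcting biomass
differences between samples of one organism's experiment, and pooling
distributions across organisms with genuinely different metabolomes would
be wrong. Technical replicates are averaged into their biological
replicate before any testing, giving n = 4 (microbes) or n = 3 (human
lines) independent observations per condition.

Per metabolite, organism and stress level the summary is
$\log_2(\text{mean stressed bio-replicate intensity}) -
\log_2(\text{mean IC0 intensity})$; the test is Student's pooled-variance
two-sided t on the log2 replicate intensities (log2 both stabilizes the
multiplicative noise and matches the fold-change scale). Multiple testing
is controlled by Storey–Tibshirani q-values implemented in `qvalues()`:
$\hat\pi_0$ from a df-3 smoothing spline through
$\#\{p > \lambda\} / (m(1-\lambda))$ over $\lambda = 0, 0.05, \ldots,
0.90$, evaluated at 0.90 and clamped to (0, 1]; then
$q_{(i)} = \hat\pi_0\, m\, p_{(i)}/i$ with monotonicity enforced from the
largest p downward (forcing $\pi_0 = 1$ recovers Benjamini–Hochberg
exactly, which the tests assert against `p.adjust`). The FDR family is all
ions × stress levels within one organism, matching the per-organism
structure of the analysis; the choice is documented rather than prescribed
by the data. A record is *differential* at |log2 FC| ≥ 1 and q < 0.05, and
a metabolite is differential for an organism if any level qualifies.

Cross-species baseline comparison standardizes the organism-mean log2 IC0
abundance of each metabolite across organisms (Z-scores); |Z| < 1 is
flagged "small", constant metabolites get Z = 0 with a zero-variance flag.

A sensitivity limit worth knowing: with three biological replicates the
pooled t-test has 4 degrees of freedom, so even a clean 4-fold effect at
20% CV cannot produce p-values much below $10^{-3}$; inside a
$\sim 10^4$-test family such records only reach q < 0.05 when the family
contains hundreds of stronger effects. Detection power for the
three-replicate (human) systems is therefore intrinsically lower than for
the four-replicate microbes — a property of the study design, not of the
implementation.

## Comparative stage

PCA column-centers the fold-change matrix (missing values imputed to 0 =
"unchanged versus control"; PCA needs a complete matrix) and decomposes by
SVD. Distances, in contrast, are computed pairwise-complete **without**
imputation or missingness rescaling: the Cityblock distance is the plain
sum of absolute differences over entries present in both rows (note that
`stats::dist` would rescale by the number of missing entries, which is why
the package computes this sum itself). Cladograms use agglomerative
clustering with average linkage by default (a common choice for
non-Euclidean metrics; single/complete/Ward are available), with Newick
export through `ape`.

Jukes–Cantor distances $d = -\tfrac34 \ln(1 - \tfrac43 p)$ use the
mismatch fraction p over alignment columns where both sequences carry an
unambiguous base. Saturated pairs (p ≥ 3/4) are undefined and flagged
rather than clipped. The implementation is the package's own so these
semantics are explicit; the test suite cross-checks it against
`ape::dist.dna` on simulated gapped alignments.

The association between metabolic-response distances and phylogenetic
distances is tested by a Mantel permutation test (`vegan::mantel`,
one-sided for positive association, 999 permutations by default). A
t-based p-value with $\binom{n}{2} - 2$ degrees of freedom is reported
alongside but labeled approximate: distance pairs are not independent, so
the permutation p is primary and the package makes no claim to reproduce
any particular parametric p-value for this statistic.

## Screens

**Four-way ANOVA screen.** Per metabolite, IC50-level log2 fold-changes
across organisms are modeled by a main-effects-only linear model on four
categorical factors: taxonomic group, habitat, cell-wall class, and
tolerance class (`tolerance_class()` bins: IC50 < 500 mM low, 500–1000
medium with both boundaries inclusive, > 1000 high). Each factor is tested
by its partial (added-last) sum of squares — `drop1(..., test = "F")` —
the standard convention for unbalanced main-effects models; with 16
organisms and correlated factors this is deliberately conservative: an
effect on a factor level that is reproducible from the other factors earns
no unique variance. Organisms missing a metabolite are dropped per
metabolite; a factor reduced to one level, or without residual df, is
marked untestable rather than forced. Hits require factor p < 0.01 and a
group-mean |log2 FC| > 1 in at least one of the factor's groups; per-factor
lists are ranked by p and truncated to 40 for reporting, while the union
count across factors is taken before truncation.

**Tolerance correlation screen.** Per metabolite detected in more than 10
organisms (strictly: ≥ 11), Pearson's R between IC50-level fold-changes
and organism IC50 values, and the upper quartile $x_{0.75}$ of the
absolute fold-changes. The quartile uses linear interpolation between
order statistics at position $1 + 0.75(n-1)$ — R's default type-7
convention (configurable at the `quantile` level if ever needed). Hits
require |R| > 0.5 and $x_{0.75} > 1$, split into correlating (R > 0.5) and
anticorrelating (R < −0.5). The screen is invariant to organism order and
to any common rescaling of the IC50 units.

Because the differential table carries one row per metabolite *ion*, the
screens operate on a compound-level matrix in which the rows of one
compound are averaged (`compound_fc_matrix()`); they measure the same
underlying quantity, and averaging halves their independent technical
noise.

## The synthetic-data generator

`simulate_study()` emits a complete study whose defaults are the study
conditions: 16 cell systems (two of them "human" lines with 3 biological
replicates, all others 4), true IC50 drawn log-uniformly over 150–1500 mM
(the span of tolerances in such panels), Hill slopes in [1.5, 3.5], four
stress levels, two extract phases, two technical replicates, multiplicative
log-normal intensity noise (20% CV biological, 10% technical — standard
magnitudes for FIA-MS intensities, and positivity-preserving), and ten
decoy (unannotatable) features per true feature, echoing the roughly 10:1
ratio of detected ions to annotated metabolites in real FIA-TOF data.
Every output is a pure function of (arguments, seed).

Planted effects, all on the log2 scale so truth comparisons are exact, and
graded over stress levels (0.4/0.7/1 of the IC50-level effect at
IC10/IC25/IC50):

* *osmoprotectant accumulation* — each flagged library osmoprotectant
  accumulates in each organism with probability 0.6, log2 FC drawn from
  U(1, 3) at IC50;
* *tolerance-correlated* — log2 FC $= \beta \cdot IC50 + \varepsilon$.
  By default $\beta$ and $sd(\varepsilon)$ are **calibrated to the realized
  panel**: $\beta$ is chosen (by a small Monte Carlo under the generator's
  own noise model) so the expected realized $x_{0.75}$ of a planted
  metabolite is 1.5, and the scatter so its expected |R| is 0.8 after
  accounting for replicate-averaging measurement noise. Calibration is
  necessary because the sample upper quartile of the skewed
  $|\beta \cdot IC50|$ profile is biased downward by symmetric noise, and
  because the IC50 spread varies between panel draws. A slope/noise
  combination whose expected |R| falls below the 0.5 hit threshold draws a
  warning: the screen would be unrecoverable by construction;
* *factor-specific* — a common offset, magnitude U(2.5, 5) with random
  sign, within one level of one screen factor. Magnitudes sit in the
  strong single-group-response regime (comparable to the largest group
  effects such panels show); smaller effects are not reliably detectable
  at p < 0.01 with only ~4 residual degrees of freedom in the four-factor
  model. Only *identifiable* factor levels are planted: a level whose
  organism indicator is nearly reproducible from the other three factors
  (R² ≥ 0.6 against their design matrix — e.g. "no cell wall", which
  coincides with the human group) carries no unique added-last variance,
  so an effect planted there would be unattributable in principle;
* *species-specific* — a strong response in one or two organisms;
* everything else is *null*.

Two identifiability guards shape where effects are planted. First,
non-osmoprotectant effects go only on compounds whose ion species collide
with no other library mass (neither isobaric nor offset by the ¹³C
spacing, within 0.02 Da): a colliding partner's features annotate to the
planted compound and dilute its compound-level fold-change with null
signal. Accurate-mass ambiguity itself remains present in the data via the
deliberately isobaric pairs of the bundled library (sorbitol/mannitol,
inositol/hexose, the phosphohexoses, leucine/isoleucine). Second,
cell-wall class is drawn with 15% probability of a non-canonical value per
taxonomic group, because a fully deterministic taxonomy→wall map would
alias the two factors outright.

What the generator does **not** emulate: realistic isotope-pattern
intensity ratios (the ¹³C feature is a fixed 0.3 of the parent),
chromatographic or batch effects, ionization suppression, missingness
mechanisms beyond organism–compound association, and real biological
covariance between metabolites. Passing recovery tests therefore certifies
the inference machinery — windows, tests, corrections, screens — under a
controlled noise model, not performance on any particular real dataset.

Aligned sequences are evolved along the panel's true coalescent tree under
the equal-rates four-state substitution model (`phangorn::simSeq`), with
root-to-tip depth 0.3 substitutions/site so pairwise distances stay well
below the p = 3/4 saturation point. `simulate_phylo_foldchanges()`
separately generates organism response profiles with Brownian covariance
along the tree, used to verify that the cladogram and the Mantel test
recover tree-structured signal.

## Numerical choices and degenerate inputs

* Mass arithmetic uses bundled monoisotopic constants (≥ 6 decimals);
  unknown elements are hard errors, never silently skipped.
* Window queries use a sorted expected-m/z index with `findInterval`; the
  test suite proves equivalence to the brute-force all-pairs scan at
  10³ compounds × 10⁴ features.
* Zero pooled variance with equal means gives t = 0, p = 1 by convention;
  with unequal means, p = 0. Groups of fewer than two replicates are not
  tested.
* Zero or negative means after normalization yield a missing fold-change,
  excluded from testing — never an imputed zero (imputation is reserved
  for the PCA, where it is the explicit "unchanged" convention).
* Dose-response fits at the parameter bounds (e.g. flat rate profiles)
  are flagged `determined = FALSE`; non-convergence from every start is an
  error carrying the optimizer diagnostics.
* Ties in clustering are broken deterministically by input label order;
  trees are invariant (as topologies) to label permutations.

## Problem sizes in the test suite

The suite verifies: annotation against the brute-force oracle at 10³
compounds × 10⁴ features; q-value equivalence with Benjamini–Hochberg and
a null differential-call rate below 5% on a full no-effect study; IC
recovery exactly (< 10⁻⁶ relative) on noiseless sigmoids and with median
error < 5% over 100 noisy organisms; Jukes–Cantor consistency on a
10⁵-column alignment (≤ 5% deviation from true path lengths); Mantel
calibration under the null and > 0.9 power on tree-structured responses
(n = 16, 999 permutations); and end-to-end recovery over 50 generated
studies at full defaults — ≥ 90% sensitivity and ≤ 5% false-positive rate
for planted tolerance-correlated metabolites, and ≥ 95% correct-factor
attribution for planted factor-specific effects. These sizes were chosen
as the smallest at which each property is a stable, study-like statement.

## Known limitations

* Quantile normalization rank-compresses individual large fold-changes
  where the intensity distribution's tails are sparse; at the generator's
  feature count this costs about 7% of a planted fold-change at the
  median. Real FIA-TOF tables with ~2 × 10⁴ features have denser quantile
  grids and smaller compression.
* Annotation is accurate-mass only: isobaric compounds are inseparable by
  design, and the package propagates rather than resolves the ambiguity.
* The four-way ANOVA on 16 organisms has ~4 residual degrees of freedom;
  only strong group effects are detectable at p < 0.01, and effects on
  factor levels confounded with other factors are unattributable (the
  added-last convention makes this explicit).
* Three-replicate systems have a p-value floor that limits their
  per-organism detection power inside large FDR families (see the
  differential section).
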