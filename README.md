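# saltmet

Cross-species metabolomics of hyperosmotic salt stress.

`saltmet` implements, as a tested reusable R package, the full inference
pipeline for nontargeted flow-injection mass-spectrometry studies of salt
stress across a diverse organism panel (bacteria, yeasts, human cell lines):
from growth-inhibition dose-response fitting and accurate-mass ion
annotation through differential calling, cross-species distance analysis,
and two hit-finding screens. A first-class synthetic-data generator emits a
complete study with machine-readable ground truth, so every stage is
verifiable by parameter recovery without any external data.

## The models at the core

**Salt tolerance.** Maximum exponential growth rates r(c) at NaCl
concentration c are fitted with a three-parameter Hill inhibition curve

    r(c) = top / (1 + (c/k)^h),    top in [0.8, 1.2], k > 0, h > 0

with the bottom fixed at 0 (rates are normalized to the unstressed
control). The concentration inhibiting growth by a fraction f is
IC_f = k (f/(1-f))^(1/h); in particular IC50 = k. Tolerance classes bin
IC50 as low (< 500 mM), medium (500-1000 mM, boundaries inclusive) and
high (> 1000 mM).

**Annotation.** Centroided negative-mode ions are matched within an
absolute tolerance (default 0.005 Da) to the expected m/z of the
deprotonated ([M-H]⁻, neutral monoisotopic mass − 1.0072765 Da) and
one-¹³C isotopologue ([M-H]+13C, + 1.0033548 Da) species of an
organism-restricted compound library; compounds with logP(O/W) ≤ 0 are read
from the polar extract, logP > 0 from the nonpolar extract. Ambiguous
matches are kept and flagged, never auto-resolved.

**Differential analysis.** Intensities are quantile-normalized per organism,
technical replicates averaged into biological replicates, and each
metabolite/organism/stress level summarized by the log2 fold-change versus
the unstressed control with a pooled-variance two-sided t-test. FDR control
is by Storey–Tibshirani q-values (smoothing-spline π₀ estimate over
λ = 0, 0.05, …, 0.90); a record is differential when |log2 FC| ≥ 1 and
q < 0.05.

**Comparative analysis and screens.** Global responses are compared by PCA,
Cityblock (Manhattan) distance cladograms, Jukes–Cantor sequence distances
d = −(3/4) ln(1 − 4p/3), and a Mantel permutation test between the two
distance structures. Hits are found by (i) a four-way ANOVA
(main-effects-only, added-last sums of squares) of IC50-level fold-changes
on taxonomic group, habitat, cell-wall class and tolerance class, selecting
metabolites with factor p < 0.01 and a group-mean |log2 FC| > 1; and (ii) a
salt-tolerance correlation screen: per metabolite detected in more than 10
species, Pearson R of IC50-level fold-changes against organism IC50 and the
upper quartile x0.75 of |log2 FC|, with hits at |R| > 0.5 and x0.75 > 1.

## Worked example

Fit a dose-response curve from noisy relative growth rates:

```r
library(saltmet)
conc <- c(0, 50, 100, 200, 300, 450, 600, 800, 1000, 1300, 1700, 2500)
set.seed(1)
rates <- pmax(1 / (1 + (conc / 520)^2.3) + rnorm(length(conc), 0, 0.03), 0)
fit <- fit_dose_response(conc, rates)
fit
#> Sigmoidal dose-response fit: r(c) = top / (1 + (c/k)^h)
#>   top = 0.9985, k = 532.2 mM, h = 2.253 (RSS 0.00651)
#>   IC10 = 200.7  IC25 = 326.8  IC50 = 532.2 mM
```

The fitted k (= IC50) recovers the true 520 mM within the noise; `plot(fit)`
draws the curve with the IC markers.

Simulate a complete study (16 organisms, 4 stress levels, two extract
phases, full replicate structure, planted effects) and run the pipeline:

```r
study <- simulate_study(seed = 17)
study$ions$polar
#> ion_table: 3916 m/z features x 496 samples (16 organisms)
#>   m/z range 50.4632 - 999.9991 Da; 1.0% missing values

res <- run_salt_screens(study$ions$polar, study$ions$nonpolar,
                        study$lib, study$panel$meta)
res
#> salt-stress metabolomics screens
#> metabolite_table: 428 metabolite ion rows (201 compounds) x 496 samples
#>   differential records: 18339 (1682 called differential)
#>   ANOVA hit union: 15 metabolites
#> tolerance screen: 201 metabolites, 19 hits (9 anticorrelating, 10 correlating)

head(subset(as.data.frame(res$tolerance), hit,
            select = c(metabolite, n_detected, r, x075, direction)))
#>    metabolite n_detected      r x075       direction
#> 3         pyr         16  0.732 1.32     correlating
#> 4         ala         16  0.813 1.54     correlating
#> 7         ser         16  0.816 1.48     correlating
#> 17        thr         16 -0.821 1.49 anticorrelating
#> 22       ala5         16 -0.843 1.84 anticorrelating
#> 28        akg         16 -0.849 1.66 anticorrelating
```

Each tolerance-screen hit is a metabolite whose high-stress response grows
(correlating) or shrinks (anticorrelating) linearly with how much salt an
organism tolerates; `x075` is the upper quartile of its absolute log2
fold-changes across the panel. Comparing against the generator's ground
truth (`study$ions$truth`), 18 of the 20 planted tolerance-correlated
metabolites are recovered in this study, with no false positive among the
null metabolites.

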