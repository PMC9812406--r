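---
title: "Methods: guilt-by-association inference from dynamic metabolome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guilt-by-association inference from dynamic metabolome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboguilt)
library(data.table)
```

## The problem

Flow-injection mass spectrometry can profile the metabolome of hundreds of
deletion mutants cheaply: one intensity per annotated ion per sample, no
chromatography. When the library is additionally perturbed dynamically — here,
a time course after adding the TORC1 inhibitor rapamycin — mutants whose gene
products act in the same pathway leave similar fingerprints in how their
metabolomes depart from wild-type over time. `metaboguilt` implements the full
chain from raw ion-intensity tables to a ranked list of candidate pathway
members ("guilt by association"), plus the companion growth-kinetics readouts
used to phenotype candidate mutants after a nutritional upshift.

## The analysis model

**Normalization.** Samples are first screened for outliers in biomass (OD600)
and total ion current: a sample is dropped when either covariate deviates from
the cohort median by more than `k_mad` (default 3) median absolute deviations.
The rule is applied to convergence so that no retained sample violates it with
respect to the retained cohort — this makes the filter idempotent, which a
single literal pass is not. Intensities are then detrended per metabolite by
LOWESS on the natural-log scale, first against acquisition order (instrument
drift) and then against OD600 (biomass loading). The residual is re-centred so
each metabolite's mean log intensity is preserved exactly. The LOWESS span
defaults to 0.3 with 3 robustifying iterations: wide enough to track slow
drift over a ~1200-injection run without chasing replicate noise. Detrending
is per ion because drift in electrospray response need not be shared across
masses; this is the conservative choice where the upstream protocol is
ambiguous. `quantile_normalize()` (for proteome-style matrices) forces each
sample to the across-sample mean of order statistics, with average-rank
interpolation at ties.

**Profiles.** For mutant $m$, timepoint $t$ and metabolite $j$, the profile
entry is

$$\mathrm{fc}_{mjt} = \log_2 \bar{I}_{mjt} - \log_2 \bar{I}_{\mathrm{WT},jt},$$

the difference of log2 group means (mathematically the log2 ratio of means,
but computed as a difference so that swapping mutant and reference negates the
value bit-exactly). The per-metabolite p-value is a two-sided pooled-variance
Student t-test on natural-log intensities; log-scale testing stabilises the
variance of multiplicative ion-count noise. A change is "significant" when
$|\mathrm{fc}| > 0.5$ and $p < 0.05$; counts of significant changes are raw
(no multiple-testing correction), because the readout is a per-mutant summary
surface, not a discovery list — this is stated prominently wherever counts are
reported. A ratio-of-means versus mean-of-ratios flag is provided; the default
follows the convention of comparing average intensities.

**Similarity.** Within one timepoint, mutants' fold-change vectors are
correlated pairwise (Pearson, pairwise-complete over shared metabolites;
zero-variance profiles are excluded with a warning). Each mutant's
*correlation profile* is its row of that matrix; the dissimilarity between two
mutants is the Manhattan distance between their rows. By default the full rows
enter the sum, including the unit diagonal and the pair's mutual entries; an
`exclude_self` flag drops the pair's own two coordinates (the choice shifts
every distance by a small amount and does not change ranks much — both are
supported because the upstream convention is ambiguous). Trees are built by
Ward's method via Lance–Williams updates applied directly to these distances
(`ward.D` convention, input not squared). Ward's criterion is only proper on
squared Euclidean input; applying it to Manhattan distances is a deliberate
convention of this pipeline and is implemented exactly as stated rather than
"fixed". Ties at the minimal dissimilarity merge the lexicographically
smallest label pair, which makes merges invariant to leaf input order.

**Classifier.** The score of mutant $m$ is the median (default; mean
available) of its distances to the annotated positive regulators, with
annotated positives scored leave-one-out. Lower scores are more
positive-regulator-like. Cohesion of the positive set is tested by label
permutation: the observed statistic is the median pairwise distance within the
set; the null re-draws sets of the same size uniformly from all mutants,
B = 10,000 times; the empirical p-value uses the add-one rule
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1+B)$, so $p \ge 1/(B+1)$
always. Note the permutation p-value is invariant under monotone transforms of
the distances only when the number of positive pairs is odd (the median is
then a pure order statistic; with an even count it averages two order
statistics).

**Recovery and nomination.** Treating annotated positives as true positives
and all other mutants as negatives, a score threshold is swept over all
observed scores (predict positive when score $\le t$). AUC is computed by the
Mann–Whitney rank formulation with ties counted one half, which equals the
trapezoidal integral of the ROC curve (both are asserted against brute-force
pair enumeration in the tests). The nomination threshold is the largest
observed score with FPR $\le$ 0.2; each mutant's `ratio_to_threshold` is
score/threshold and `pass` requires ratio strictly below 1. Two caveats are
worth stating plainly: (i) at a 0.2 FPR target roughly 20% of non-positive
mutants pass *by construction*, signal or no signal — nomination controls the
false-positive *rate*, not the false discovery rate, even though screening
parlance often conflates the two; (ii) the mutant sitting exactly at the
threshold has ratio 1 and does not pass under the strict rule.

## The synthetic world

`generate_dataset()` emulates the structure of a rapamycin time-course screen
so every downstream stage is testable without any download. On the log2 scale,

$$\log_2 I = \log_2 b_j + f_j^{\mathrm{WT}}(t) + \delta_{mj}(t) + d(i) +
  s\,\log_2(\mathrm{OD}/\mathrm{OD}_{\mathrm{ref}}) + \varepsilon/\ln 2 .$$

Defaults and why:

* **Design**: 6 positive regulators, 6 negative regulators, 48 neutral
  strains plus wild-type; 4 biological replicates; timepoints 0/5/30/60/90
  min. Class sizes mirror the six annotated positive and six negative
  regulators of the motivating screen; 0/5/30/60/90 is the grid actually used
  in analysis (an upstream protocol note also lists 10 min — the config
  accepts any grid containing 0). 100 metabolites is desk-scale for an
  annotated FIA ion list.
* **Wild-type response** $f_j^{\mathrm{WT}}(t) = A_j (1 - e^{-t/\tau})$, with
  $\tau$ = 15 min and $|A_j| \sim U(0.5, 1.5)$ in log2 units: half the
  metabolites rise (amino-acid/nucleoside-like accumulation under TORC1
  inhibition), half fall. The exponential-approach shape and time constant
  are a modelling choice — responses largely develop within 15–30 min.
* **Planted classes**: positives share one signature vector
  ($s_j \sim N(0, 0.5)$ log2 units) plus an amplified wild-type response
  (factor 1.5); negatives carry the negated signature; neutrals carry
  independent $N(0, 0.2)$ effects. All deviations scale with
  $1 - e^{-t/\tau}$ and are therefore **zero before treatment**, which is
  what makes the untreated timepoint the least informative — the qualitative
  pattern the method is designed to exploit.
* **Nuisance structure**: replicate noise $\sigma = 0.2$ on the natural-log
  scale (~20% CV, typical for flow injection); a smooth drift (linear plus
  one slow sinusoid of the injection index) spanning 0.25 log2 units by
  default; a log-linear OD600 effect (slope 0.3 log2 per log2 OD), the
  simplest monotone biomass confounder.

What the generator does **not** emulate: mass spectra, ion annotation
ambiguity, missing values, batch structure across independent runs, or
correlated metabolite modules beyond the planted classes. A green end-to-end
test therefore establishes that the pipeline recovers planted structure under
realistic noise, drift and confounding — not that it reproduces any particular
laboratory dataset.

`generate_growth_curves()` emits lag-then-exponential kinetics with an
optional logistic ceiling (default OD 2.0) and multiplicative noise (default
2%). The ceiling exists because a pure lag-exponential has no interior slope
maximum: without saturation the windowed slope is constant over the whole
exponential phase and the position of its noisy maximum is arbitrary, making
"time to maximum slope" unidentifiable. `od_max = Inf` reproduces the exact
lag-exponential when needed.

## Growth readouts

Curves are smoothed by a centered 1-h moving average (windows shrink at the
edges), log-transformed, and the slope is estimated by least squares within
every 1-h window anchored at each grid point. The maximum windowed slope is
the growth rate. The lag time is the start time of the earliest window whose
slope reaches at least 90% of the maximum. The 90% attainment tolerance is a
numerical choice: at the stated noise level the windowed slope estimate has a
standard error near 2.7% of the rate, so demanding exact attainment (or 95%)
dates the lag at a noise-determined position, while 90% is several standard
errors above slope noise yet far below the depth of the lag-phase ramp, so
the crossing point is stable. Dating the lag at the window *onset* rather
than its midpoint removes the half-window bias at the lag-to-exponential
transition. Rates and lags are finally expressed relative to the
experiment-wide mean after averaging technical replicates
(`relative_to_reference()`, with a strain-referenced alternative).

## Numerical conventions, degenerate inputs

* Zero-variance groups in the t-test: p = 1 when the means agree, 0 when they
  differ; fewer than 2 replicates in either group gives NA.
* A constant detrending covariate is a warned no-op (the fit is undefined).
* MAD = 0 in the outlier rule flags any nonzero deviation.
* `k_mad = Inf` disables outlier filtering entirely.
* Quantile-normalization ties receive the mean of the tied reference values;
  missing cells are an error (impute or drop upstream).
* All distances/scores inherit determinism from seeds: the simulation takes
  its seed from the config, permutation tests take an explicit seed, and
  `run_pipeline()` derives per-timepoint permutation seeds from the master
  seed, so a repeated run is byte-identical.

## Known limitations

* Ward-on-Manhattan is mathematically improper (see above); dendrogram
  heights can in principle invert.
* The classifier assumes the annotated positive set is itself coherent; a
  heterogeneous positive set dilutes both the scores and the permutation
  test.
* FPR-based nomination does not control FDR (see above).
* The LOWESS spans, the drift form, and the response time constant are
  modelling defaults, not estimates; they are exposed in the configuration
  objects and should be revisited for instruments with different drift
  behaviour.
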