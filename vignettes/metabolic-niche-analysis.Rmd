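---
title: "Methods and design notes: metabolic niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: metabolic niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elentomics)
```

This vignette records the statistical models, parameter conventions, and
numerical decisions behind the package, in the spirit of a methods section a
maintainer can audit. The running scientific context is an anaerobic gut
bacterium of the *Eggerthella* type: no sugar fermentation, energy from the
arginine (and, in some conditions, agmatine) deiminase pathway, carbon
assimilation from acetate, and extensive strain-level variation in
metabolite output traceable to variable gene families.

## Feature QC and differential abundance

A `feature_table` couples a features x samples intensity matrix to feature
metadata (m/z in Da, retention time in minutes, ionization mode, adduct,
MSI annotation level 1–4) and sample metadata (role: sample / blank / pool /
control; group; time in hours; replicate; strain).

The QC chain and its defaults:

* **Presence over blanks** — a feature is present when its mean non-blank
  intensity strictly exceeds `blank_fold = 3` times its mean blank
  intensity. The comparison can be run per level of any sample column (e.g.
  per time point) via `by`; pooled evaluation is the default, and per-level
  evaluation marks a feature present if any level passes.
* **Replicate CV filter** — per replicate group, CV = sd/mean of raw
  intensities; a feature is removed when its **median** CV across groups
  exceeds `cv_max = 0.5`. The median (rather than pooling all replicates
  into one CV) is robust to a single noisy condition; groups of size 1 or
  with zero mean are skipped, and an error is raised only when no group of
  size >= 2 exists. Grouping defaults to the `group` column; `by = NULL`
  pools everything.
* **Outlier samples** — a non-blank sample is dropped when its total
  feature signal deviates from the assay median total by more than 50%
  (`dev_max = 0.5`); at least 3 non-blank samples are required and a zero
  median is an error.
* **Log transform** — log10 of intensity plus a per-feature pseudocount of
  `pseudocount_frac = 0.25` times the minimum nonzero intensity. The
  transform is skippable because some datasets (notably strain panels) are
  approximately normal untransformed. All-zero features are a named error.

**Welch testing.** `differential_abundance` computes Welch's *t* on log2
values (converted from the table's log base when already transformed;
pseudocounted log2 otherwise) — the *t* statistic is invariant to the log
base, and log2FC is defined as the difference of mean log2 pseudocounted
intensities, consistent with testing on the log scale. BH adjustment runs
across all tested features in one family; calls require `p_adj < 0.1`
**and** `|log2FC| > 0.5` (0.75 is the stricter heatmap-style setting).
Zero-variance groups with equal means get p = 1 (flagged `degenerate`)
rather than NaN so the BH family stays well defined; with unequal means the
*t* statistic is infinite and p = 0.

A caveat worth stating: at n = 3 per group the Satterthwaite approximation
makes Welch's test conservative — its true type-I rate at nominal 0.05 is
about 0.032 even on exactly normal data. The calibration checks in the test
suite use a band (0.03–0.07) that accommodates this known behavior.

**Trajectory comparison.** Each replicate time series is smoothed by
`stats::smooth.spline` with fixed `df = 5` (an error suggests lowering `df`
when a series has fewer unique time points); group mean curves are averaged
on a uniform 50-point grid, and the statistic is the mean absolute
difference between the two group curves — a functional-ANOVA-flavored
distance that is exactly δ for two flat curves offset by δ. Significance
comes from permuting whole replicate series between groups,
p = (#{permuted >= observed} + 1)/(n_perm + 1) with `n_perm = 1000` by
default, BH-adjusted, significant at `p_adj < 0.25`. Constant series bypass
the spline (their prediction is the constant), keeping degenerate features
well defined. **Design limit:** with only 3 series per group there are
C(6,3) = 20 distinct relabelings, so permutation p-values cannot fall below
~0.1 and adjusted significance at 0.25 is effectively unreachable; power
analyses in the tests therefore use 4 series per group (floor 2/70). With 0
permutations the p-value is undefined and the function errors.

**Cross-mode dereplication.** Neutral masses use a fixed adduct table
([M+H]+ −1.00728, [M−H]− +1.00728, [M+Na]+ −22.98922, [M+Cl]− −34.96940 Da
offsets); unknown adducts fall back to direct m/z comparison at the same
tolerance. Pairs merge under |Δmass| < 0.02 Da, |ΔRT| < 0.1 min, Pearson
r >= 0.7 across shared samples (>= 3 shared samples required). Candidate
pairs are resolved one-to-one greedily by smallest mass difference; the
lower (more confident) MSI level survives, ties keep the positive-mode
feature. Strain-variability labels follow the "changed in >= 1 but fewer
than `near_all` = 29 of 30 strains" rule.

## Cross-dataset linking

Fragment matching inside `spectral_cosine` is greedy closest-pair within
`frag_tol = 0.01` Da — standard spectral-similarity practice; the paperwork
of normalization uses the full-spectrum intensity norms so unmatched
fragments dilute the score, keeping it symmetric and in [0, 1]. The null
calibration draws two disjoint sets of 200 features with MS2, keeps
cross-set pairs differing by >= 1 min RT and >= 0.01 Da, and takes the
99.5th percentile of their cosines per ionization mode; fewer than 1000
eligible pairs is an error (`min_pairs` is exposed so small fixtures can
calibrate). Linking requires same mode, same adduct, |Δmz| <= 0.007 Da,
|ΔRT| <= 0.5 min and cosine at or above the mode cutoff; features without
MS2 instead use 0.001 Da / 0.2 min. Multi-candidate links — which the
original procedure leaves unspecified — are resolved one-to-one, best
cosine first, ties by smaller Δmz, preventing identity chains. The conflict
audit treats all annotation levels alike.

## Stable-isotope enrichment

The correction matrix for a compound with n carbons has column i equal to a
Binomial(n − i, p13) mass function shifted by i: the i tracer-labeled
carbons are fixed, the rest carry ¹³C at natural abundance
`p13 = 0.0107` (configurable; carbon-only correction, matching a ¹³C tracer
and common vendor practice — no N/H/O isotopes). `correct_mid` solves the
non-negative least-squares problem rather than inverting the matrix,
because at low signal direct inversion produces negative fractions; the
solution is renormalized to sum to 1, and a residual norm above 0.5 of the
normalized observation is reported as a degenerate fit. Enrichment is
1 − M+0 fraction, invariant to uniform area scaling. Labeling calls apply
the 3% enrichment floor and the preset area/fraction criteria
conjunctively, so the order of application does not change the outcome.

## Constraint-based modeling

The LP core is a two-phase dense tableau simplex with Bland's anti-cycling
rule, written for this package so that solver behavior is fully
deterministic: identical inputs give bitwise-identical solutions, pivot
tolerance 1e-9, infinite bounds clamped at ±1e6. It is appropriate for
curated networks of up to a few thousand reactions and is validated in the
tests against closed forms and an independent LP implementation.

Conventions: exchange reactions touch exactly one metabolite and encode
uptake as negative flux. `media_to_bounds` closes every exchange to uptake,
then opens listed compounds at U = C/(X·Δt) — concentration in mM divided
by biomass density (gDW/L) times exponential-phase duration (h), giving
mmol/gDW/h — and qualitative (trace, unquantified) compounds at 1
mmol/gDW/h, the natural dimensional reading of the conventional "1 mM/gDW/h"
phrasing. Secretion is never constrained by media. Biomass density and
duration are required configuration with no asserted defaults, since they
are experiment-specific; the cell dry weight 3.3e-13 g is recorded for
cell-count conversions.

Growth/no-growth is binarized at μ > 1e-6 h⁻¹; a reaction is "active" at
|v| > 1e-9 mmol/gDW/h. pFBA fixes the biomass flux at its optimum and
minimizes Σ|v| via flux splitting (v = p − n; reactions with a forced sign
get the exact one-sided encoding). FVA minimizes and maximizes each
reaction's flux at >= 99% of μ* by default. Knockouts are reaction-level
(both bounds zeroed), categorized essential (μ <= 1e-6), reduced, or
neutral, with a separate flag for reduction below 70% of wild type — the
criterion used when relating model essentiality to gene conservation.
Fisher exact tests are two-sided with the conditional-MLE odds ratio;
degenerate 2x2 tables report a boundary odds ratio with a note, and fully
tied Wilcoxon comparisons report p = 1. MCC is 0 by convention when a
marginal is empty. Gene–reaction pairs for expression concordance are
enumerated from GPR rules with repeats (a gene in several reactions counts
once per pairing).

Model I/O covers SBML Level 3 with the FBC package (species, flux-bound
parameters, nested gene-product associations, the active objective;
subsystems round-trip through notes) and a JSON dialect mirroring the
common exchange schema. GPR rules are parsed by a small recursive-descent
parser (`and`/`or`/parentheses).

## Strain associations

Patterns are distinct presence/absence columns over the strain panel;
constant patterns are untestable and dropped. Per (feature, pattern) the
test is Welch on per-strain values — replicate means of log10 intensities —
with all pairs adjusted in **one** BH family, significance at
`p_adj < 1e-4`. The separability filter implements: (a) |median difference|
>= 0.4 log10; (b) 10th percentile of with-gene strains >= max(control) +
0.4; (c) 90th percentile of without-gene strains **below that same bar**
(the "max(control) + margin" reading of the criterion, exposed as
configurable margins); percentiles use linear interpolation (`quantile`
type 7) so results are pinned across implementations. Only the lowest-p
association per feature survives. The written criteria assume the
production direction (with-gene strains higher); mirrored
depletion-direction criteria exist behind `mirror_depletion = FALSE` to
keep the default faithful to the stated rules. Pathway enrichment is the
one-sided hypergeometric test per annotation term with BH adjustment at
q < 0.1.

## Growth curves

Blank normalization subtracts the time-matched mean of blank wells and does
not clip negative values by default (background-subtracted noise is
legitimately negative; clipping is available). The logistic model
N(t) = K/(1 + ((K − N0)/N0)e^(−rt)) is fit by deterministic multi-start
nonlinear least squares: K starts at the maximum OD (and 1.2x it), N0 at
the first positive reading (and a tenth of it), r at the log-linear slope
of the sub-half-maximum phase plus a fixed grid (0.05, 0.2, 0.5, 1 h⁻¹);
the best residual sum of squares wins, so repeated fits agree exactly.
`sigma` is the residual standard error sqrt(RSS/(n − 3)), matching the
definition used by standard growth-curve packages, and fits with
sigma > 0.1 are flagged excluded. Flat or non-growing wells return a failed
fit with the r = 0 convention instead of erroring. AUC is the trapezoidal
integral (OD·h) — additive over partitions and invariant to collinear
insertions. Condition effects are two-sided exact Wilcoxon rank-sum tests
against a reference, BH-adjusted at 0.2; conditions with fewer than 3
replicates are skipped with a warning. Growth rates averaged across
replicates for reporting use the harmonic mean.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of configuration and seed and emit
machine-readable ground truth. Intensities are log-normal with
multiplicative replicate noise (defaults: baseline log10 mean 4, sd 0.5,
CV 10%, blanks at 100), matching the log-scale analysis conventions;
planted effects default to log2 = 3 (8-fold), the regime where a 3-vs-3
Welch design has essentially full power. Time-course mode shapes planted
effects with a logistic ramp. Cross-mode duplicates share neutral mass and
RT and correlate >= 0.9; linked datasets share identical MS2 spectra with
configurable m/z/RT jitter and decoys placed beyond all tolerances. The
strain panel plants gene-linked shifts of 1.0 log10 with clean separability
margins over a sterile-control background (30 strains, 3 replicates).
Isotopologue noise is multiplicative per channel (sd proportional to each
isotopologue's own expected area): that is the realistic LC-MS peak-area
noise model, and it is the reading under which low-signal channels do not
swamp the natural-abundance correction. Growth curves add Gaussian OD noise
(sd 0.01 by default) over a constant blank background.

The toy metabolic network fixes its coefficients so that one arginine
yields one ATP, activating one acetate costs one ATP, and biomass consumes
one acetyl precursor plus nine further ATP — hence
μ(A, C) = min(A/10, C), with both substrates binding at the default bounds
(A = 10, C = 1 mmol/gDW/h), reproducing the qualitative dose dependence of
growth on both substrates. The agmatine variant adds an independent
ATP-generating deiminase route, giving μ = min((A + G)/10, C), so growth
survives arginine removal when agmatine is supplied.

What passing on these data does **not** show: the generators contain no
chromatographic drift, batch effects, missing-value structure,
heteroscedastic ionization artifacts, or model-misspecification (real
growth is not exactly logistic; real replicate noise is not exactly
log-normal). Results on synthetic data certify the implementation, not the
robustness of the statistical choices to real-instrument pathologies.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to exercise
every property well within a single-CPU interactive session: 2,000 null
features for calibration, 500 features with 50 planted effects for power,
20 independent 30-strain panels for association recovery, 300 draws for
isotopologue specificity, 100 noisy curves for logistic recovery, a 5x5
uptake-bound grid for the toy network, and 500 shuffled gene–reaction pairs
for the expression-concordance null. The full suite runs in roughly a
minute; `scripts/acceptance.R` in a few seconds.

## Known limitations

* The simplex is dense; genome-scale models with tens of thousands of
  reactions would need a sparse solver behind the same interface.
* Gene-level knockouts (GPR evaluation) are out of scope; knockouts are
  reaction-level.
* Natural-abundance correction is carbon-only; an elemental-composition
  hook would be needed for N/H/O isotope corrections.
* The trajectory permutation test is limited by replicate count (see
  above); a model-based functional test would be needed for 3-replicate
  designs.
* Depletion-direction separability is off by default and mirrors the
  production criteria when enabled; it has no published reference values.
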