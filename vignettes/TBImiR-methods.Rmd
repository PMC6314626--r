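---
title: "Biofluid miRNA biomarkers of mild TBI: models and methods"
author: "TBImiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biofluid miRNA biomarkers of mild TBI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Contact-sport athletes experience repeated sub-concussive and concussive head
impacts whose dose can be quantified from fight video as hits to the head
(HTH). TBImiR implements a longitudinal biomarker-discovery analysis for such
cohorts: saliva and serum small-RNA sequencing before and after an exposure
event, computerized balance/cognitive testing, and a serum protein panel.
The working currency throughout is the **within-subject log2 change**: every
post-event measurement is expressed relative to the same subject's pre-event
baseline, which removes the large, stable inter-individual differences that
dominate biofluid miRNA levels.

The pipeline has eight analysis stages, each exposed as a documented
function and orchestrated by `runPipeline()`:

1. **Normalization** (`normalizeToReference()`): each miRNA count is
   expressed relative to an invariant reference miRNA (default
   hsa-miR-24-3p) on the log2 scale,
   `log2((count + c) / (count_ref + c))` with pseudocount `c = 1`.
2. **Baseline differencing** (`baselineDelta()`): post minus the same
   subject's baseline in the same fluid, preferring the day-of-event
   pre-sample over the 1-week-pre sample.
3. **Missingness filter** (`filterMissingness()`): features with more than
   60% missing delta values (per fluid) are eliminated.
4. **Cohort design** (`addCohortDesign()`): HTH likelihood classes Low
   (0--3), Moderate (4--9), VeryLikely (10+), and the four temporal bins
   (HTH-negative controls at the acute timepoint; HTH+ at ~1 h, 2--3 d and
   7 d).
5. **Screens** (`screenFeatures()`): feature-wise two-way fixed-effects
   models, class x fluid (the dose screen, BH FDR 0.15) and temporal bin x
   fluid (the time screen, raw p < 0.05).
6. **Panel classification** (`stepwiseSelect()`, `fitLogisticPanel()`,
   `mccvAuc()`): forward-AIC selection of up to 13 miRNAs predicting the
   HTH count, logistic classification of Low vs VeryLikely, and 100-fold
   Monte-Carlo cross-validated AUC.
7. **Temporal pattern calls** (`callPatterns()`): the explicit
   acute-saliva-response / delayed-serum-response rule (below).
8. **Associations, proteins, factors** (`correlateFeatures()`,
   `pairedProteinTest()`, `substituteBelowLod()`,
   `proteinVsHthRegression()`, `brainEnriched()`,
   `principalAxisFactor()`, `quartimaxRotate()`).

# Key models and rules

## Two-way screens on unbalanced data

Each feature's delta values are fit with a fixed-effects linear model
`delta ~ A * fluid` where `A` is the HTH class or the temporal bin. Because
the observational design is unbalanced, main effects are tested with
**Type-II sums of squares** (each main effect adjusted for the other main
effect), computed by residual-sum-of-squares comparisons of nested QR
decompositions. Features sharing a missingness pattern reuse the same
projections, which keeps 1000-feature screens around a second. A flag for
each feature records when its observed samples collapse a factor level, in
which case it is tested on the reduced design (one-way if a whole factor is
lost) rather than dropped.

The three p-value columns (factor, fluid, interaction) are BH-adjusted
separately across features. The dose screen calls significance at FDR
$\le$ 0.15; the time screen follows the convention of unadjusted p < 0.05
with q-values still reported.

**Statistical caveat.** Subjects contribute several post-event samples that
share one baseline, so delta columns are positively correlated within
subject while the class factor is constant within subject. Pooling them, as
this design does (a formal repeated-measures model is not fitted — the
changing subject sets per timepoint and learning effects preclude it),
makes the F tests anticonservative for between-subject factors. The
type-I-error calibration properties verified by the test suite therefore
use one post sample per subject; screens on the full longitudinal design
should be read as enrichment rankings, not calibrated hypothesis tests.

## The ASR/DSR temporal rule

A feature with a significant time effect is pattern-called from its per-bin
mean profiles (`binProfiles()`), with two printed thresholds: a change must
exceed 1.3-fold — operationalized as |log2| $\ge$ 0.28, taking the stated
log2 value as operative since $\log_2 1.3 \approx 0.379$ and
$2^{0.28} \approx 1.21$ disagree — and must exceed the HTH-negative control
group's magnitude at least two-fold.

* **ASR** (acute saliva response): saliva T1-HTH+ mean $\ge$ +0.28
  (increases only, matching the observed pattern class), at least twice the
  control magnitude, and back below 0.28 in magnitude by 2--3 days.
* **DSR** (delayed serum response): serum 7-day mean magnitude $\ge$ 0.28
  (either sign) and twice the control magnitude, with no acute serum change
  (|T1-HTH+| < 0.28) and a graded profile peaking at 1 week
  (|T3| $\ge$ |T2|).

The return-to-baseline, no-acute-change and graded conditions are narrative
criteria operationalized with the same 0.28 threshold; each is
independently toggleable. A control mean of exactly zero would satisfy the
ratio criterion trivially, which is why the absolute threshold is always
required as well. A feature satisfying both rules is called ASR (precedence
logged); raising the threshold can only shrink the call set.

## Panel selection and validation

Forward stepwise regression of the HTH count on screen-passing features
adds, at each step, the candidate minimizing AIC
($n \log(\mathrm{RSS}/n) + 2k$), stopping when AIC stops decreasing or at
13 features; ties break by feature label for determinism. Missing candidate
values are mean-substituted within fluid. Logistic classification of Low vs
VeryLikely (Moderate held out) reports *apparent* (resubstitution)
confusion matrices, labelled as such; a perfectly separating panel implies
divergent ML coefficients, so separation triggers a ridge penalty of 1e-4
(penalized IRLS) and is flagged. Out-of-sample performance comes from
100-fold Monte-Carlo cross-validation: stratified 75/25 splits, a
500-tree random forest (or the ridge-guarded logistic model), and ROC AUC
by threshold sweep with trapezoid integration, which equals the
Mann-Whitney statistic scaled by $n_1 n_0$.

## Protein panel and atlas rules

Pre/post concentrations are compared by two-sided paired t tests with the
median percent change; zero-variance differences are guarded (t = 0,
p = 1). A below-LOD pre-event value is replaced by **half the lowest
measurable post-event concentration** of that analyte; an analyte with no
measurable post value is declared unanalyzable. The change of each analyte
is regressed on HTH by OLS. A miRNA is *brain-enriched* when its median
expression across CNS atlas sources strictly exceeds every non-neural
source's median.

## Joint factor analysis

Pattern miRNAs and the 14 functional measures are reduced jointly by
**iterative principal-axis factoring**: the correlation matrix
(pairwise-complete, eigenvalue-clipped to positive semidefinite when
needed, flagged) has its diagonal replaced by communalities initialized at
squared multiple correlations; eigendecomposition of the reduced matrix
gives loadings, communalities update to row sums of squared loadings, and
the cycle repeats until the largest communality change is below 1e-4 (at
most 100 iterations; non-convergence returns a flagged solution, Heywood
communalities are clipped at 1). **Quartimax rotation** then maximizes the
sum of fourth powers of loadings by Kaiser's closed-form pairwise plane
rotations iterated to a criterion change below 1e-8; it preserves
communalities and the fitted correlation matrix. Three factors are
extracted by default, and variables are grouped per factor at |loading|
$\ge$ 0.4, partitioned by sign. Working on correlations (not covariances)
keeps loadings in [-1, 1] and puts miRNA log2 changes and functional
difference scores on one scale.

# The synthetic cohort generator

No raw data are deposited for studies of this design, so every stage is
validated against `simulateCohort()`, which plants known effects and
returns the generating truth. The generator's defaults are the study
conditions: ~50 subjects (60 in the acceptance checks, giving at least 10
samples per temporal bin), two fluids per visit, one or two pre-event
baselines and a random subset of the four post timepoints per subject, HTH
concentrated near zero / mid 4--9 / heavy 10+ tail (class means about
0.3, 6.5, 24), 12 acute-saliva and 13 delayed-serum features, 20 dose
features at 0.05 log2 per hit, acute/delayed amplitudes of 1.0 log2, and
NB overdispersion 0.2.

Counts are negative-binomial around per-feature lognormal baselines times
library size (1e5--5e5 reads) and a per-feature fluid offset. The total
overdispersion is split into a **persistent subject-level lognormal
component** (ICC 0.7) that cancels in within-subject deltas and a
**visit-level NB component** that does not — the standard longitudinal
variance decomposition, and the reason baseline differencing pays off.
Planted features draw their baselines from the reliably-quantified
abundance range, since temporal patterns are only observable where the
assay quantifies reliably; null features keep the full abundance spectrum,
including counts too low to call. The reference miRNA is generated with
technical (Poisson) noise only, which is what "invariant reference" means
operationally; 5% of count cells are reported as not detected to exercise
the missingness filter.

Acute/delayed effects apply only to subjects with at least 2 hits, scaled
by a latent per-subject severity shared with the sway-sensitive functional
measures (TLEC, DSB_Bal), so molecular and functional responses co-vary as
a real injury process would. ASR features spike +1.0 log2 in saliva at the
acute timepoint only, half of them with a delayed serum decrease; DSR
features ramp in serum to their full amplitude (random sign) at 7 days with
nothing acute. Functional scores add a learning trend (default 0.15 units
per session) on the learning-prone tasks, an acute cognitive dip, and unit
Gaussian noise; backward-digit-span tasks are missing at random (12%) to
exercise the KNN imputer. The protein panel plants one HTH-linear analyte
(UCHL1, 25 pg/mL per hit), HTH-independent post-event shifts (GFAP, MBP,
NSE2), one analyte mostly below LOD pre-event with measurable post values
(S100B), and one entirely below LOD (IL6, unanalyzable). A tissue atlas
plants brain-enriched features among the ASR set.

What the generator does **not** emulate: sequencing reads (counts are drawn
directly), compositional closure of the count fractions, dispersion-mean
trends beyond the single dispersion parameter, fluid-specific missingness
structure, repeat fighters, and any real miRNA identities. Passing tests
demonstrate that the machinery recovers what was planted under this model —
not that the published biological findings replicate.

# Numerical choices and problem sizes

* Pseudocount 1 (exposed); baseline priority day-of-event first (exposed).
* KNN imputation: k = 5, columns scaled by SD, distances on mutually
  observed columns normalized by their number, donors restricted to rows
  with the target observed, deterministic tie-break by row order.
* Stepwise: strict AIC decrease (1e-9 slack), early stop below 2 samples
  per parameter.
* Screens: features grouped by missingness pattern; rank-deficient
  contrasts return NA and are flagged; constant features get F = 0, p = 1.
* Factor analysis: SMC initialization clipped to [0.05, 0.995]; sign
  convention makes each factor's largest loading positive; factors
  reordered by explained variance after rotation.
* Test-suite problem sizes, chosen to exercise each property at
  desk scale: cohorts of 16--100 subjects and 50--1000 features;
  calibration over 50 seeds of 1000 null features; recovery checks at the
  60-subject study scale. `scripts/acceptance.R` re-runs the main
  computations in under a minute.

# Known limitations

* Pooled repeated samples make the screens anticonservative for
  between-subject factors (see the statistical caveat above); a
  mixed-model screen is deliberately out of scope.
* The temporal rule is a deterministic threshold rule; it inherits the
  printed thresholds and does not propagate bin-mean uncertainty.
* Apparent classification accuracies are optimistic by construction and
  always labelled; only the MCCV AUC estimates generalization.
* The Bonferroni family for HTH correlations is the feature x scope table
  computed in one call; other family definitions are defensible.
* `quartimax` here is principal-axis extraction followed by quartimax
  rotation; factor-score estimation and oblique rotations are not
  implemented.
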