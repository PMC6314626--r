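# TBImiR

Saliva and serum miRNA biomarker discovery for mild traumatic brain injury
(mTBI) in longitudinal contact-sport cohorts.

Concussion-spectrum head injury routinely escapes clinical detection, which
has driven interest in biofluid biomarkers tied to an objective injury dose —
here, video-counted **hits to the head (HTH)**. TBImiR is an R/Bioconductor-style
package for analysts working with such designs: repeated pre- and post-event
sampling of two biofluids, small-RNA sequencing counts, computerized
balance/cognitive measures, and a serum protein panel. Because raw data for
studies of this kind are typically not deposited, the package ships a
ground-truthed synthetic cohort generator so every stage of the pipeline is
validated against planted effects.

## What it computes

The analysis currency is the within-subject change
$\Delta_{fs} = \log_2\frac{x_{fs}+c}{x_{\mathrm{ref},s}+c} -
\log_2\frac{x_{fb}+c}{x_{\mathrm{ref},b}+c}$,
the reference-normalized log2 difference of post-event sample *s* from the
same subject's baseline *b*. On these deltas the package provides:

* **Dose screen** — per-feature two-way fixed-effects models,
  HTH class (Low 0–3 / Moderate 4–9 / VeryLikely 10+) x fluid, Type-II F
  tests, Benjamini–Hochberg FDR (0.15).
* **Time screen** — temporal bin x fluid (HTH-negative controls, ~1 h,
  2–3 d, 7 d post), raw p < 0.05.
* **Temporal pattern rule** — Acute Saliva Response (ASR) and Delayed Serum
  Response (DSR) calls: a qualifying change must exceed |log2| ≥ 0.28 and
  twice the control-group magnitude, with return-to-baseline (ASR) or
  no-acute-change plus a graded 1-week peak (DSR).
* **Panel classifier** — forward-AIC stepwise selection (≤ 13 miRNAs)
  against HTH, logistic Low-vs-VeryLikely classification with
  separation-safe ridge fallback, and 100-fold Monte-Carlo cross-validated
  ROC AUC (random forest or logistic learner).
* **Associations and proteins** — Pearson correlations with HTH
  (Bonferroni) and functional measures (unadjusted), paired pre/post
  protein tests, half-minimum below-LOD substitution, protein-vs-HTH
  regression, tissue-atlas brain-enrichment calls.
* **Joint factor analysis** — iterative principal-axis factoring with
  quartimax rotation over pattern miRNAs plus functional measures, and
  |loading| ≥ 0.4 variable grouping.

## Worked example

```r
library(TBImiR)
library(SummarizedExperiment)

coh <- simulateCohort(simConfig(nSubjects = 60, seed = 1))
coh
#> MirCohort: 300 miRNAs x 448 samples
#>   fluids:         saliva (224), serum (224)
#>   subjects:       60
#>   planted:        dose=20, asr=12, dsr=13
#>   functional:     156 assessments x 14 measures
#>   protein panel:  11 analytes, 24 subjects

norm  <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
delta <- addCohortDesign(filterMissingness(baselineDelta(norm)))

screen <- screenFeatures(delta, "temporal_bin")
sum(screen$significant)
#> 52
calls <- callPatterns(binProfiles(delta), screen$feature[screen$significant])
table(calls$label)
#>  ASR  DSR none
#>   12   14   26

hth   <- screenFeatures(delta, "tbi_class", alphaFdr = 0.15)
panel <- stepwiseSelect(delta, maxFeatures = 13,
                        candidates = hth$feature[hth$significant])
length(panel$selected); round(panel$r_squared, 2)
#> 13
#> 0.95
mccvAuc(delta, panel$selected, nIter = 100, seed = 1)$mean_auc
#> 0.999
```

Reading the output: the time screen flags 52 of 300 miRNAs; the pattern
rule then recovers all 12 planted acute-saliva and all 13 delayed-serum
features (the 14th DSR call is one false positive among 255 true-null
features, i.e. an FPR of 0.4%). The dose screen feeds a 13-miRNA panel
that predicts the planted HTH dose (R² = 0.95) and separates the extreme
HTH classes with a cross-validated AUC near 1 at these planted amplitudes.
`runPipeline(pipelineConfig(...))` chains all stages, writes each stage's
table, and returns a checksummed, seed-reproducible run report.

## Package layout

* `R/` — S4 classes (`SimConfig`, `MirCohort`, `DeltaExperiment`,
  `FactorSolution`) and the stage functions.
* `tests/testthat/` — unit, property and acceptance tests (oracle-checked
  against hand arithmetic, brute-force searches, `car::Anova`, rank
  statistics, and grid searches).
* `vignettes/TBImiR-methods.Rmd` — the models, rules, generator design,
  numerical choices, and known limitations.
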