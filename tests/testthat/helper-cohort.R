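library(SummarizedExperiment)

## shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulateCohort(
      simConfig(nSubjects = 16, pMirnas = 50, seed = 42))
  .fixtures$small
}

## the small cohort taken through normalize -> delta -> filter -> design
smallDelta <- function() {
  if (is.null(.fixtures$smallDelta)) {
    coh <- smallCohort()
    norm <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
    .fixtures$smallDelta <-
      addCohortDesign(filterMissingness(suppressWarnings(baselineDelta(norm))))
  }
  .fixtures$smallDelta
}

## the acceptance-scale cohort (study conditions: amplitudes 1.0,
## >= 10 samples per temporal bin)
studyCohort <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulateCohort(simConfig(nSubjects = 60, seed = 7))
  .fixtures$study
}

studyDelta <- function() {
  if (is.null(.fixtures$studyDelta)) {
    coh <- studyCohort()
    norm <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
    .fixtures$studyDelta <-
      addCohortDesign(filterMissingness(suppressWarnings(baselineDelta(norm))))
  }
  .fixtures$studyDelta
}

## larger cohort for dose-recovery properties (n >= 100 subjects)
doseDelta <- function() {
  if (is.null(.fixtures$doseDelta)) {
    coh <- simulateCohort(simConfig(nSubjects = 100, pMirnas = 60,
                                    dropoutFraction = 0, seed = 5))
    norm <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
    .fixtures$doseCohort <- coh
    .fixtures$doseDelta <-
      addCohortDesign(filterMissingness(suppressWarnings(baselineDelta(norm))))
  }
  .fixtures$doseDelta
}

doseCohort <- function() {
  doseDelta()
  .fixtures$doseCohort
}

## tiny deterministic count matrix + metadata for hand-checkable cases
toyCounts <- function() {
  cnt <- rbind(
    ref = c(100L, 7L, 50L, 64L),
    a   = c(100L, 0L, 25L, 128L),
    b   = c(400L, 14L, 100L, 32L))
  colnames(cnt) <- c("s1", "s2", "s3", "s4")
  cnt
}

toyMeta <- function() {
  S4Vectors::DataFrame(
    sample_id = c("s1", "s2", "s3", "s4"),
    subject_id = c("A", "A", "A", "B"),
    fluid = c("saliva", "saliva", "saliva", "serum"),
    timepoint = c("pre_0d", "pre_1wk", "post_0d", "post_0d"),
    hth = c(5L, 5L, 5L, 0L),
    fought = c(TRUE, TRUE, TRUE, FALSE),
    row.names = c("s1", "s2", "s3", "s4"))
}

## delta experiment built directly from a given matrix + design columns
deltaFromMatrix <- function(mat, fluid, timepoint, hth,
                            fought = hth > 0,
                            subject = paste0("S", seq_len(ncol(mat)))) {
  cd <- S4Vectors::DataFrame(
    subject_id = subject, fluid = fluid, timepoint = timepoint,
    hth = as.integer(hth), fought = fought,
    sample_id = colnames(mat),
    baseline_sample = paste0(subject, "_base"),
    row.names = colnames(mat))
  addCohortDesign(new("DeltaExperiment",
      SummarizedExperiment(assays = list(delta = mat), colData = cd)))
}
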