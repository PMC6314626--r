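#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.TIMEPOINTS <- c("pre_1wk", "pre_0d", "post_0d", "post_2_3d", "post_1wk",
                 "post_3wk")
.PRE_TIMEPOINTS  <- c("pre_1wk", "pre_0d")
.POST_TIMEPOINTS <- c("post_0d", "post_2_3d", "post_1wk", "post_3wk")
.FLUIDS <- c("saliva", "serum")
.TBI_CLASSES <- c("Low", "Moderate", "VeryLikely")
.TEMPORAL_BINS <- c("T1_HTHneg", "T1_HTHpos", "T2_HTHpos", "T3_HTHpos",
                    "unassigned")

#' Functional outcome measure codes
#'
#' The 14 balance and cognitive measures of the computerized assessment
#' battery: body sway during eight stances (floor and foam pad, eyes open or
#' closed), sway while holding a tablet, sway during two dual tasks, and
#' three task completion times.
#'
#' @format Character vector of 14 measure codes.
#' @export
FUNCTIONAL_MEASURES <- c(
  "TLEO", "TLEC", "TSEO", "TSEC",
  "TLEOFP", "TLECFP", "TSEOFP", "TSECFP",
  "HT", "TMB_Dual_Bal", "DSB_Bal",
  "TMA_Cog", "TMB_Cog", "DSB_Cog")

#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated contact-sport cohort: subjects with video-counted
#' hits to the head (HTH), longitudinal saliva and serum miRNA sequencing,
#' functional (balance/cognitive) difference scores, a serum protein panel,
#' and a tissue expression atlas. Planted effect archetypes (HTH-dose,
#' acute-saliva, delayed-serum, null) give every downstream stage a ground
#' truth.
#'
#' @slot nSubjects number of subjects.
#' @slot pMirnas number of miRNA features (including the reference).
#' @slot referenceId label of the invariant reference miRNA.
#' @slot controlFraction fraction of subjects who attend the event but do
#'   not fight (hth = 0, fought = FALSE).
#' @slot hthClassProbs mixing probabilities over the Low / Moderate /
#'   VeryLikely HTH classes for subjects who fight.
#' @slot nDose,nAsr,nDsr numbers of planted dose-responsive, acute-saliva
#'   and delayed-serum features; the remainder (minus the reference) is null.
#' @slot doseSlope log2 units of post-fight change per hit to the head for
#'   dose features.
#' @slot asrAmplitude,dsrAmplitude planted log2 amplitudes of the acute
#'   saliva spike and the delayed serum ramp.
#' @slot dispersion total negative-binomial overdispersion of counts across
#'   subjects (var = mu + dispersion * mu^2).
#' @slot subjectIcc fraction of the overdispersion attributable to a
#'   persistent subject-level component (cancels in within-subject deltas).
#' @slot librarySizeRange range (reads) from which per-sample library sizes
#'   are drawn uniformly.
#' @slot learningRate per-session improvement (score units) in the
#'   learning-prone functional tasks.
#' @slot noiseSdFunctional residual noise SD of functional difference scores.
#' @slot dropoutFraction fraction of count cells reported as not detected
#'   (NA), emulating missingness in low-input biofluid sequencing.
#' @slot postProbs per-subject probability of contributing each post-fight
#'   timepoint (post_0d, post_2_3d, post_1wk, post_3wk).
#' @slot eventEffect nonspecific log2 change at the day-of-event timepoint
#'   applied to all attendees (control contamination; 0 disables).
#' @slot seed master seed; fully determines the generated cohort.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer",
  pMirnas = "integer",
  referenceId = "character",
  controlFraction = "numeric",
  hthClassProbs = "numeric",
  nDose = "integer",
  nAsr = "integer",
  nDsr = "integer",
  doseSlope = "numeric",
  asrAmplitude = "numeric",
  dsrAmplitude = "numeric",
  dispersion = "numeric",
  subjectIcc = "numeric",
  librarySizeRange = "numeric",
  learningRate = "numeric",
  noiseSdFunctional = "numeric",
  dropoutFraction = "numeric",
  postProbs = "numeric",
  eventEffect = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  ints <- c(nSubjects = object@nSubjects, pMirnas = object@pMirnas,
            nDose = object@nDose, nAsr = object@nAsr, nDsr = object@nDsr)
  if (any(is.na(ints)) || any(ints < 0L))
    msg <- c(msg, "counts must be nonnegative integers")
  if (object@nSubjects < 1L || object@pMirnas < 2L)
    msg <- c(msg, "need >= 1 subject and >= 2 features")
  if (object@nDose + object@nAsr + object@nDsr + 1L > object@pMirnas)
    msg <- c(msg, "planted features plus reference exceed pMirnas")
  if (length(object@referenceId) != 1L || is.na(object@referenceId) ||
      !nzchar(object@referenceId))
    msg <- c(msg, "referenceId must be a single non-empty label")
  amps <- c(object@doseSlope, object@asrAmplitude, object@dsrAmplitude,
            object@eventEffect)
  if (any(!is.finite(amps)))
    msg <- c(msg, "all planted amplitudes must be finite")
  if (object@dispersion < 0 || object@subjectIcc < 0 || object@subjectIcc > 1)
    msg <- c(msg, "dispersion must be >= 0 and subjectIcc in [0, 1]")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "librarySizeRange must be an increasing positive pair")
  if (object@controlFraction < 0 || object@controlFraction >= 1)
    msg <- c(msg, "controlFraction must be in [0, 1)")
  if (length(object@hthClassProbs) != 3L || any(object@hthClassProbs < 0) ||
      sum(object@hthClassProbs) <= 0)
    msg <- c(msg, "hthClassProbs must be 3 nonnegative weights")
  if (length(object@postProbs) != 4L || any(object@postProbs < 0) ||
      any(object@postProbs > 1))
    msg <- c(msg, "postProbs must be 4 probabilities")
  if (object@dropoutFraction < 0 || object@dropoutFraction >= 1)
    msg <- c(msg, "dropoutFraction must be in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Simulated biofluid miRNA cohort with ground truth
#'
#' Container returned by [simulateCohort()]: raw count matrices for both
#' biofluids (one [SummarizedExperiment::SummarizedExperiment] whose column
#' data carry subject, fluid, timepoint, HTH and fight participation),
#' functional difference scores, the serum protein panel, a tissue
#' expression atlas, and the generating ground truth.
#'
#' @slot counts SummarizedExperiment of raw counts (assay \code{"counts"}),
#'   features x samples, both fluids as columns.
#' @slot functionalScores data.frame of subject/timepoint rows by the 14
#'   functional measure columns (standardized post-minus-pre differences,
#'   NAs allowed).
#' @slot proteins data.frame of the protein panel in long format (subject,
#'   analyte, pre, post, LOD, below-LOD flags, hth).
#' @slot tissueAtlas matrix of median expression, features x sources.
#' @slot cnsSources character vector naming which atlas columns are CNS.
#' @slot groundTruth list with elements \code{archetype} (named character:
#'   dose / asr / dsr / null / reference), \code{effectSize} (named numeric,
#'   signed planted amplitude or slope), \code{hth} (named by subject),
#'   \code{brainEnriched} (character), and the config used.
#' @export
setClass("MirCohort", representation(
  counts = "SummarizedExperiment",
  functionalScores = "data.frame",
  proteins = "data.frame",
  tissueAtlas = "matrix",
  cnsSources = "character",
  groundTruth = "list"))

setValidity("MirCohort", function(object) {
  msg <- character()
  cd <- colData(object@counts)
  need <- c("subject_id", "fluid", "timepoint", "hth", "fought")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (any(cd$hth[!cd$fought] != 0L))
      msg <- c(msg, "hth must be 0 whenever fought is FALSE")
    if (!all(cd$fluid %in% .FLUIDS))
      msg <- c(msg, "fluid must be saliva or serum")
    if (!all(cd$timepoint %in% .TIMEPOINTS))
      msg <- c(msg, "unknown timepoint label")
  }
  cnt <- assay(object@counts, "counts")
  if (any(cnt[!is.na(cnt)] < 0) ||
      any(cnt[!is.na(cnt)] != round(cnt[!is.na(cnt)])))
    msg <- c(msg, "counts must be nonnegative integers (NA = not detected)")
  arch <- object@groundTruth$archetype
  if (!is.null(arch)) {
    if (!setequal(names(arch), rownames(object@counts)))
      msg <- c(msg, "every feature must have exactly one archetype")
    ref <- names(arch)[arch == "reference"]
    if (length(ref) != 1L)
      msg <- c(msg, "exactly one reference feature required")
    else if (!isTRUE(object@groundTruth$effectSize[[ref]] == 0))
      msg <- c(msg, "reference feature must have zero planted effect")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject baseline-differenced expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' \code{"delta"} holds, for each post-fight sample, the reference-normalized
#' log2 value minus the same subject's pre-fight baseline value (a log2 fold
#' change). Column data record the originating sample metadata plus the
#' baseline sample each column traces to; cohort design columns
#' (\code{tbi_class}, \code{temporal_bin}) are added by [addCohortDesign()].
#'
#' @export
setClass("DeltaExperiment", contains = "SummarizedExperiment")

setValidity("DeltaExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("subject_id", "fluid", "timepoint", "hth", "fought",
            "baseline_sample")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (!all(cd$timepoint %in% .POST_TIMEPOINTS))
      msg <- c(msg, "only post timepoints may appear in a DeltaExperiment")
    if (any(is.na(cd$baseline_sample)))
      msg <- c(msg, "every column must trace to a baseline sample")
  }
  if (!"delta" %in% names(assays(object)))
    msg <- c(msg, "assay 'delta' is required")
  if (length(msg)) msg else TRUE
})

#' Common-factor solution
#'
#' Result of iterative principal-axis factoring ([principalAxisFactor()]),
#' optionally rotated by [quartimaxRotate()].
#'
#' @slot loadings variables x factors loading matrix.
#' @slot communalities named numeric, one per variable, in [0, 1].
#' @slot varianceExplained sum of squared loadings per factor.
#' @slot rotation rotation applied ("none" or "quartimax").
#' @slot iterations communality iterations used.
#' @slot converged logical; FALSE carries a non-convergence warning flag.
#' @slot heywood variables whose communality was clipped at 1.
#' @export
setClass("FactorSolution", representation(
  loadings = "matrix",
  communalities = "numeric",
  varianceExplained = "numeric",
  rotation = "character",
  iterations = "integer",
  converged = "logical",
  heywood = "character"))

setValidity("FactorSolution", function(object) {
  msg <- character()
  if (ncol(object@loadings) != length(object@varianceExplained))
    msg <- c(msg, "one varianceExplained entry per factor required")
  if (nrow(object@loadings) != length(object@communalities))
    msg <- c(msg, "one communality per variable required")
  h2 <- object@communalities
  if (any(h2 < -1e-8 | h2 > 1 + 1e-8))
    msg <- c(msg, "communalities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
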