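#' TBI likelihood class from hits to the head
#'
#' Bins video-counted hits to the head (HTH) into the three mTBI-likelihood
#' classes used for screening and classification: Low (0-3 HTH), Moderate
#' (4-9 HTH) and VeryLikely (10+ HTH). The assignment is a total, piecewise
#' constant, monotone function of HTH.
#'
#' @param hth vector of nonnegative integer hit counts.
#' @return factor with levels \code{Low, Moderate, VeryLikely}.
#' @examples
#' assignTbiClass(c(0, 3, 4, 9, 10, 65))
#' @export
assignTbiClass <- function(hth) {
  stopifnot(all(!is.na(hth)), all(hth >= 0))
  cut(hth, breaks = c(-Inf, 3, 9, Inf), labels = .TBI_CLASSES)
}

#' Temporal bin for the acute/delayed analysis
#'
#' Maps each post-fight delta sample to the four-bin temporal design:
#' samples collected within ~1 hour post-event from subjects who either did
#' not fight or fought without meaningful head impact (fewer than 2 hits)
#' are the HTH-negative controls (\code{T1_HTHneg}); samples from fighters
#' with at least 2 hits are binned by collection time into \code{T1_HTHpos}
#' (<= 1 h), \code{T2_HTHpos} (2-3 days) and \code{T3_HTHpos} (7 days).
#' Anything else (e.g. the 3+ week timepoint, or control samples at later
#' timepoints) is \code{unassigned}.
#'
#' @param meta data.frame/DataFrame of post-fight delta sample metadata with
#'   columns \code{timepoint, hth, fought}.
#' @return factor with levels
#'   \code{T1_HTHneg, T1_HTHpos, T2_HTHpos, T3_HTHpos, unassigned}.
#' @export
assignTemporalBin <- function(meta) {
  meta <- as.data.frame(meta)
  if (any(meta$timepoint %in% .PRE_TIMEPOINTS))
    stop("contract violation: pre-fight record passed to assignTemporalBin",
         call. = FALSE)
  hthPos <- meta$fought & meta$hth >= 2L
  control <- !meta$fought | meta$hth == 0L   # hth = 1 fits neither definition
  bin <- rep("unassigned", nrow(meta))
  bin[control & meta$timepoint == "post_0d"] <- "T1_HTHneg"
  bin[hthPos & meta$timepoint == "post_0d"] <- "T1_HTHpos"
  bin[hthPos & meta$timepoint == "post_2_3d"] <- "T2_HTHpos"
  bin[hthPos & meta$timepoint == "post_1wk"] <- "T3_HTHpos"
  factor(bin, levels = .TEMPORAL_BINS)
}

#' Attach cohort design columns to a DeltaExperiment
#'
#' Adds \code{tbi_class} ([assignTbiClass()]) and \code{temporal_bin}
#' ([assignTemporalBin()]) to the column data.
#'
#' @param delta a [DeltaExperiment-class].
#' @return the annotated object.
#' @export
addCohortDesign <- function(delta) {
  cd <- colData(delta)
  cd$tbi_class <- assignTbiClass(cd$hth)
  cd$temporal_bin <- assignTemporalBin(cd)
  colData(delta) <- cd
  delta
}

#' @importFrom SummarizedExperiment colData colData<-
NULL
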