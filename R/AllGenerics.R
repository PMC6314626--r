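#' @rdname MirCohort-class
#' @param object,x a \code{MirCohort}.
#' @export
setGeneric("mirCounts", function(x) standardGeneric("mirCounts"))

#' @rdname MirCohort-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname MirCohort-class
#' @export
setGeneric("functionalScores", function(x) standardGeneric("functionalScores"))

#' @rdname MirCohort-class
#' @export
setGeneric("proteinTable", function(x) standardGeneric("proteinTable"))

#' @rdname MirCohort-class
#' @export
setGeneric("tissueAtlas", function(x) standardGeneric("tissueAtlas"))

#' @rdname MirCohort-class
#' @export
setGeneric("cnsSources", function(x) standardGeneric("cnsSources"))

#' @rdname MirCohort-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Accessors for MirCohort components
#'
#' @name MirCohort-accessors
#' @aliases mirCounts sampleMeta functionalScores proteinTable tissueAtlas
#'   cnsSources groundTruth
NULL

#' @rdname MirCohort-class
setMethod("mirCounts", "MirCohort", function(x) x@counts)

#' @rdname MirCohort-class
setMethod("sampleMeta", "MirCohort",
          function(x) colData(x@counts))

#' @rdname MirCohort-class
setMethod("functionalScores", "MirCohort", function(x) x@functionalScores)

#' @rdname MirCohort-class
setMethod("proteinTable", "MirCohort", function(x) x@proteins)

#' @rdname MirCohort-class
setMethod("tissueAtlas", "MirCohort", function(x) x@tissueAtlas)

#' @rdname MirCohort-class
setMethod("cnsSources", "MirCohort", function(x) x@cnsSources)

#' @rdname MirCohort-class
setMethod("groundTruth", "MirCohort", function(x) x@groundTruth)

#' @rdname MirCohort-class
setMethod("show", "MirCohort", function(object) {
  cd <- colData(object@counts)
  arch <- object@groundTruth$archetype
  cat("MirCohort:", nrow(object@counts), "miRNAs x", ncol(object@counts),
      "samples\n")
  cat("  fluids:        ",
      paste(sprintf("%s (%d)", .FLUIDS, tabulate(factor(cd$fluid, .FLUIDS),
                                                 2L)), collapse = ", "), "\n")
  cat("  subjects:      ", length(unique(cd$subject_id)), "\n")
  if (!is.null(arch))
    cat("  planted:       ",
        paste(sprintf("%s=%d", c("dose", "asr", "dsr"),
                      c(sum(arch == "dose"), sum(arch == "asr"),
                        sum(arch == "dsr"))), collapse = ", "), "\n")
  cat("  functional:    ", nrow(object@functionalScores), "assessments x",
      ncol(object@functionalScores) - 2L, "measures\n")
  cat("  protein panel: ", length(unique(object@proteins$analyte)),
      "analytes,", length(unique(object@proteins$subject_id)), "subjects\n")
})

#' @rdname FactorSolution-class
#' @param object a \code{FactorSolution}.
setMethod("show", "FactorSolution", function(object) {
  cat("FactorSolution:", nrow(object@loadings), "variables,",
      ncol(object@loadings), "factors (rotation:", object@rotation, ")\n")
  cat("  variance explained:",
      paste(sprintf("%.3f", object@varianceExplained), collapse = ", "), "\n")
  cat("  iterations:", object@iterations,
      if (!object@converged) "(NOT converged)" else "", "\n")
  if (length(object@heywood))
    cat("  Heywood-clipped:", paste(object@heywood, collapse = ", "), "\n")
})

#' @rdname FactorSolution-class
#' @param x a \code{FactorSolution}.
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))

#' @rdname FactorSolution-class
setMethod("factorLoadings", "FactorSolution", function(x) x@loadings)

#' @rdname FactorSolution-class
#' @export
setGeneric("communalities", function(x) standardGeneric("communalities"))

#' @rdname FactorSolution-class
setMethod("communalities", "FactorSolution", function(x) x@communalities)
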