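#' Default pipeline configuration
#'
#' Returns the full configuration of [runPipeline()] as a named list whose
#' defaults are the published analysis settings: reference-miRNA
#' normalization with pseudocount 1 and baseline priority (day-of-fight pre,
#' then 1-week pre), the 60% missingness filter, HTH classes 0-3 / 4-9 /
#' 10+, FDR 0.15 for the miRNA dose screen and 0.05 for the functional
#' screen, raw p < 0.05 for the time screen, a 13-feature stepwise panel,
#' 100 Monte-Carlo cross-validation iterations with 75/25 stratified splits,
#' the 0.28 log2 / 2x-control temporal pattern rule, Bonferroni for HTH
#' correlations, and 3 quartimax-rotated principal-axis factors. The
#' configuration round-trips losslessly through YAML
#' ([readPipelineConfig()]).
#'
#' @param ... name = value overrides of any default.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,
    sim = list(),                 # overrides passed to simConfig()
    input_dir = NULL,             # used when simulate = FALSE
    out_dir = NULL,               # default: fresh temporary directory
    stages = c("normalize", "design", "screen_hth", "classify",
               "screen_time", "patterns", "associations", "proteins",
               "factor"),
    reference_id = "hsa-miR-24-3p",
    pseudocount = 1,
    baseline_priority = c("pre_0d", "pre_1wk"),
    max_missing_fraction = 0.60,
    knn_k = 5L,
    fdr_hth = 0.15,
    fdr_functional = 0.05,
    alpha_time = 0.05,
    max_panel_features = 13L,
    mccv_iterations = 100L,
    mccv_test_fraction = 0.25,
    mccv_learner = "random_forest",
    min_log2 = 0.28,
    control_ratio = 2,
    loading_threshold = 0.4,
    n_factors = 3L)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("configuration error: unknown option(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  }
  for (nm in c("seed", "knn_k", "max_panel_features", "mccv_iterations",
               "n_factors"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file of overrides.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.writeStage <- function(obj, file) {
  utils::write.table(obj, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (or load) -> normalize -> baseline delta ->
#' missingness filter -> cohort design -> dose screen -> panel
#' classification -> time screen -> temporal pattern calls -> correlations
#' and functional screen -> protein statistics -> joint factor analysis, in
#' dependency order, writing each stage's table to \code{out_dir} and
#' returning a machine-readable run report (also written as
#' \code{report.yaml}). A stage failure aborts with the failing stage named;
#' partial outputs are retained. Every number in the report is re-derivable
#' from the written stage outputs, and two runs with the same seed produce
#' identical reports (checksums included).
#'
#' @param config a configuration list from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return list: \code{parameters} (effective config), \code{counts} (stage
#'   tallies), \code{results} (headline numbers), \code{checksums} (md5 per
#'   written file), \code{out_dir}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stage <- "configure"
  report <- list(parameters = config, counts = list(), results = list())
  outDir <- config$out_dir
  if (is.null(outDir)) outDir <- tempfile("tbimir_run_")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- character()
  on.exit(if (stage != "done")
    message("pipeline aborted at stage '", stage,
            "'; partial outputs in ", outDir))
  need <- function(dep, who) {
    if (!dep %in% config$stages)
      stop("dependency error: stage '", who, "' requires '", dep, "'",
           call. = FALSE)
  }

  stage <- "simulate"
  if (isTRUE(config$simulate)) {
    simArgs <- utils::modifyList(list(seed = config$seed), config$sim)
    cohort <- simulateCohort(do.call(simConfig, simArgs))
    counts <- mirCounts(cohort)
  } else {
    ind <- config$input_dir
    if (is.null(ind)) stop("input_dir required when simulate = FALSE",
                           call. = FALSE)
    cs <- lapply(.FLUIDS, function(fl)
      readCounts(file.path(ind, paste0("counts.", fl, ".tsv"))))
    cnt <- do.call(cbind, cs)
    meta <- readSampleMeta(file.path(ind, "samples.tsv"))
    counts <- SummarizedExperiment(assays = list(counts =
                                                   cnt[, rownames(meta)]),
                                   colData = meta)
    cohort <- NULL
  }
  set.seed(config$seed)
  report$counts$n_samples <- ncol(counts)
  report$counts$n_features <- nrow(counts)

  stage <- "normalize"
  delta <- NULL
  if ("normalize" %in% config$stages) {
    norm <- normalizeToReference(counts, config$reference_id,
                                 config$pseudocount)
    delta <- suppressWarnings(
      baselineDelta(norm, baselinePriority = config$baseline_priority))
    delta <- filterMissingness(delta, config$max_missing_fraction)
    report$counts$n_delta_columns <- ncol(delta)
    report$counts$n_features_kept <- nrow(delta)
    dOut <- data.frame(feature = rownames(delta),
                       assay(delta, "delta"), check.names = FALSE)
    files <- c(files, .writeStage(dOut, file.path(outDir, "delta.tsv")))
  }

  stage <- "design"
  if ("design" %in% config$stages) {
    need("normalize", "design")
    delta <- addCohortDesign(delta)
    files <- c(files, .writeStage(as.data.frame(colData(delta)),
                                  file.path(outDir, "design.tsv")))
  }

  stage <- "screen_hth"
  screenHth <- NULL
  if ("screen_hth" %in% config$stages) {
    need("design", "screen_hth")
    screenHth <- screenFeatures(delta, "tbi_class",
                                alphaFdr = config$fdr_hth)
    report$counts$n_hth_significant <- sum(screenHth$significant)
    files <- c(files, .writeStage(as.data.frame(screenHth),
                                  file.path(outDir, "screen_hth.tsv")))
  }

  stage <- "classify"
  if ("classify" %in% config$stages) {
    need("screen_hth", "classify")
    cand <- screenHth$feature[screenHth$significant]
    if (length(cand) >= 2L) {
      panel <- stepwiseSelect(delta, maxFeatures = config$max_panel_features,
                              candidates = cand)
      report$counts$panel_size <- length(panel$selected)
      fits <- lapply(c("saliva", "serum", "combined"), function(sc)
        tryCatch(fitLogisticPanel(delta, panel$selected, sc),
                 error = function(e) NULL))
      names(fits) <- c("saliva", "serum", "combined")
      report$results$apparent_accuracy <- lapply(
        Filter(Negate(is.null), fits),
        function(f) f$accuracy$overall)
      mccv <- mccvAuc(delta, panel$selected,
                      nIter = config$mccv_iterations,
                      testFraction = config$mccv_test_fraction,
                      learner = config$mccv_learner, seed = config$seed)
      report$results$mccv_mean_auc <- mccv$mean_auc
      files <- c(files, .writeStage(
        data.frame(feature = panel$selected),
        file.path(outDir, "panel.tsv")))
    } else {
      report$counts$panel_size <- 0L
      report$results$classifier_note <-
        "fewer than 2 screen-passing candidates; classifier skipped"
    }
  }

  stage <- "screen_time"
  screenTime <- NULL
  if ("screen_time" %in% config$stages) {
    need("design", "screen_time")
    screenTime <- screenFeatures(delta, "temporal_bin",
                                 alphaFdr = config$alpha_time)
    report$counts$n_time_significant <- sum(screenTime$significant)
    files <- c(files, .writeStage(as.data.frame(screenTime),
                                  file.path(outDir, "screen_time.tsv")))
  }

  stage <- "patterns"
  calls <- NULL
  if ("patterns" %in% config$stages) {
    need("screen_time", "patterns")
    profiles <- binProfiles(delta)
    sig <- screenTime$feature[screenTime$significant]
    calls <- callPatterns(profiles, features = sig,
                          minLog2 = config$min_log2,
                          controlRatio = config$control_ratio)
    report$counts$n_asr <- sum(calls$label == "ASR")
    report$counts$n_dsr <- sum(calls$label == "DSR")
    files <- c(files, .writeStage(calls,
                                  file.path(outDir, "patterns.tsv")))
  }

  stage <- "associations"
  if ("associations" %in% config$stages) {
    need("design", "associations")
    corr <- correlateFeatures(delta)
    report$counts$n_hth_correlated <- sum(corr$significant)
    files <- c(files, .writeStage(corr,
                                  file.path(outDir, "correlations.tsv")))
    if (!is.null(cohort)) {
      fun <- knnImpute(functionalScores(cohort), k = config$knn_k)
      files <- c(files, .writeStage(fun, file.path(outDir,
                                                   "functional_imputed.tsv")))
      fscreen <- .screenFunctional(fun, delta, config$fdr_functional)
      if (!is.null(fscreen)) {
        report$counts$n_functional_significant <- sum(fscreen$significant)
        files <- c(files, .writeStage(as.data.frame(fscreen),
                                      file.path(outDir,
                                                "screen_functional.tsv")))
      }
    }
  }

  stage <- "proteins"
  if ("proteins" %in% config$stages && !is.null(cohort)) {
    prot <- proteinTable(cohort)
    rows <- lapply(unique(prot$analyte), function(a) {
      tab <- tryCatch(substituteBelowLod(prot, a), error = function(e) NULL)
      if (is.null(tab))
        return(data.frame(analyte = a, t = NA, p = NA,
                          median_pct_change = NA, slope = NA,
                          r_squared = NA, n = 0L, note = "unanalyzable"))
      tst <- pairedProteinTest(tab, a)
      reg <- proteinVsHthRegression(tab, a)
      data.frame(analyte = a, t = tst$t, p = tst$p,
                 median_pct_change = tst$median_pct_change,
                 slope = reg$slope, r_squared = reg$r_squared,
                 n = tst$n_pairs, note = "")
    })
    protRes <- do.call(rbind, rows)
    report$counts$n_protein_significant <-
      sum(protRes$p < 0.05, na.rm = TRUE)
    files <- c(files, .writeStage(protRes,
                                  file.path(outDir, "proteins.tsv")))
  }

  stage <- "factor"
  if ("factor" %in% config$stages && !is.null(cohort) && !is.null(calls)) {
    asr <- calls$feature[calls$label == "ASR"]
    joint <- .jointFunctionalMatrix(delta, cohort, asr, "saliva")
    if (!is.null(joint) && ncol(joint) > config$n_factors + 1L &&
        nrow(joint) >= 10L) {
      sol <- quartimaxRotate(
        suppressWarnings(principalAxisFactor(joint, config$n_factors)))
      grp <- groupByLoading(sol, config$loading_threshold)
      report$counts$n_factor_variables <- ncol(joint)
      report$results$variance_explained <-
        sum(sol@varianceExplained) / ncol(joint)
      ld <- data.frame(variable = rownames(factorLoadings(sol)),
                       factorLoadings(sol), check.names = FALSE)
      files <- c(files, .writeStage(ld, file.path(outDir, "loadings.tsv")))
    }
  }

  stage <- "report"
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  report$checksums <- as.list(sums)
  report$out_dir <- outDir
  yaml::write_yaml(report[c("counts", "results", "checksums")],
                   file.path(outDir, "report.yaml"))
  stage <- "done"
  report
}

## two-way screen of functional measures: one pseudo-sample per assessment
## per biofluid collected at that visit, mTBI class x fluid design
.screenFunctional <- function(fun, delta, alphaFdr) {
  cd <- as.data.frame(colData(delta))
  key <- paste(cd$subject_id, cd$timepoint)
  fkey <- paste(fun$subject_id, fun$timepoint)
  hit <- match(key, fkey)
  ok <- !is.na(hit)
  if (sum(ok) < 8L) return(NULL)
  meas <- t(as.matrix(fun[hit[ok], setdiff(colnames(fun),
                                           c("subject_id", "timepoint"))]))
  colnames(meas) <- cd$sample_id[ok]
  se <- SummarizedExperiment(
    assays = list(delta = meas),
    colData = DataFrame(cd[ok, c("subject_id", "fluid", "timepoint",
                                 "hth", "fought")],
                        row.names = cd$sample_id[ok]))
  cdd <- colData(se)
  cdd$tbi_class <- assignTbiClass(cdd$hth)
  colData(se) <- cdd
  tryCatch(screenFeatures(se, "tbi_class", alphaFdr = alphaFdr,
                          useAdjusted = TRUE),
           error = function(e) NULL)
}

## joint miRNA + functional matrix (observations x variables) for the
## factor analysis of one fluid's post-fight samples
.jointFunctionalMatrix <- function(delta, cohort, features, fluid) {
  if (length(features) < 2L) return(NULL)
  cd <- as.data.frame(colData(delta))
  cols <- which(cd$fluid == fluid)
  if (!length(cols)) return(NULL)
  fun <- functionalScores(cohort)
  fkey <- paste(fun$subject_id, fun$timepoint)
  key <- paste(cd$subject_id[cols], cd$timepoint[cols])
  hit <- match(key, fkey)
  ok <- !is.na(hit)
  if (sum(ok) < 10L) return(NULL)
  mir <- t(assay(delta, "delta")[features, cols[ok], drop = FALSE])
  meas <- as.matrix(fun[hit[ok], setdiff(colnames(fun),
                                         c("subject_id", "timepoint"))])
  cbind(mir, meas)
}
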