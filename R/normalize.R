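#' Read a count table and sample metadata from TSV/CSV
#'
#' \code{readCounts} expects a header row with sample labels and features in
#' the first column; \code{readSampleMeta} expects the columns
#' \code{sample_id, subject_id, fluid, timepoint, hth, fought}. Both accept
#' tab- or comma-separated files ('#'-prefixed lines are ignored).
#'
#' @param file path to the table.
#' @return \code{readCounts}: an integer matrix (features x samples, NA =
#'   not detected); \code{readSampleMeta}: a [S4Vectors::DataFrame].
#' @export
readCounts <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]]))
    stop("duplicate feature labels in ", file, call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample labels in ", file, call. = FALSE)
  ok <- is.na(m) | (m >= 0 & m == round(m))
  if (!all(ok))
    stop("counts must be nonnegative integers in ", file, call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCounts
#' @export
readSampleMeta <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "fluid", "timepoint", "hth", "fought")
  if (!all(need %in% colnames(d)))
    stop("sample metadata must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(d$hth[!d$fought] != 0))
    stop("hth must be 0 whenever fought is FALSE", call. = FALSE)
  DataFrame(d, row.names = d$sample_id)
}

#' Reference-miRNA log2 normalization
#'
#' Expresses every feature's count relative to an invariant reference miRNA
#' on the log2 scale: \code{value(f, s) = log2((count(f,s) + pseudocount) /
#' (count(ref,s) + pseudocount))}. The reference row of the result is
#' identically zero. Counts reported NA (not detected) propagate as NA.
#'
#' @param counts integer matrix (features x samples) or a
#'   [SummarizedExperiment::SummarizedExperiment] with a \code{"counts"}
#'   assay.
#' @param referenceId label of the reference feature; it must be present
#'   with a count > 0 in every sample.
#' @param pseudocount positive stabilizer added to every count (default 1).
#' @return object of the same shape with the normalized log2 matrix (assay
#'   \code{"log2norm"} when the input is a SummarizedExperiment).
#' @examples
#' cnt <- rbind(ref = c(100L, 7L), a = c(100L, 0L))
#' normalizeToReference(cnt, "ref")   # a: 0 and log2(1/8) = -3
#' @export
normalizeToReference <- function(counts, referenceId, pseudocount = 1) {
  se <- NULL
  if (is(counts, "SummarizedExperiment")) {
    se <- counts
    counts <- assay(se, "counts")
  }
  stopifnot(is.matrix(counts), pseudocount > 0)
  if (!referenceId %in% rownames(counts))
    stop("normalization error: reference '", referenceId,
         "' absent from the count matrix", call. = FALSE)
  ref <- counts[referenceId, ]
  bad <- is.na(ref) | ref <= 0
  if (any(bad))
    stop("normalization error: reference '", referenceId,
         "' missing or zero in sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  norm <- log2(sweep(counts + pseudocount, 2, ref + pseudocount, "/"))
  norm[referenceId, ] <- 0
  if (is.null(se)) return(norm)
  assays(se)[["log2norm"]] <- norm
  se
}

#' @importFrom SummarizedExperiment assays assays<-
NULL

#' Within-subject baseline differencing
#'
#' For every post-fight sample, subtracts the same subject's pre-fight
#' baseline from the normalized log2 values, yielding the log2 fold change
#' that is the currency of all downstream analysis. When a subject has both
#' baselines, the first available timepoint in \code{baselinePriority} is
#' used (default: the immediately-pre-fight sample, then the 1-week-pre
#' sample). Post samples in a fluid with no baseline in that fluid are
#' skipped with a warning and listed in \code{metadata(.)$skipped}.
#'
#' @param norm a SummarizedExperiment carrying assay \code{"log2norm"} and
#'   column data \code{subject_id, fluid, timepoint, hth, fought} (e.g. the
#'   output of [normalizeToReference()] on [mirCounts()]), or a plain matrix
#'   plus \code{meta}.
#' @param meta sample metadata ([S4Vectors::DataFrame] or data.frame) when
#'   \code{norm} is a matrix.
#' @param baselinePriority ordered pre-fight timepoints to use as baseline.
#' @return a [DeltaExperiment-class] with assay \code{"delta"}; columns are
#'   post samples, column data gain \code{baseline_sample}.
#' @export
baselineDelta <- function(norm, meta = NULL,
                          baselinePriority = c("pre_0d", "pre_1wk")) {
  if (is(norm, "SummarizedExperiment")) {
    meta <- colData(norm)
    mat <- assay(norm, "log2norm")
  } else mat <- norm
  stopifnot(!is.null(meta), all(colnames(mat) %in% rownames(meta)))
  meta <- as.data.frame(meta[colnames(mat), , drop = FALSE])
  stopifnot(all(baselinePriority %in% .PRE_TIMEPOINTS))

  isPost <- meta$timepoint %in% .POST_TIMEPOINTS
  ## first-available baseline per subject x fluid, in priority order
  baseOf <- rep(NA_character_, nrow(meta))
  for (i in which(isPost)) {
    for (tp in baselinePriority) {
      hit <- which(meta$subject_id == meta$subject_id[i] &
                   meta$fluid == meta$fluid[i] & meta$timepoint == tp)
      if (length(hit)) { baseOf[i] <- rownames(meta)[hit[1]]; break }
    }
  }
  keep <- isPost & !is.na(baseOf)
  skipped <- rownames(meta)[isPost & is.na(baseOf)]
  if (length(skipped))
    warning("skipping ", length(skipped),
            " post sample(s) with no baseline: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!any(keep))
    stop("no post sample has a usable baseline", call. = FALSE)
  delta <- mat[, keep, drop = FALSE] - mat[, baseOf[keep], drop = FALSE]
  cd <- DataFrame(meta[keep, c("subject_id", "fluid", "timepoint", "hth",
                               "fought"), drop = FALSE])
  cd$sample_id <- rownames(meta)[keep]
  cd$baseline_sample <- baseOf[keep]
  out <- new("DeltaExperiment",
             SummarizedExperiment(assays = list(delta = delta),
                                  colData = cd))
  metadata(out)$skipped <- skipped
  metadata(out)$baseline_priority <- baselinePriority
  out
}

#' Filter features by missingness
#'
#' Removes features whose fraction of missing delta values exceeds
#' \code{maxMissingFraction} (default 0.60, i.e. features with more than 60%
#' missingness are eliminated). By default the fraction is computed within
#' each fluid separately and a feature must pass in every fluid it appears
#' in; \code{perFluid = FALSE} pools all columns. Feature order is
#' preserved; the operation is idempotent.
#'
#' @param delta a [DeltaExperiment-class] (or matrix with \code{fluid}
#'   supplied via \code{meta}).
#' @param maxMissingFraction maximum tolerated missing fraction in [0, 1].
#' @param perFluid compute missingness per fluid (default TRUE).
#' @return the filtered object; removed features are recorded in
#'   \code{metadata(.)$removed_features}.
#' @export
filterMissingness <- function(delta, maxMissingFraction = 0.60,
                              perFluid = TRUE) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
  mat <- assay(delta, "delta")
  fluid <- colData(delta)$fluid
  frac <- if (perFluid) {
    do.call(pmax, c(lapply(unique(fluid), function(fl)
      rowMeans(is.na(mat[, fluid == fl, drop = FALSE]))),
      list(na.rm = TRUE)))
  } else rowMeans(is.na(mat))
  keep <- frac <= maxMissingFraction
  out <- delta[keep, ]
  metadata(out)$removed_features <- rownames(delta)[!keep]
  out
}

#' K-nearest-neighbour imputation of functional scores
#'
#' Replaces each missing cell by the unweighted mean of that column over the
#' \code{k} nearest rows (by Euclidean distance on mutually observed
#' columns, after scaling every column by its standard deviation) among rows
#' where the target column is observed. Observed cells are returned
#' bit-exactly unchanged.
#'
#' @param table data.frame or matrix of numeric measure columns; non-numeric
#'   columns (identifiers) are passed through untouched.
#' @param k number of neighbours (default 5).
#' @return the table with no missing numeric cells.
#' @export
knnImpute <- function(table, k = 5L) {
  stopifnot(k >= 1L)
  df <- as.data.frame(table)
  numCols <- vapply(df, is.numeric, logical(1))
  x <- as.matrix(df[, numCols, drop = FALSE])
  if (!anyNA(x)) return(table)
  if (any(colSums(!is.na(x)) == 0))
    stop("imputation error: column(s) missing in all rows: ",
         paste(colnames(x)[colSums(!is.na(x)) == 0], collapse = ", "),
         call. = FALSE)
  if (any(rowSums(!is.na(x)) == 0))
    stop("imputation error: row(s) with no observed value", call. = FALSE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  z <- sweep(x, 2, sds, "/")
  filled <- x
  for (j in which(colSums(is.na(x)) > 0)) {
    donors <- which(!is.na(x[, j]))
    if (k > length(donors))
      stop("imputation error: k exceeds rows with column '",
           colnames(x)[j], "' observed", call. = FALSE)
    for (i in which(is.na(x[, j]))) {
      d <- vapply(donors, function(r) {
        shared <- !is.na(z[i, ]) & !is.na(z[r, ])
        if (!any(shared)) return(Inf)
        sqrt(sum((z[i, shared] - z[r, shared])^2) / sum(shared))
      }, numeric(1))
      nn <- donors[order(d, donors)[seq_len(k)]]
      filled[i, j] <- mean(x[nn, j])
    }
  }
  df[, numCols] <- filled
  if (is.matrix(table)) {
    out <- as.matrix(df)
    names(out) <- NULL
    dimnames(out) <- dimnames(table)
    out
  } else df
}
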