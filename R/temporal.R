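#' Per-bin mean change profiles
#'
#' Arithmetic mean of the delta values per (feature, fluid, temporal bin),
#' over assigned bins only; bins with no samples are absent (NA) with n = 0.
#'
#' @param delta a [DeltaExperiment-class] with design columns from
#'   [addCohortDesign()].
#' @return data.frame with columns \code{feature, fluid, bin, mean, n}.
#' @export
binProfiles <- function(delta) {
  cd <- colData(delta)
  if (!"temporal_bin" %in% colnames(cd))
    stop("run addCohortDesign() first", call. = FALSE)
  y <- assay(delta, "delta")
  bins <- setdiff(.TEMPORAL_BINS, "unassigned")
  grid <- expand.grid(feature = rownames(y), fluid = .FLUIDS, bin = bins,
                      stringsAsFactors = FALSE)
  grid$mean <- NA_real_
  grid$n <- 0L
  for (fl in .FLUIDS) for (b in bins) {
    cols <- which(cd$fluid == fl & cd$temporal_bin == b)
    rows <- grid$fluid == fl & grid$bin == b
    if (length(cols)) {
      sub <- y[, cols, drop = FALSE]
      grid$n[rows] <- as.integer(rowSums(!is.na(sub)))
      mns <- rowMeans(sub, na.rm = TRUE)
      mns[grid$n[rows] == 0L] <- NA_real_
      grid$mean[rows] <- mns
    }
  }
  grid
}

.profileOf <- function(profiles, feat, fl) {
  sub <- profiles[profiles$feature == feat & profiles$fluid == fl, ]
  stats::setNames(sub$mean, sub$bin)
}

#' Acute-saliva / delayed-serum pattern calls
#'
#' Applies the explicit rule that defines the two temporal biomarker
#' archetypes. A post-fight change qualifies only if it exceeds 1.3-fold
#' (operationalized as a log2 change of +/- \code{minLog2}, default 0.28)
#' and exceeds the magnitude of change in the HTH-negative control group by
#' at least \code{controlRatio}-fold (default 2).
#'
#' \emph{ASR} (acute saliva response): the saliva T1 HTH+ mean is at least
#' +\code{minLog2} (increases only), at least \code{controlRatio} times the
#' control magnitude, and the saliva change has returned to near baseline
#' (|mean| < \code{minLog2}) by 2-3 days. \emph{DSR} (delayed serum
#' response): the serum 1-week mean magnitude is at least \code{minLog2}
#' (either sign) and \code{controlRatio} times the control magnitude, no
#' acute serum change is present (|T1 HTH+| < \code{minLog2}), and the
#' response is graded, peaking at 1 week (|T3| >= |T2|). A feature
#' satisfying both is called ASR (logged in the \code{both} column). Each
#' narrative sub-criterion is independently toggleable.
#'
#' @param profiles output of [binProfiles()].
#' @param features features to call (default: all in \code{profiles});
#'   restrict to time-screen-significant features for the published
#'   procedure.
#' @param minLog2 minimum absolute log2 change (default 0.28).
#' @param controlRatio required fold over the control magnitude (default 2).
#' @param requireReturn enforce the ASR return-to-baseline condition.
#' @param requireNoAcute enforce the DSR no-acute-change condition.
#' @param requireGraded enforce the DSR peak-at-1-week condition.
#' @return data.frame with one row per feature: \code{label} (ASR / DSR /
#'   none), \code{direction} (up / down / n/a), per-criterion booleans, a
#'   \code{reason} for non-calls with missing bins, and the per-bin means.
#' @export
callPatterns <- function(profiles, features = unique(profiles$feature),
                         minLog2 = 0.28, controlRatio = 2,
                         requireReturn = TRUE, requireNoAcute = TRUE,
                         requireGraded = TRUE) {
  res <- lapply(features, function(feat) {
    sal <- .profileOf(profiles, feat, "saliva")
    ser <- .profileOf(profiles, feat, "serum")
    out <- data.frame(feature = feat, label = "none", direction = "n/a",
                      asr_magnitude = NA, asr_over_control = NA,
                      asr_return = NA, dsr_magnitude = NA,
                      dsr_over_control = NA, dsr_no_acute = NA,
                      dsr_graded = NA, both = FALSE, reason = "",
                      stringsAsFactors = FALSE)

    asrOK <- FALSE
    need <- c("T1_HTHneg", "T1_HTHpos", "T2_HTHpos")
    if (anyNA(sal[need])) {
      out$reason <- paste("saliva bin absent:",
                          paste(need[is.na(sal[need])], collapse = ","))
    } else {
      out$asr_magnitude <- sal["T1_HTHpos"] >= minLog2      # increases only
      out$asr_over_control <-
        abs(sal["T1_HTHpos"]) >= controlRatio * abs(sal["T1_HTHneg"])
      out$asr_return <- abs(sal["T2_HTHpos"]) < minLog2
      asrOK <- out$asr_magnitude && out$asr_over_control &&
        (!requireReturn || out$asr_return)
    }

    dsrOK <- FALSE
    need <- c("T1_HTHneg", "T1_HTHpos", "T2_HTHpos", "T3_HTHpos")
    if (anyNA(ser[need])) {
      if (!nzchar(out$reason))
        out$reason <- paste("serum bin absent:",
                            paste(need[is.na(ser[need])], collapse = ","))
    } else {
      out$dsr_magnitude <- abs(ser["T3_HTHpos"]) >= minLog2
      out$dsr_over_control <-
        abs(ser["T3_HTHpos"]) >= controlRatio * abs(ser["T1_HTHneg"])
      out$dsr_no_acute <- abs(ser["T1_HTHpos"]) < minLog2
      out$dsr_graded <- abs(ser["T3_HTHpos"]) >= abs(ser["T2_HTHpos"])
      dsrOK <- out$dsr_magnitude && out$dsr_over_control &&
        (!requireNoAcute || out$dsr_no_acute) &&
        (!requireGraded || out$dsr_graded)
    }

    if (asrOK && dsrOK) out$both <- TRUE
    if (asrOK) {                                   # ASR takes precedence
      out$label <- "ASR"
      out$direction <- "up"
    } else if (dsrOK) {
      out$label <- "DSR"
      out$direction <- if (ser["T3_HTHpos"] >= 0) "up" else "down"
    }
    out$saliva_T1neg <- sal["T1_HTHneg"]; out$saliva_T1pos <- sal["T1_HTHpos"]
    out$saliva_T2 <- sal["T2_HTHpos"]; out$saliva_T3 <- sal["T3_HTHpos"]
    out$serum_T1neg <- ser["T1_HTHneg"]; out$serum_T1pos <- ser["T1_HTHpos"]
    out$serum_T2 <- ser["T2_HTHpos"]; out$serum_T3 <- ser["T3_HTHpos"]
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(out$both))
    message(sum(out$both), " feature(s) satisfied both ASR and DSR; ",
            "called ASR by precedence")
  out
}
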