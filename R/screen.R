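#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around \code{stats::p.adjust(method = "BH")}: q_i is the
#' minimum over j >= rank(i) of m * p_(j) / j, capped at 1, returned in the
#' input order. NAs are preserved and excluded from m.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of BH-adjusted q-values.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
benjaminiHochberg <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

.rssByPattern <- function(X, Y) {
  ## residual sum of squares of every column of Y on the column span of X
  q <- qr(X)
  list(rss = colSums(qr.resid(q, Y)^2), rank = q$rank)
}

#' Feature-wise two-way fixed-effects screen
#'
#' Fits, for every feature, an unbalanced two-way fixed-effects linear model
#' with interaction on the observed delta values: factor A is either the
#' mTBI-likelihood class (\code{tbi_class}, the head-impact dose screen) or
#' the temporal bin (\code{temporal_bin}, the time screen); factor B is the
#' biofluid. Type-II sums of squares give F tests for the two main effects
#' and their interaction (each main effect is tested after the other main
#' effect, the standard choice for unbalanced observational designs);
#' Benjamini-Hochberg adjustment is applied separately to each of the three
#' p-value columns across the tested features.
#'
#' Features are grouped by their missingness pattern so the four model
#' projections are computed once per pattern, which keeps genome-scale
#' screens fast. Features whose observed columns collapse a factor level are
#' tested on the reduced design and flagged; features where a factor retains
#' a single level get NA for the affected tests and are reported, not
#' dropped. Features with (numerically) constant values get F = 0, p = 1.
#'
#' Significance: for the dose screen, \code{q_factor <= alphaFdr} (default
#' FDR 0.15); for the time screen the convention is the unadjusted
#' \code{p_factor < 0.05}, with q-values still reported. Override with
#' \code{useAdjusted}.
#'
#' @param delta a [DeltaExperiment-class] with design columns from
#'   [addCohortDesign()].
#' @param factorA \code{"tbi_class"} or \code{"temporal_bin"}.
#' @param alphaFdr significance level (default 0.15 for the dose screen,
#'   0.05 for the time screen).
#' @param useAdjusted use BH q-values for the significance call (default
#'   TRUE for \code{tbi_class}, FALSE for \code{temporal_bin}).
#' @return a [S4Vectors::DataFrame] with one row per feature: \code{p_factor,
#'   p_fluid, p_interaction}, matching \code{q_} columns, \code{n_used},
#'   \code{reduced} (collapsed-level flag) and \code{significant};
#'   screen parameters are stored in its metadata.
#' @export
screenFeatures <- function(delta,
                           factorA = c("tbi_class", "temporal_bin"),
                           alphaFdr = NULL, useAdjusted = NULL) {
  factorA <- match.arg(factorA)
  if (is.null(alphaFdr)) alphaFdr <- if (factorA == "tbi_class") 0.15 else 0.05
  if (is.null(useAdjusted)) useAdjusted <- factorA == "tbi_class"
  cd <- colData(delta)
  if (!factorA %in% colnames(cd))
    stop("run addCohortDesign() first: column '", factorA, "' absent",
         call. = FALSE)
  keep <- if (factorA == "temporal_bin") cd[[factorA]] != "unassigned"
          else rep(TRUE, ncol(delta))
  y <- assay(delta, "delta")[, keep, drop = FALSE]
  A <- droplevels(factor(cd[[factorA]][keep]))
  B <- droplevels(factor(cd$fluid[keep]))
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("screening error: factor with fewer than two observed levels",
         call. = FALSE)

  feats <- rownames(y)
  res <- data.frame(feature = feats, p_factor = NA_real_, p_fluid = NA_real_,
                    p_interaction = NA_real_, n_used = 0L, reduced = FALSE,
                    stringsAsFactors = FALSE)

  pattern <- apply(!is.na(y), 1, function(o) paste(which(o), collapse = ","))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    obs <- as.integer(strsplit(pat, ",")[[1]])
    res$n_used[rows] <- length(obs)
    if (length(obs) < 4L) next
    a <- droplevels(A[obs]); b <- droplevels(B[obs])
    collapsed <- nlevels(a) < nlevels(A) || nlevels(b) < nlevels(B)
    res$reduced[rows] <- collapsed
    Y <- t(y[rows, obs, drop = FALSE])
    if (nlevels(a) < 2L || nlevels(b) < 2L) {
      ## a factor lost all contrast: test the other one one-way
      fac <- if (nlevels(a) >= 2L) a else if (nlevels(b) >= 2L) b else NULL
      if (!is.null(fac)) {
        mF <- .rssByPattern(stats::model.matrix(~ fac), Y)
        m0 <- .rssByPattern(matrix(1, length(obs), 1), Y)
        dfRes <- length(obs) - mF$rank
        df <- mF$rank - 1L
        if (dfRes >= 1L && df >= 1L) {
          totVar <- colSums(scale(Y, scale = FALSE)^2)
          f <- ifelse(totVar < 1e-12, 0,
                      ((m0$rss - mF$rss) / df) / (mF$rss / dfRes))
          pv <- ifelse(totVar < 1e-12, 1,
                       stats::pf(f, df, dfRes, lower.tail = FALSE))
          if (nlevels(a) >= 2L) res$p_factor[rows] <- pv
          else res$p_fluid[rows] <- pv
        }
      }
      next
    }
    mFull <- .rssByPattern(stats::model.matrix(~ a * b), Y)
    mAB <- .rssByPattern(stats::model.matrix(~ a + b), Y)
    mA <- .rssByPattern(stats::model.matrix(~ a), Y)
    mB <- .rssByPattern(stats::model.matrix(~ b), Y)
    dfRes <- length(obs) - mFull$rank
    if (dfRes < 1L) next
    mse <- mFull$rss / dfRes
    totVar <- colSums(scale(Y, scale = FALSE)^2)
    fTest <- function(rssRed, rankRed, rssNest, rankNest) {
      df <- rankNest - rankRed
      if (df < 1L) return(rep(NA_real_, length(rssRed)))
      ss <- pmax(rssRed - rssNest, 0)
      f <- ifelse(totVar < 1e-12, 0, (ss / df) / mse)
      ifelse(totVar < 1e-12, 1,
             stats::pf(f, df, dfRes, lower.tail = FALSE))
    }
    res$p_factor[rows] <- fTest(mB$rss, mB$rank, mAB$rss, mAB$rank)
    res$p_fluid[rows] <- fTest(mA$rss, mA$rank, mAB$rss, mAB$rank)
    res$p_interaction[rows] <- fTest(mAB$rss, mAB$rank, mFull$rss,
                                     mFull$rank)
  }

  res$q_factor <- benjaminiHochberg(res$p_factor)
  res$q_fluid <- benjaminiHochberg(res$p_fluid)
  res$q_interaction <- benjaminiHochberg(res$p_interaction)
  res$significant <- if (useAdjusted) !is.na(res$q_factor) &
                       res$q_factor <= alphaFdr
                     else !is.na(res$p_factor) & res$p_factor < alphaFdr
  out <- DataFrame(res)
  metadata(out) <- list(factorA = factorA, alphaFdr = alphaFdr,
                        useAdjusted = useAdjusted,
                        n_samples = sum(keep))
  out
}
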