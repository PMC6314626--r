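#' Correlate feature changes with a covariate
#'
#' Pearson correlation of each feature's delta values with a per-sample
#' covariate (the HTH counts themselves, or a functional difference score
#' aligned to the delta columns), on pairwise-complete observations, within
#' each requested scope (all samples, saliva only, serum only). Significance
#' comes from the r-to-t transform \code{t = r * sqrt((n - 2) / (1 - r^2))}
#' (two-sided). For the HTH covariate the published convention is a
#' Bonferroni family-wise correction over the whole feature x scope family;
#' functional covariates are interpreted at unadjusted p < 0.05
#' (\code{adjust = "none"}). Benjamini-Hochberg is available via
#' \code{adjust = "BH"}.
#'
#' @param delta a [DeltaExperiment-class].
#' @param covariate numeric vector, one value per delta column (default: the
#'   HTH counts from the column data).
#' @param covariateName label recorded in the output.
#' @param scopes subset of \code{c("all", "saliva", "serum")}.
#' @param adjust \code{"bonferroni"} (default), \code{"BH"} or
#'   \code{"none"}.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns \code{feature, covariate, scope, r, n, p,
#'   p_adjusted, significant}; the adjustment family is all rows returned.
#' @export
correlateFeatures <- function(delta, covariate = colData(delta)$hth,
                              covariateName = "HTH",
                              scopes = c("all", "saliva", "serum"),
                              adjust = c("bonferroni", "BH", "none"),
                              alpha = 0.05) {
  adjust <- match.arg(adjust)
  y <- assay(delta, "delta")
  fluid <- colData(delta)$fluid
  covariate <- as.numeric(covariate)
  stopifnot(length(covariate) == ncol(y))
  rows <- list()
  for (sc in scopes) {
    cols <- if (sc == "all") seq_len(ncol(y)) else which(fluid == sc)
    for (f in rownames(y)) {
      ok <- !is.na(y[f, cols]) & !is.na(covariate[cols])
      n <- sum(ok)
      r <- p <- NA_real_
      if (n >= 3) {
        xv <- y[f, cols][ok]; cv <- covariate[cols][ok]
        if (stats::sd(xv) > 0 && stats::sd(cv) > 0) {
          r <- stats::cor(xv, cv)
          tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
          p <- 2 * stats::pt(-abs(tt), n - 2)
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, covariate = covariateName, scope = sc,
                   r = r, n = n, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjust,
    bonferroni = pmin(out$p * sum(!is.na(out$p)), 1),
    BH = benjaminiHochberg(out$p),
    none = out$p)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  attr(out, "adjust") <- adjust
  attr(out, "family_size") <- sum(!is.na(out$p))
  out
}

#' Paired pre/post test for one protein analyte
#'
#' Two-sided paired t test of post-fight versus pre-fight concentrations
#' over complete pairs (after any below-LOD substitution), plus the median
#' percent change \code{median(100 * (post - pre) / pre)}. Zero-variance
#' differences are guarded (t = 0, p = 1).
#'
#' @param proteins protein panel data.frame (columns \code{subject_id,
#'   analyte, pre, post, ...}).
#' @param analyte analyte name.
#' @return list with \code{t, p, median_pct_change, n_pairs}.
#' @export
pairedProteinTest <- function(proteins, analyte) {
  sub <- proteins[proteins$analyte == analyte, ]
  ok <- !is.na(sub$pre) & !is.na(sub$post)
  if (sum(ok) < 2)
    stop("need >= 2 complete pairs for '", analyte, "'", call. = FALSE)
  d <- sub$post[ok] - sub$pre[ok]
  if (stats::sd(d) < 1e-12) {
    tt <- 0; p <- 1
  } else {
    ht <- stats::t.test(d)
    tt <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = tt, p = p,
       median_pct_change = stats::median(100 * d / sub$pre[ok]),
       n_pairs = sum(ok))
}

#' Substitute below-LOD pre-fight values
#'
#' Replaces every below-LOD pre-fight concentration of an analyte by half
#' the lowest measurable post-fight concentration of that analyte (the
#' standard half-minimum substitution for immunoassay values below the
#' limit of detection). Measurable values are never altered and the
#' operation is idempotent; substituted rows are flagged in
#' \code{pre_substituted} and the count is reported via
#' \code{attr(., "n_substituted")}.
#'
#' @param proteins protein panel data.frame with columns \code{analyte, pre,
#'   post, pre_below_lod, post_below_lod}.
#' @param analyte analyte name.
#' @param rule substitution rule; only \code{"half_min_post"} is defined.
#' @return the table with substituted pre values.
#' @examples
#' tab <- data.frame(subject_id = 1:2, analyte = "S100B",
#'                   pre = c(NA, 50), post = c(45.4, 60),
#'                   pre_below_lod = c(TRUE, FALSE),
#'                   post_below_lod = FALSE)
#' substituteBelowLod(tab, "S100B")$pre[1]  # 22.7
#' @export
substituteBelowLod <- function(proteins, analyte, rule = "half_min_post") {
  rule <- match.arg(rule)
  idx <- proteins$analyte == analyte
  measurablePost <- idx & !proteins$post_below_lod & !is.na(proteins$post)
  if (!any(measurablePost))
    stop("analyte unanalyzable: '", analyte,
         "' has no measurable post-fight value", call. = FALSE)
  fill <- 0.5 * min(proteins$post[measurablePost])
  target <- idx & proteins$pre_below_lod
  proteins$pre[target] <- fill
  if (!"pre_substituted" %in% colnames(proteins))
    proteins$pre_substituted <- FALSE
  proteins$pre_substituted[target] <- TRUE
  attr(proteins, "n_substituted") <- sum(target)
  proteins
}

#' Regression of protein change on hits to the head
#'
#' Ordinary least squares of the post-minus-pre concentration change on the
#' per-subject HTH count.
#'
#' @param proteins protein panel data.frame.
#' @param analyte analyte name.
#' @param hth per-row HTH values (default: the table's \code{hth} column).
#' @return list with \code{slope, r_squared, p, n}.
#' @export
proteinVsHthRegression <- function(proteins, analyte,
                                   hth = proteins$hth[proteins$analyte ==
                                                        analyte]) {
  sub <- proteins[proteins$analyte == analyte, ]
  ok <- !is.na(sub$pre) & !is.na(sub$post) & !is.na(hth)
  if (sum(ok) < 3)
    stop("need >= 3 subjects with change and HTH for '", analyte, "'",
         call. = FALSE)
  fit <- stats::lm((sub$post - sub$pre)[ok] ~ hth[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = sum(ok))
}

#' Brain enrichment from a tissue expression atlas
#'
#' A feature is brain-enriched iff its median expression over the CNS
#' sources strictly exceeds the median expression of every non-neural
#' source.
#'
#' @param atlas matrix of per-source median expression, features x sources.
#' @param cnsSources column names that are CNS sources.
#' @param features features to test (default all).
#' @return named logical vector.
#' @export
brainEnriched <- function(atlas, cnsSources, features = rownames(atlas)) {
  stopifnot(all(cnsSources %in% colnames(atlas)),
            length(cnsSources) >= 1,
            length(setdiff(colnames(atlas), cnsSources)) >= 1)
  nonCns <- setdiff(colnames(atlas), cnsSources)
  vapply(features, function(f) {
    stats::median(atlas[f, cnsSources]) > max(atlas[f, nonCns])
  }, logical(1))
}
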