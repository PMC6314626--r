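.pairwiseCorrelation <- function(x) {
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(r))
    stop("correlation undefined for variable pair(s) with no shared ",
         "observations or zero variance", call. = FALSE)
  smoothed <- FALSE
  e <- eigen(r, symmetric = TRUE)
  if (any(e$values < -1e-8)) {       # pairwise-complete can leave R non-PSD
    smoothed <- TRUE
    v <- pmax(e$values, 0)
    r <- e$vectors %*% (v * t(e$vectors))
    r <- stats::cov2cor(r)
    dimnames(r) <- dimnames(e$vectors)
  }
  list(r = r, smoothed = smoothed)
}

.smcInit <- function(r) {
  h2 <- tryCatch(1 - 1 / diag(solve(r)),
                 error = function(e) apply(abs(r - diag(diag(r))), 1, max))
  pmin(pmax(h2, 0.05), 0.995)
}

## deterministic sign convention: largest-magnitude loading positive
.fixSigns <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Iterative principal-axis factoring
#'
#' Extracts common factors from the correlation matrix of the input
#' variables by the principal-axis method: the diagonal is replaced by
#' communality estimates (initialized at squared multiple correlations), the
#' reduced matrix is eigendecomposed, loadings are the top eigenvectors
#' scaled by the square roots of their eigenvalues, communalities are
#' updated to the row sums of squared loadings, and the cycle repeats until
#' the largest communality change falls below \code{tol} or \code{maxIter}
#' is reached (non-convergence returns the solution with a warning flag).
#' Heywood cases (communality above 1) are clipped and recorded. Variables
#' are standardized implicitly by working on the correlation (not
#' covariance) matrix; missing observations enter through pairwise-complete
#' correlations with eigenvalue-clipping PSD smoothing, flagged when
#' applied.
#'
#' @param data numeric matrix or data.frame, observations in rows and
#'   variables in columns (NAs allowed).
#' @param nFactors number of factors (must be < number of variables).
#' @param tol communality convergence tolerance (default 1e-4).
#' @param maxIter maximum iterations (default 100).
#' @return a [FactorSolution-class] (unrotated).
#' @export
principalAxisFactor <- function(data, nFactors, tol = 1e-4, maxIter = 100L) {
  x <- as.matrix(data)
  stopifnot(is.numeric(x), nFactors >= 1L)
  if (nFactors >= ncol(x))
    stop("nFactors must be smaller than the number of variables",
         call. = FALSE)
  pc <- .pairwiseCorrelation(x)
  r <- pc$r
  h2 <- .smcInit(r)
  heywood <- logical(ncol(x))
  iter <- 0L
  converged <- FALSE
  L <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    rr <- r
    diag(rr) <- h2
    e <- eigen(rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(nFactors)], 0)
    L <- e$vectors[, seq_len(nFactors), drop = FALSE] %*% diag(sqrt(ev),
                                                               nFactors)
    h2new <- rowSums(L^2)
    hw <- h2new > 1
    heywood <- heywood | hw
    h2new[hw] <- 1
    if (max(abs(h2new - h2)) < tol) {
      h2 <- h2new
      converged <- TRUE
      break
    }
    h2 <- h2new
  }
  if (!converged)
    warning("principal-axis iteration did not converge in ", maxIter,
            " iterations", call. = FALSE)
  if (pc$smoothed)
    message("pairwise-complete correlation matrix smoothed to PSD")
  L <- .fixSigns(L)
  dimnames(L) <- list(colnames(x), paste0("Factor", seq_len(nFactors)))
  names(h2) <- colnames(x)
  new("FactorSolution", loadings = L, communalities = pmin(h2, 1),
      varianceExplained = colSums(L^2), rotation = "none",
      iterations = iter, converged = converged,
      heywood = colnames(x)[heywood])
}

#' Quartimax rotation
#'
#' Orthogonal rotation maximizing the sum of fourth powers of the loadings,
#' by iterated pairwise plane rotations (Kaiser's closed-form angle for the
#' orthomax family with weight 0) until the criterion changes by less than
#' \code{tol}. Communalities, row sums of squared loadings and the fitted
#' correlation matrix L L' are preserved. A 1-factor solution is returned
#' unchanged (rotation of a single axis is the identity).
#'
#' @param solution a [FactorSolution-class].
#' @param tol criterion convergence tolerance (default 1e-8).
#' @param maxSweeps maximum full sweeps over factor pairs (default 100).
#' @return the rotated [FactorSolution-class] (factors reordered by
#'   explained variance, signs fixed).
#' @export
quartimaxRotate <- function(solution, tol = 1e-8, maxSweeps = 100L) {
  L <- solution@loadings
  k <- ncol(L)
  if (k < 2L) {
    out <- solution
    out@rotation <- "quartimax"
    return(out)
  }
  crit <- sum(L^4)
  for (sweep in seq_len(maxSweeps)) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      x <- L[, i]; y <- L[, j]
      u <- x^2 - y^2
      v <- 2 * x * y
      num <- sum(2 * u * v)
      den <- sum(u^2 - v^2)
      theta <- atan2(num, den) / 4
      if (abs(theta) < 1e-12) next
      co <- cos(theta); si <- sin(theta)
      L[, i] <- co * x + si * y
      L[, j] <- -si * x + co * y
    }
    newCrit <- sum(L^4)
    if (newCrit - crit < tol) break
    crit <- newCrit
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- .fixSigns(L[, ord, drop = FALSE])
  colnames(L) <- paste0("Factor", seq_len(k))
  out <- solution
  out@loadings <- L
  out@varianceExplained <- colSums(L^2)
  out@rotation <- "quartimax"
  out
}

#' Group variables by factor loading
#'
#' Per factor, lists the variables whose absolute loading meets the
#' threshold (default 0.4, the conventional cut for a strong loading),
#' partitioned by sign. A variable may appear under several factors.
#'
#' @param solution a [FactorSolution-class].
#' @param threshold positive loading cutoff (default 0.4).
#' @return named list, one element per factor, each with \code{positive} and
#'   \code{negative} character vectors.
#' @export
groupByLoading <- function(solution, threshold = 0.4) {
  stopifnot(threshold > 0)
  L <- solution@loadings
  out <- lapply(seq_len(ncol(L)), function(j) {
    hit <- abs(L[, j]) >= threshold
    list(positive = rownames(L)[hit & L[, j] > 0],
         negative = rownames(L)[hit & L[, j] < 0])
  })
  names(out) <- if (is.null(colnames(L))) paste0("Factor", seq_len(ncol(L)))
                else colnames(L)
  out
}
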