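.roundHalfUp <- function(x) floor(x + 0.5)

## samples x features matrix of delta values with missing cells replaced by
## the within-fluid feature mean (falling back to the overall mean)
.panelMatrix <- function(delta, features = rownames(delta)) {
  x <- t(assay(delta, "delta")[features, , drop = FALSE])
  fluid <- colData(delta)$fluid
  for (j in seq_len(ncol(x))) {
    for (fl in unique(fluid)) {
      idx <- fluid == fl
      nas <- idx & is.na(x[, j])
      if (any(nas)) {
        fill <- mean(x[idx, j], na.rm = TRUE)
        if (!is.finite(fill)) fill <- mean(x[, j], na.rm = TRUE)
        if (!is.finite(fill)) fill <- 0
        x[nas, j] <- fill
      }
    }
  }
  x
}

#' Forward stepwise panel selection against HTH
#'
#' Selects the miRNA panel that best predicts the actual hits-to-the-head
#' values by forward stepwise linear regression: at each step the candidate
#' whose addition minimizes AIC joins the model; selection stops when AIC no
#' longer decreases, when \code{maxFeatures} (default 13) is reached, or
#' when fewer than two samples per estimated parameter would remain (early
#' stop with a warning). Ties are broken deterministically by feature label
#' order. Missing candidate values are mean-substituted within fluid.
#'
#' @param delta a [DeltaExperiment-class], typically restricted to
#'   screen-passing features.
#' @param hth per-sample hit counts (default: from the column data).
#' @param maxFeatures maximum panel size (default 13).
#' @param candidates candidate feature labels (default all rows).
#' @return list with \code{selected} (ordered labels), \code{aic} (criterion
#'   value after each step, starting from the intercept-only model),
#'   \code{coefficients} of the final linear model (log2-change units to
#'   hits) and \code{r_squared}.
#' @export
stepwiseSelect <- function(delta, hth = colData(delta)$hth,
                           maxFeatures = 13L, candidates = rownames(delta)) {
  if (maxFeatures < 1L)
    stop("selection error: maxFeatures must be >= 1", call. = FALSE)
  if (length(candidates) < 2L)
    stop("selection error: need >= 2 candidate features", call. = FALSE)
  x <- .panelMatrix(delta, candidates)
  y <- as.numeric(hth)
  n <- length(y)
  candidates <- sort(candidates)

  aicOf <- function(cols) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x[, cols, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    n * log(max(rss, 1e-12) / n) + 2 * (length(cols) + 2)
  }
  selected <- character()
  path <- aicOf(character())
  repeat {
    if (length(selected) >= maxFeatures) break
    if (n < 2 * (length(selected) + 3)) {
      warning("stepwise selection stopped early: fewer than 2 samples per ",
              "parameter", call. = FALSE)
      break
    }
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(f) aicOf(c(selected, f)), numeric(1))
    best <- which.min(trial)                       # first = label order
    if (trial[best] >= path[length(path)] - 1e-9) break
    selected <- c(selected, remaining[best])
    path <- c(path, trial[best])
  }
  fit <- if (length(selected))
    stats::lm(y ~ ., data = as.data.frame(x[, selected, drop = FALSE]))
  else stats::lm(y ~ 1)
  list(selected = selected, aic = path,
       coefficients = stats::coef(fit),
       r_squared = summary(fit)$r.squared)
}

## logistic regression with a small ridge penalty (excluding the intercept),
## by penalized iteratively reweighted least squares; used when the
## unpenalized ML fit separates
.ridgeLogistic <- function(X, y, lambda = 1e-4, maxit = 200L, tol = 1e-10) {
  X1 <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(X1))
  beta <- numeric(ncol(X1))
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X1 %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    step <- solve(crossprod(X1, X1 * w) + pen,
                  crossprod(X1, y - p) - pen %*% beta)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

.logisticScores <- function(xTrain, yTrain, xTest) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, xTrain), yTrain,
                                         family = stats::binomial()))
  prob <- fit$fitted.values
  separated <- !fit$converged || any(prob > 1 - 1e-8) || any(prob < 1e-8)
  beta <- if (separated) .ridgeLogistic(xTrain, yTrain) else fit$coefficients
  list(scores = stats::plogis(drop(cbind(1, xTest) %*% beta)),
       separated = separated, beta = beta)
}

#' Accuracies from a 2x2 confusion matrix
#'
#' Per-class accuracy is 100 * correct / row total; overall accuracy is
#' 100 * trace / total; both rounded to the nearest integer (half away from
#' zero), the convention of printed classification tables.
#'
#' @param counts 2x2 matrix of nonnegative integers, observed classes in
#'   rows, predicted in columns.
#' @return list with \code{per_class} (length 2) and \code{overall}.
#' @examples
#' accuracyFromConfusion(matrix(c(38, 5, 7, 39), 2))  # 84, 89; overall 87
#' @export
accuracyFromConfusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0),
            all(counts == round(counts)), sum(counts) > 0)
  rs <- rowSums(counts)
  perClass <- ifelse(rs > 0, .roundHalfUp(100 * diag(counts) / rs), NA_real_)
  list(per_class = stats::setNames(perClass, rownames(counts)),
       overall = .roundHalfUp(100 * sum(diag(counts)) / sum(counts)))
}

.classifierSamples <- function(delta, scope) {
  cd <- colData(delta)
  if (!"tbi_class" %in% colnames(cd))
    stop("run addCohortDesign() first", call. = FALSE)
  keep <- cd$tbi_class %in% c("Low", "VeryLikely")
  if (scope != "combined") keep <- keep & cd$fluid == scope
  cls <- droplevels(factor(cd$tbi_class[keep], c("Low", "VeryLikely")))
  if (nlevels(cls) < 2L)
    stop("classification error: class absent in scope '", scope, "'",
         call. = FALSE)
  list(keep = which(keep), class = cls)
}

#' Logistic panel classifier, Low vs VeryLikely
#'
#' Fits a maximum-likelihood logistic regression of mTBI likelihood class
#' (VeryLikely vs Low, holding out the Moderate group) on the selected
#' miRNA panel, within one biofluid or pooling both. On complete separation
#' (which a perfectly classifying panel implies) the fit falls back to a
#' small ridge penalty (1e-4) so coefficients stay finite, and the report
#' flags it. The confusion matrix and accuracies are apparent
#' (resubstitution) performance and labelled as such.
#'
#' @param delta a [DeltaExperiment-class] with design columns.
#' @param panel character vector of panel feature labels.
#' @param scope \code{"saliva"}, \code{"serum"} or \code{"combined"}.
#' @return list with \code{scope}, \code{confusion} (observed x predicted),
#'   \code{accuracy} ([accuracyFromConfusion()] output), \code{separation},
#'   \code{coefficients}, \code{n} and \code{apparent = TRUE}.
#' @export
fitLogisticPanel <- function(delta, panel,
                             scope = c("combined", "saliva", "serum")) {
  scope <- match.arg(scope)
  ss <- .classifierSamples(delta, scope)
  x <- .panelMatrix(delta, panel)[ss$keep, , drop = FALSE]
  y <- as.integer(ss$class == "VeryLikely")
  fit <- .logisticScores(x, y, x)
  predicted <- factor(ifelse(fit$scores >= 0.5, "VeryLikely", "Low"),
                      c("Low", "VeryLikely"))
  confusion <- table(observed = ss$class, predicted = predicted)
  list(scope = scope, confusion = unclass(confusion),
       accuracy = accuracyFromConfusion(confusion),
       separation = fit$separated, coefficients = fit$beta,
       n = length(y), apparent = TRUE)
}

#' Area under the ROC curve by threshold sweep
#'
#' Sweeps every distinct score as a threshold, forming the ROC polygon, and
#' integrates by the trapezoid rule; ties contribute diagonal segments, so
#' the result equals the Mann-Whitney U statistic scaled by n1 * n0.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return AUC in [0, 1].
#' @export
aucTrapezoid <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- labels[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)    # last index of each tie group
  tpr <- c(0, cumsum(yy)[keep] / sum(labels))
  fpr <- c(0, cumsum(!yy)[keep] / sum(!labels))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Monte-Carlo cross-validated AUC for the panel classifier
#'
#' Repeats stratified random train/test splits (default 75/25), fits the
#' learner on the training split, scores the held-out samples and computes
#' the ROC AUC by threshold sweep ([aucTrapezoid()]). Learners: a random
#' forest (500 trees, default feature subsampling) or the ridge-guarded
#' logistic regression. Splits whose test part would contain a single class
#' are redrawn (logged); the whole procedure is reproducible from
#' \code{seed}.
#'
#' @param delta a [DeltaExperiment-class] with design columns.
#' @param panel panel feature labels.
#' @param nIter number of Monte-Carlo iterations (default 100).
#' @param testFraction held-out fraction per iteration (default 0.25).
#' @param learner \code{"random_forest"} or \code{"logistic"}.
#' @param seed RNG seed for the splits (and forests).
#' @param scope \code{"combined"}, \code{"saliva"} or \code{"serum"}.
#' @param nTree trees per forest (default 500).
#' @return list with \code{mean_auc}, \code{sd_auc}, \code{aucs}
#'   (per-iteration), \code{learner}, \code{redraws}.
#' @export
mccvAuc <- function(delta, panel, nIter = 100L, testFraction = 0.25,
                    learner = c("random_forest", "logistic"), seed = 1L,
                    scope = "combined", nTree = 500L) {
  learner <- match.arg(learner)
  stopifnot(nIter >= 1L, testFraction > 0, testFraction < 1)
  ss <- .classifierSamples(delta, scope)
  x <- .panelMatrix(delta, panel)[ss$keep, , drop = FALSE]
  y <- ss$class == "VeryLikely"
  set.seed(seed)
  aucs <- numeric(nIter)
  redraws <- 0L
  for (it in seq_len(nIter)) {
    repeat {
      test <- c(sample(which(y), max(1L, round(testFraction * sum(y)))),
                sample(which(!y), max(1L, round(testFraction * sum(!y)))))
      if (any(y[test]) && any(!y[test]) &&
          any(y[-test]) && any(!y[-test])) break
      redraws <- redraws + 1L
    }
    scores <- if (learner == "random_forest") {
      rf <- randomForest::randomForest(x[-test, , drop = FALSE],
                                       factor(y[-test], c(FALSE, TRUE)),
                                       ntree = nTree)
      stats::predict(rf, x[test, , drop = FALSE], type = "prob")[, "TRUE"]
    } else {
      .logisticScores(x[-test, , drop = FALSE], as.integer(y[-test]),
                      x[test, , drop = FALSE])$scores
    }
    aucs[it] <- aucTrapezoid(scores, y[test])
  }
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), aucs = aucs,
       learner = learner, redraws = redraws, n = length(y))
}
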