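## orthogonal 2-factor model generator for recovery checks
.twoFactorData <- function(n = 500, seed = 50, noise = 0.4) {
  set.seed(seed)
  L <- cbind(c(0.9, 0.8, 0.7, 0.0, 0.0, 0.0),
             c(0.0, 0.0, 0.0, 0.9, 0.8, 0.7))
  f <- matrix(rnorm(n * 2), n, 2)
  x <- f %*% t(L) + matrix(rnorm(n * 6, 0, noise), n, 6)
  colnames(x) <- paste0("v", 1:6)
  list(x = x, L = L)
}

test_that("a noiseless 1-factor model is recovered up to sign", {
  set.seed(51)
  lam <- c(0.9, 0.7, 0.5, 0.8)
  f <- rnorm(2000)
  x <- outer(f, lam) + matrix(rnorm(8000, 0, 1e-6), 2000, 4)
  colnames(x) <- paste0("v", 1:4)
  sol <- principalAxisFactor(x, 1)
  got <- abs(factorLoadings(sol)[, 1])
  expect_equal(unname(got), rep(1, 4), tolerance = 0.01)
  expect_true(sol@converged)
})

test_that("a 2-factor orthogonal model is recovered within 0.05", {
  td <- .twoFactorData()
  sol <- quartimaxRotate(principalAxisFactor(td$x, 2))
  L <- factorLoadings(sol)
  ## align by best column permutation and sign; truth on the standardized
  ## scale: loading_j / sqrt(var(x_j)) with var(x_j) = sum(L_j^2) + noise^2
  trueStd <- td$L / sqrt(rowSums(td$L^2) + 0.4^2)
  perms <- list(1:2, 2:1)
  errs <- sapply(perms, function(pm) {
    Lp <- L[, pm]
    sgn <- sign(colSums(Lp * trueStd))
    max(abs(sweep(Lp, 2, sgn, "*") - trueStd))
  })
  expect_lt(min(errs), 0.05)
})

test_that("one iteration with huge tol equals the eigendecomposition oracle", {
  td <- .twoFactorData(n = 200, seed = 52)
  sol <- principalAxisFactor(td$x, 2, tol = 1e6, maxIter = 100)
  expect_identical(sol@iterations, 1L)
  ## oracle: one-step PCA on the SMC-reduced correlation matrix
  r <- cor(td$x)
  h2 <- pmin(pmax(1 - 1 / diag(solve(r)), 0.05), 0.995)
  diag(r) <- h2
  e <- eigen(r, symmetric = TRUE)
  L <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
  got <- factorLoadings(sol)
  for (j in 1:2) {
    s <- sign(sum(got[, j] * L[, j]))
    expect_equal(unname(got[, j]), s * L[, j], tolerance = 1e-10)
  }
})

test_that("quartimax angle matches an exhaustive grid search on 6x2", {
  set.seed(53)
  for (i in 1:5) {
    L <- matrix(rnorm(12), 6, 2)
    sol <- new("FactorSolution", loadings = L,
               communalities = pmin(rowSums(L^2), 1),
               varianceExplained = colSums(L^2), rotation = "none",
               iterations = 1L, converged = TRUE, heywood = character())
    rot <- quartimaxRotate(sol)
    critGot <- sum(factorLoadings(rot)^4)
    grid <- seq(-pi / 4, pi / 4, length.out = 100000)
    critGrid <- max(vapply(grid, function(th) {
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
      sum((L %*% R)^4)
    }, numeric(1)))
    expect_equal(critGot, critGrid, tolerance = 1e-4)
    expect_gte(critGot, critGrid - 1e-4)
  }
})

test_that("rotation preserves communalities and the fitted correlation", {
  td <- .twoFactorData(n = 300, seed = 54)
  sol <- principalAxisFactor(td$x, 2)
  rot <- quartimaxRotate(sol)
  expect_equal(communalities(rot), communalities(sol), tolerance = 1e-10)
  expect_equal(rowSums(factorLoadings(rot)^2),
               rowSums(factorLoadings(sol)^2), tolerance = 1e-10)
  L0 <- factorLoadings(sol); L1 <- factorLoadings(rot)
  expect_equal(L1 %*% t(L1), L0 %*% t(L0), tolerance = 1e-8)
  expect_equal(sum(communalities(rot)), sum(communalities(sol)),
               tolerance = 1e-10)
  ## 1-factor input passes through unchanged
  one <- principalAxisFactor(td$x, 1)
  expect_identical(factorLoadings(quartimaxRotate(one)),
                   factorLoadings(one))
})

test_that("variance explained is nonincreasing before rotation", {
  td <- .twoFactorData(n = 300, seed = 55)
  sol <- principalAxisFactor(td$x, 3)
  expect_true(all(diff(sol@varianceExplained) <= 1e-10))
})

test_that("loading-based grouping applies the threshold by sign", {
  L <- matrix(c(0.41, -0.39, 0.12, -0.75,
                0.05, 0.44, -0.41, 0.10), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  sol <- new("FactorSolution", loadings = L,
             communalities = pmin(rowSums(L^2), 1),
             varianceExplained = colSums(L^2), rotation = "none",
             iterations = 1L, converged = TRUE, heywood = character())
  grp <- groupByLoading(sol, 0.4)
  expect_identical(grp$Factor1$positive, "a")    # 0.41 >= 0.4 included
  expect_identical(grp$Factor1$negative, "d")    # -0.39 excluded, -0.75 in
  expect_setequal(c(grp$Factor2$positive, grp$Factor2$negative), c("b", "c"))
  empty <- groupByLoading(sol, 0.99)
  expect_identical(lengths(empty$Factor1), c(positive = 0L, negative = 0L))
})

test_that("planted molecular-functional co-loading structure is recovered", {
  hits <- vapply(1:10, function(seed) {
    coh <- simulateCohort(simConfig(nSubjects = 40, pMirnas = 60,
                                    seed = seed))
    norm <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
    d <- addCohortDesign(filterMissingness(
      suppressWarnings(baselineDelta(norm))))
    gt <- groundTruth(coh)
    asr <- names(gt$archetype)[gt$archetype == "asr"]
    joint <- TBImiR:::.jointFunctionalMatrix(d, coh, asr, "saliva")
    if (is.null(joint)) return(NA)
    sol <- quartimaxRotate(suppressWarnings(suppressMessages(
      principalAxisFactor(joint, 3))))
    L <- factorLoadings(sol)
    dominant <- apply(abs(L[asr, , drop = FALSE]), 1, which.max)
    shared <- as.integer(names(which.max(table(dominant))))
    ## majority of ASR miRNAs share one dominant factor, and the
    ## sway-sensitive measures load positively on it
    mean(dominant == shared) >= 0.75 &&
      mean(L[c("TLEC", "DSB_Bal"), shared]) > 0
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
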