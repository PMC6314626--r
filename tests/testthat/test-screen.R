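test_that("Benjamini-Hochberg equals the hand-computed step-up", {
  ## step-up by hand: q_i = min_{j >= rank(i)} m p_(j) / j, capped at 1
  bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    run <- 1
    for (j in m:1) {
      run <- min(run, m * p[o[j]] / j)
      q[o[j]] <- run
    }
    q
  }
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjaminiHochberg(c(0.5, 0.5, 0.5)), rep(0.5, 3))
  expect_equal(benjaminiHochberg(0.04), 0.04)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))^2
    expect_equal(benjaminiHochberg(p), bhOracle(p))
  }
})

test_that("BH is permutation-invariant, monotone, and bounded below by p", {
  set.seed(9)
  p <- runif(40)
  q <- benjaminiHochberg(p)
  expect_true(all(q >= p - 1e-12))
  perm <- sample(40)
  expect_equal(benjaminiHochberg(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("balanced 2x2 screen matches the matrix least-squares oracle", {
  set.seed(10)
  n <- 5                      # per cell
  A <- rep(c("Low", "VeryLikely"), each = 2 * n)
  B <- rep(rep(c("saliva", "serum"), each = n), 2)
  mu <- c(0, 0.4, 0.8, 1.9)   # cell means with a real interaction
  y <- mu[as.integer(interaction(A, B, lex.order = TRUE))] + rnorm(4 * n, 0, 0.3)
  mat <- rbind(f1 = y)
  colnames(mat) <- sprintf("s%02d", seq_along(y))
  d <- deltaFromMatrix(mat, B, rep("post_0d", length(y)),
                       ifelse(A == "Low", 0L, 12L))
  res <- screenFeatures(d, "tbi_class")

  ## oracle: explicit projections via solve() on the normal equations
  rssOf <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  a <- factor(A); b <- factor(B)
  rFull <- rssOf(model.matrix(~ a * b)); dfFull <- length(y) - 4
  rAB <- rssOf(model.matrix(~ a + b))
  rA <- rssOf(model.matrix(~ a))
  rB <- rssOf(model.matrix(~ b))
  mse <- rFull / dfFull
  pOf <- function(ss, df) pf((ss / df) / mse, df, dfFull, lower.tail = FALSE)
  expect_equal(res$p_factor, pOf(rB - rAB, 1), tolerance = 1e-8)
  expect_equal(res$p_fluid, pOf(rA - rAB, 1), tolerance = 1e-8)
  expect_equal(res$p_interaction, pOf(rAB - rFull, 1), tolerance = 1e-8)
})

test_that("unbalanced Type-II tests agree with car::Anova", {
  skip_if_not_installed("car")
  d <- smallDelta()
  res <- screenFeatures(d, "tbi_class")
  cd <- colData(d)
  y <- assay(d, "delta")
  feats <- setdiff(sample(rownames(d), 8), "hsa-miR-24-3p")
  for (f in feats) {
    ok <- !is.na(y[f, ])
    df <- data.frame(y = y[f, ok], a = factor(cd$tbi_class[ok]),
                     b = factor(cd$fluid[ok]))
    if (nlevels(droplevels(df$a)) < 2 || nlevels(droplevels(df$b)) < 2) next
    an <- car::Anova(lm(y ~ a * b, df), type = 2)
    i <- match(f, res$feature)
    expect_equal(res$p_factor[i], an[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(res$p_fluid[i], an[["Pr(>F)"]][2], tolerance = 1e-10)
    expect_equal(res$p_interaction[i], an[["Pr(>F)"]][3], tolerance = 1e-10)
  }
})

test_that("constant features yield F = 0 and p = 1, single-level factors error", {
  mat <- rbind(flat = rep(2.5, 12), ok = rnorm(12))
  colnames(mat) <- sprintf("s%02d", 1:12)
  d <- deltaFromMatrix(mat, rep(c("saliva", "serum"), 6),
                       rep("post_0d", 12), rep(c(0L, 12L), each = 6))
  res <- screenFeatures(d, "tbi_class")
  expect_equal(res$p_factor[res$feature == "flat"], 1)
  expect_equal(res$p_interaction[res$feature == "flat"], 1)
  dOne <- deltaFromMatrix(mat, rep("saliva", 12), rep("post_0d", 12),
                          rep(0L, 12))
  expect_error(screenFeatures(dOne, "tbi_class"), "screening error")
})

test_that("global-null positive rate is calibrated at alpha = 0.05", {
  ## one post sample per subject: the F test's calibration claim requires
  ## independent observations (pooling repeated samples of a subject shares
  ## the baseline and is anticonservative by design, as documented)
  coh <- simulateCohort(simConfig(nSubjects = 40, pMirnas = 200,
                                  doseSlope = 0, asrAmplitude = 0,
                                  dsrAmplitude = 0, nDose = 0L, nAsr = 0L,
                                  nDsr = 0L, dropoutFraction = 0,
                                  postProbs = c(1, 0, 0, 0), seed = 77))
  norm <- normalizeToReference(mirCounts(coh), "hsa-miR-24-3p")
  d <- addCohortDesign(suppressWarnings(baselineDelta(norm)))
  res <- screenFeatures(d, "tbi_class")
  res <- res[res$feature != "hsa-miR-24-3p", ]
  rate <- mean(res$p_factor < 0.05, na.rm = TRUE)
  m <- sum(!is.na(res$p_factor))
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / m) + 0.01)
})

test_that("the dose screen recovers planted features and controls the FDP", {
  d <- doseDelta()
  gt <- groundTruth(doseCohort())
  res <- screenFeatures(d, "tbi_class", alphaFdr = 0.15)
  arch <- gt$archetype[res$feature]
  hits <- res$significant
  expect_gte(mean(hits[arch == "dose"]), 0.80)
  falsePos <- sum(hits & arch %in% c("null", "reference"))
  expect_lte(falsePos, 0.15 * sum(hits) + 2)
})

test_that("missing cells route features to reduced designs, never dropped", {
  set.seed(12)
  mat <- matrix(rnorm(3 * 20), 3, 20,
                dimnames = list(c("f1", "f2", "f3"), sprintf("s%02d", 1:20)))
  mat["f2", 1:10] <- NA                      # loses all saliva samples
  mat["f3", c(1, 5, 12)] <- NA               # arbitrary missingness
  d <- deltaFromMatrix(mat, rep(c("saliva", "serum"), each = 10),
                       rep("post_0d", 20), rep(c(0L, 12L), 10))
  res <- screenFeatures(d, "tbi_class")
  expect_identical(nrow(res), 3L)            # reported, not silently dropped
  expect_true(is.na(res$p_fluid[res$feature == "f2"]))
  expect_identical(res$n_used[res$feature == "f3"], 17L)
  expect_false(res$reduced[res$feature == "f1"])
})
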