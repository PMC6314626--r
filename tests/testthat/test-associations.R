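test_that("Pearson correlation matches the covariance-formula oracle", {
  set.seed(40)
  mat <- matrix(rnorm(10 * 3), nrow = 3,
                dimnames = list(c("f1", "f2", "f3"), sprintf("s%02d", 1:10)))
  cov <- rnorm(10)
  d <- deltaFromMatrix(mat, rep(c("saliva", "serum"), 5),
                       rep("post_0d", 10), sample(0:20, 10, TRUE))
  res <- correlateFeatures(d, cov, scopes = "all")
  for (f in rownames(mat)) {
    x <- mat[f, ]
    rOracle <- sum((x - mean(x)) * (cov - mean(cov))) /
      sqrt(sum((x - mean(x))^2) * sum((cov - mean(cov))^2))
    expect_equal(res$r[res$feature == f], rOracle, tolerance = 1e-12)
  }
  ## p from the closed-form t transform
  i <- 1
  r <- res$r[i]; n <- res$n[i]
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p[i], 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
  ## and against cor.test
  expect_equal(res$p[i], cor.test(mat[1, ], cov)$p.value, tolerance = 1e-10)
})

test_that("exact dependence and independence give the expected extremes", {
  mat <- rbind(lin = 1:12 / 3)
  colnames(mat) <- sprintf("s%02d", 1:12)
  d <- deltaFromMatrix(mat, rep("saliva", 12), rep("post_0d", 12),
                       rep(4L, 12))
  res <- correlateFeatures(d, 1:12, scopes = "all", adjust = "none")
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)
  ## decorrelated pair: two independent draws (the TLEC / DSB_Bal situation)
  set.seed(41)
  a <- rnorm(300)
  mat2 <- rbind(x = a)
  colnames(mat2) <- sprintf("s%03d", 1:300)
  d2 <- deltaFromMatrix(mat2, rep("saliva", 300), rep("post_0d", 300),
                        rep(4L, 300))
  res2 <- correlateFeatures(d2, rnorm(300), scopes = "all", adjust = "none")
  expect_lt(abs(res2$r), 0.15)
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(42)
  mat <- rbind(f = rnorm(20))
  colnames(mat) <- sprintf("s%02d", 1:20)
  cov <- rnorm(20)
  d <- deltaFromMatrix(mat, rep("serum", 20), rep("post_0d", 20),
                       rep(4L, 20))
  d2 <- deltaFromMatrix(mat * 7 + 3, rep("serum", 20), rep("post_0d", 20),
                        rep(4L, 20))
  r1 <- correlateFeatures(d, cov, scopes = "all")$r
  r2 <- correlateFeatures(d2, 2 * cov - 5, scopes = "all")$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Bonferroni-significant is a subset of nominal-significant", {
  d <- smallDelta()
  bonf <- correlateFeatures(d, adjust = "bonferroni")
  raw <- correlateFeatures(d, adjust = "none")
  expect_true(all(raw$significant[bonf$significant]))
  expect_identical(attr(bonf, "family_size"), sum(!is.na(bonf$p)))
})

test_that("paired protein test matches the one-sample t oracle", {
  set.seed(43)
  tab <- data.frame(subject_id = 1:24, analyte = "GFAP",
                    pre = rlnorm(24, 1, 0.3))
  tab$post <- tab$pre * 1.4 * exp(rnorm(24, 0, 0.2))
  tab$pre_below_lod <- FALSE
  tab$post_below_lod <- FALSE
  res <- pairedProteinTest(tab, "GFAP")
  oracle <- t.test(tab$post - tab$pre)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  expect_equal(res$median_pct_change,
               median(100 * (tab$post - tab$pre) / tab$pre))
  ## degenerate cases
  same <- transform(tab, post = pre)
  expect_equal(pairedProteinTest(same, "GFAP")$t, 0)
  expect_equal(pairedProteinTest(same, "GFAP")$p, 1)
  doubled <- transform(tab, post = 2 * pre)
  expect_equal(pairedProteinTest(doubled, "GFAP")$median_pct_change, 100)
})

test_that("below-LOD substitution uses half the lowest measurable post", {
  tab <- data.frame(
    subject_id = 1:4, analyte = "S100B",
    pre = c(NA, NA, 60, 80), post = c(45.4, 90, 70, 100),
    pre_below_lod = c(TRUE, TRUE, FALSE, FALSE),
    post_below_lod = FALSE)
  out <- substituteBelowLod(tab, "S100B")
  expect_equal(out$pre[1:2], c(22.7, 22.7))   # 0.5 * 45.4
  expect_identical(out$pre[3:4], tab$pre[3:4])  # measurable values untouched
  expect_identical(attr(out, "n_substituted"), 2L)
  expect_true(all(out$pre_substituted[1:2]))
  ## idempotent
  again <- substituteBelowLod(out, "S100B")
  expect_identical(again$pre, out$pre)
  ## nothing below LOD -> unchanged
  clean <- transform(tab, pre = c(10, 20, 60, 80), pre_below_lod = FALSE)
  expect_identical(substituteBelowLod(clean, "S100B")$pre, clean$pre)
  ## all post below LOD -> unanalyzable
  dead <- transform(tab, post_below_lod = TRUE)
  expect_error(substituteBelowLod(dead, "S100B"), "unanalyzable")
})

test_that("protein-vs-HTH regression recovers planted slopes", {
  set.seed(44)
  hth <- sample(0:40, 24, TRUE)
  tab <- data.frame(subject_id = 1:24, analyte = "UCHL1",
                    pre = rlnorm(24, 6, 0.3), hth = hth,
                    pre_below_lod = FALSE, post_below_lod = FALSE)
  tab$post <- tab$pre + 25 * hth + rnorm(24, 0, 100)
  res <- proteinVsHthRegression(tab, "UCHL1")
  se <- summary(lm(I(tab$post - tab$pre) ~ hth))$coefficients[2, 2]
  expect_lt(abs(res$slope - 25), 2 * se)
  expect_gt(res$r_squared, 0.5)
  ## exact linearity -> r^2 = 1; permuted -> r^2 near 0
  exact <- transform(tab, post = pre + 10 * hth)
  expect_equal(
    suppressWarnings(proteinVsHthRegression(exact, "UCHL1"))$r_squared, 1)
  perm <- transform(tab, post = pre + 25 * sample(hth))
  expect_lt(proteinVsHthRegression(perm, "UCHL1")$r_squared, 0.3)
})

test_that("brain enrichment is the strict max-scan comparison", {
  atlas <- rbind(hit = c(10, 12, 9, 5, 3), miss = c(9, 9, 9, 5, 3))
  colnames(atlas) <- c("cortex", "cerebellum", "liver", "kidney", "lung")
  cns <- c("cortex", "cerebellum")
  expect_true(unname(brainEnriched(atlas, cns, "hit")))     # median 11 > 9
  expect_false(unname(brainEnriched(atlas, cns, "miss")))   # 9 > 9 is false
  ## random atlas vs exhaustive comparison oracle
  set.seed(45)
  big <- matrix(rlnorm(50 * 8), 50, 8,
                dimnames = list(sprintf("f%02d", 1:50),
                                c("c1", "c2", "c3", paste0("t", 1:5))))
  got <- brainEnriched(big, c("c1", "c2", "c3"))
  oracle <- apply(big, 1, function(v) {
    all(median(v[1:3]) > v[4:8])
  })
  expect_identical(unname(got), unname(oracle))
})
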