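.binDelta <- function() {
  ## 2 samples per (fluid, bin) with fully controlled values
  bins <- c("T1neg", "T1pos", "T2", "T3")
  tp <- c(T1neg = "post_0d", T1pos = "post_0d", T2 = "post_2_3d",
          T3 = "post_1wk")
  hth <- c(T1neg = 0L, T1pos = 12L, T2 = 12L, T3 = 12L)
  cols <- expand.grid(rep = 1:2, bin = bins, fluid = c("saliva", "serum"),
                      stringsAsFactors = FALSE)
  mat <- matrix(0, 2, nrow(cols),
                dimnames = list(c("fA", "fB"),
                                sprintf("s%02d", seq_len(nrow(cols)))))
  d <- deltaFromMatrix(mat, cols$fluid, tp[cols$bin], hth[cols$bin],
                       fought = cols$bin != "T1neg")
  list(delta = d, cols = cols)
}

.setBin <- function(bd, feature, fluid, bin, values) {
  idx <- which(bd$cols$fluid == fluid & bd$cols$bin == bin)
  assay(bd$delta, "delta")[feature, idx] <- values
  bd
}

test_that("bin profiles are group-by means with per-bin counts", {
  bd <- .binDelta()
  bd <- .setBin(bd, "fA", "saliva", "T1pos", c(0.2, 0.4))
  pr <- binProfiles(bd$delta)
  row <- pr[pr$feature == "fA" & pr$fluid == "saliva" & pr$bin == "T1_HTHpos", ]
  expect_equal(row$mean, 0.3)
  expect_identical(row$n, 2L)

  ## oracle: direct aggregation on the study cohort
  d <- smallDelta()
  pr <- binProfiles(d)
  cd <- colData(d)
  y <- assay(d, "delta")
  for (i in sample(nrow(pr), 25)) {
    cols <- which(cd$fluid == pr$fluid[i] & cd$temporal_bin == pr$bin[i])
    vals <- y[pr$feature[i], cols]
    if (all(is.na(vals))) expect_true(is.na(pr$mean[i]))
    else expect_equal(pr$mean[i], mean(vals, na.rm = TRUE))
  }
})

test_that("single-sample bins reproduce that sample's delta", {
  bd <- .binDelta()
  y <- assay(bd$delta, "delta")
  idx <- which(bd$cols$fluid == "serum" & bd$cols$bin == "T3")
  y["fB", idx] <- c(0.77, NA)
  assay(bd$delta, "delta") <- y
  pr <- binProfiles(bd$delta)
  row <- pr[pr$feature == "fB" & pr$fluid == "serum" & pr$bin == "T3_HTHpos", ]
  expect_equal(row$mean, 0.77)
  expect_identical(row$n, 1L)
})

test_that("the ASR/DSR rule reproduces its worked examples", {
  ## ASR: saliva spike over 2x control, returned to baseline by 2-3 d
  bd <- .binDelta()
  bd <- .setBin(bd, "fA", "saliva", "T1neg", c(0.05, 0.05))
  bd <- .setBin(bd, "fA", "saliva", "T1pos", c(0.60, 0.60))
  bd <- .setBin(bd, "fA", "saliva", "T2", c(0.10, 0.10))
  calls <- callPatterns(binProfiles(bd$delta))
  expect_equal(calls$label[calls$feature == "fA"], "ASR")
  expect_equal(calls$direction[calls$feature == "fA"], "up")

  ## DSR: delayed graded serum decrease absent acutely
  bd <- .binDelta()
  bd <- .setBin(bd, "fB", "serum", "T1neg", c(0, 0))
  bd <- .setBin(bd, "fB", "serum", "T1pos", c(0.05, 0.05))
  bd <- .setBin(bd, "fB", "serum", "T2", c(-0.30, -0.30))
  bd <- .setBin(bd, "fB", "serum", "T3", c(-0.60, -0.60))
  calls <- callPatterns(binProfiles(bd$delta))
  expect_equal(calls$label[calls$feature == "fB"], "DSR")
  expect_equal(calls$direction[calls$feature == "fB"], "down")

  ## control criterion: 0.60 < 2 x 0.35 fails the 2x rule
  bd <- .binDelta()
  bd <- .setBin(bd, "fA", "saliva", "T1neg", c(0.35, 0.35))
  bd <- .setBin(bd, "fA", "saliva", "T1pos", c(0.60, 0.60))
  calls <- callPatterns(binProfiles(bd$delta))
  expect_equal(calls$label[calls$feature == "fA"], "none")
  expect_false(calls$asr_over_control[calls$feature == "fA"])
})

test_that("ASR requires an increase and missing bins annul the call", {
  bd <- .binDelta()
  bd <- .setBin(bd, "fA", "saliva", "T1neg", c(0.02, 0.02))
  bd <- .setBin(bd, "fA", "saliva", "T1pos", c(-0.9, -0.9))  # decrease
  calls <- callPatterns(binProfiles(bd$delta))
  expect_equal(calls$label[calls$feature == "fA"], "none")

  ## a required bin with no samples -> none, with a recorded reason
  bd <- .binDelta()
  y <- assay(bd$delta, "delta")
  idx <- which(bd$cols$fluid == "saliva" & bd$cols$bin == "T2")
  y["fA", idx] <- NA
  assay(bd$delta, "delta") <- y
  y["fA", which(bd$cols$fluid == "saliva" & bd$cols$bin == "T1pos")] <- 0.9
  assay(bd$delta, "delta") <- y
  calls <- callPatterns(binProfiles(bd$delta))
  expect_equal(calls$label[calls$feature == "fA"], "none")
  expect_match(calls$reason[calls$feature == "fA"], "bin absent")
})

test_that("calls are order-invariant and unaffected by unused-bin samples", {
  d <- smallDelta()
  pr <- binProfiles(d)
  base <- suppressMessages(callPatterns(pr))
  perm <- d[, sample(ncol(d))]
  prP <- binProfiles(perm)
  permCalls <- suppressMessages(callPatterns(prP))
  expect_equal(base$label[order(base$feature)],
               permCalls$label[order(permCalls$feature)])
})

test_that("raising the log2 threshold never increases the number of calls", {
  d <- studyDelta()
  pr <- binProfiles(d)
  nCalls <- vapply(c(0.1, 0.28, 0.5, 0.9), function(th)
    sum(suppressMessages(callPatterns(pr, minLog2 = th))$label != "none"),
    numeric(1))
  expect_true(all(diff(nCalls) <= 0))
})

test_that("the detector meets the planted sensitivity and FPR", {
  ## study conditions: amplitudes 1.0, >= 10 samples per assigned bin
  d <- studyDelta()
  cd <- colData(d)
  tab <- table(cd$fluid, cd$temporal_bin)[, 1:4]
  expect_true(all(tab >= 10))
  st <- screenFeatures(d, "temporal_bin")
  calls <- suppressMessages(
    callPatterns(binProfiles(d), st$feature[st$significant]))
  gt <- groundTruth(studyCohort())
  arch <- gt$archetype
  called <- setNames(rep("none", length(arch)), names(arch))
  called[calls$feature] <- calls$label
  sens <- mean(c(called[names(arch)[arch == "asr"]] == "ASR",
                 called[names(arch)[arch == "dsr"]] == "DSR"))
  fpr <- mean(called[names(arch)[arch %in% c("null", "reference")]] != "none")
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})
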