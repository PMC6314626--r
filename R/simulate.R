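#' Build a synthetic-cohort configuration
#'
#' Returns a validated [SimConfig-class] describing the cohort the generator
#' emulates: amateur fighters sampled at one or two pre-fight baselines and a
#' random subset of four post-fight timepoints, in two biofluids, with
#' video-counted hits to the head (HTH) concentrated near zero, in a 4-9
#' mid range, and in a heavy 10+ tail. Planted miRNA archetypes are
#' \emph{dose} (log2 change proportional to HTH), \emph{asr} (acute saliva
#' spike at the <= 1 h timepoint, gone by 2-3 days, with a delayed serum
#' decrease in a subset), \emph{dsr} (serum ramp peaking at 1 week, either
#' sign, absent acutely) and \emph{null}; one invariant reference miRNA has
#' zero biological effect by construction.
#'
#' @param nSubjects subjects in the cohort (default 50).
#' @param pMirnas miRNA features including the reference (default 300).
#' @param referenceId reference miRNA label (default "hsa-miR-24-3p").
#' @param controlFraction fraction of subjects who attend but do not fight.
#' @param hthClassProbs Low/Moderate/VeryLikely mixing weights for fighters.
#' @param nDose,nAsr,nDsr planted feature counts (defaults 20, 12, 13; the
#'   acute/delayed counts mirror the 12 acute-saliva and 13 delayed-serum
#'   patterns a cohort of this design yields).
#' @param doseSlope log2 change per hit for dose features (default 0.05).
#' @param asrAmplitude,dsrAmplitude planted log2 amplitudes (default 1.0).
#' @param dispersion total NB overdispersion (default 0.2).
#' @param subjectIcc persistent subject-level share of the overdispersion
#'   (default 0.7); the visit-level remainder is what survives baseline
#'   differencing.
#' @param librarySizeRange per-sample reads, drawn uniformly (default
#'   1e5-5e5).
#' @param learningRate per-session improvement in learning-prone tasks
#'   (default 0.15 score units).
#' @param noiseSdFunctional residual functional-score noise SD (default 1).
#' @param dropoutFraction fraction of count cells reported NA (default 0.05).
#' @param postProbs probabilities of contributing each post timepoint
#'   (post_0d, post_2_3d, post_1wk, post_3wk).
#' @param eventEffect nonspecific day-of-event log2 change for all attendees
#'   (default 0 = uncontaminated controls).
#' @param seed master seed (default 1).
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 10, pMirnas = 40, seed = 7)
#' @export
simConfig <- function(nSubjects = 50L, pMirnas = 300L,
                      referenceId = "hsa-miR-24-3p",
                      controlFraction = 0.15,
                      hthClassProbs = c(1, 1, 1) / 3,
                      nDose = 20L, nAsr = 12L, nDsr = 13L,
                      doseSlope = 0.05,
                      asrAmplitude = 1.0, dsrAmplitude = 1.0,
                      dispersion = 0.2, subjectIcc = 0.7,
                      librarySizeRange = c(1e5, 5e5),
                      learningRate = 0.15, noiseSdFunctional = 1.0,
                      dropoutFraction = 0.05,
                      postProbs = c(post_0d = 1, post_2_3d = 0.8,
                                    post_1wk = 0.8, post_3wk = 0.15),
                      eventEffect = 0,
                      seed = 1L) {
  asInt <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      stop("configuration error: '", what,
           "' must be a single nonnegative integer", call. = FALSE)
    as.integer(x)
  }
  new("SimConfig",
      nSubjects = asInt(nSubjects, "nSubjects"),
      pMirnas = asInt(pMirnas, "pMirnas"),
      referenceId = as.character(referenceId),
      controlFraction = controlFraction,
      hthClassProbs = hthClassProbs / sum(hthClassProbs),
      nDose = asInt(nDose, "nDose"), nAsr = asInt(nAsr, "nAsr"),
      nDsr = asInt(nDsr, "nDsr"),
      doseSlope = doseSlope, asrAmplitude = asrAmplitude,
      dsrAmplitude = dsrAmplitude,
      dispersion = dispersion, subjectIcc = subjectIcc,
      librarySizeRange = as.numeric(librarySizeRange),
      learningRate = learningRate, noiseSdFunctional = noiseSdFunctional,
      dropoutFraction = dropoutFraction,
      postProbs = as.numeric(postProbs),
      eventEffect = eventEffect,
      seed = asInt(seed, "seed"))
}

# HTH draw for one fighter given a class index (1 Low, 2 Moderate, 3 VeryLikely)
.drawHth <- function(cls) {
  switch(cls,
         sample(0:3, 1L, prob = c(0.80, 0.12, 0.05, 0.03)),
         sample(4:9, 1L),
         min(65L, 10L + stats::rgeom(1L, 1 / 15.2)))
}

.LEARNING_TASKS <- c("TLEOFP", "TSEO", "TMB_Cog")
.SWAY_SENSITIVE <- c("TLEC", "DSB_Bal")

.PROTEIN_PANEL <- data.frame(
  analyte = c("UCHL1", "MBP", "GFAP", "BDNF", "CCL2", "CRP", "ICAM1",
              "IL6", "NSE2", "S100B", "VCAM"),
  lod = c(78.125, 15.6, 0.312, 0.32, 9.9, 116, 140, 87.9, 1.7, 4.34, 238),
  preMeanLog = log(c(900, 300, 1.8, 20, 120, 900, 250, 20, 9, 2.2, 700)),
  preSdLog = c(0.4, 0.5, 0.4, 0.5, 0.4, 0.6, 0.3, 0.5, 0.5, 0.5, 0.3),
  foldShift = c(1.00, 1.65, 1.35, 1.00, 1.00, 1.00, 1.00, 1.00, 1.50,
                8.50, 1.00),
  stringsAsFactors = FALSE)

#' Simulate a complete synthetic cohort
#'
#' Draws a full study data set from a [SimConfig-class]: negative-binomial
#' miRNA counts for saliva and serum with planted dose / acute-saliva /
#' delayed-serum effects injected on the log2 mean scale, sample metadata,
#' functional difference scores with severity and learning components, a
#' serum protein panel (one HTH-linear analyte, several HTH-independent
#' post-fight shifts, one analyte below LOD pre-fight, one unanalyzable
#' analyte), a tissue expression atlas with planted brain-enriched features,
#' and the generating ground truth. The master seed fully determines the
#' output.
#'
#' Counts are drawn as NB(mu, size = 1/phi_visit) around subject- and
#' fluid-specific means; phi_visit = dispersion * (1 - subjectIcc) is the
#' visit-level overdispersion, the persistent remainder being a lognormal
#' subject x feature effect that cancels in within-subject baseline
#' differences. Acute/delayed effect magnitudes are modulated by a latent
#' per-subject severity shared with the sway-sensitive functional measures,
#' so molecular and functional responses co-vary.
#'
#' @param config a [SimConfig-class], e.g. from [simConfig()].
#' @return a [MirCohort-class].
#' @examples
#' coh <- simulateCohort(simConfig(nSubjects = 8, pMirnas = 30, seed = 3))
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  n <- config@nSubjects
  p <- config@pMirnas
  subjects <- sprintf("S%03d", seq_len(n))

  ## --- subjects: participation, dose, latent severity -------------------
  fought <- stats::runif(n) >= config@controlFraction
  cls <- sample(3L, n, replace = TRUE, prob = config@hthClassProbs)
  hth <- integer(n)
  hth[fought] <- vapply(cls[fought], .drawHth, integer(1))
  sev <- pmax(0, log1p(hth) / log1p(25) + stats::rnorm(n, 0, 0.15))
  ampMod <- 0.7 + 0.5 * sev            # acute/delayed amplitude modulation

  ## --- features ---------------------------------------------------------
  features <- sprintf("mir-%04d", seq_len(p))
  refIdx <- 1L
  features[refIdx] <- config@referenceId
  nPlant <- c(dose = config@nDose, asr = config@nAsr, dsr = config@nDsr)
  archetype <- rep("null", p)
  archetype[refIdx] <- "reference"
  pool <- setdiff(seq_len(p), refIdx)
  planted <- if (sum(nPlant) > 0) pool[seq_len(sum(nPlant))] else integer()
  archetype[planted] <- rep(names(nPlant), nPlant)
  names(archetype) <- features

  doseSign <- ifelse(stats::runif(p) < 0.5, 1, -1)
  dsrSign <- ifelse(stats::runif(p) < 0.5, 1, -1)
  serumDip <- stats::runif(p) < 0.5    # ASR features with delayed serum dip

  effectSize <- numeric(p)
  effectSize[archetype == "dose"] <- (doseSign * config@doseSlope)[archetype == "dose"]
  effectSize[archetype == "asr"] <- config@asrAmplitude
  effectSize[archetype == "dsr"] <- (dsrSign * config@dsrAmplitude)[archetype == "dsr"]
  names(effectSize) <- features

  abundance <- stats::rlnorm(p, meanlog = log(200), sdlog = 1)
  ## planted archetypes emulate reliably-quantified miRNAs (the temporal
  ## and dose patterns were observed among well-measured features); null
  ## features keep the full abundance spectrum
  abundance[planted] <- stats::rlnorm(length(planted), log(500), 0.8)
  abundance[refIdx] <- 1e4             # high-abundance invariant reference
  serumOffset <- stats::rnorm(p, 0, 0.8)  # per-feature log2 fluid offset
  serumOffset[refIdx] <- 0

  sdSubj <- sqrt(config@subjectIcc * config@dispersion) / log(2)
  subjEff <- matrix(stats::rnorm(n * p, 0, sdSubj), n, p,
                    dimnames = list(subjects, features))
  subjEff[, refIdx] <- 0
  phiVisit <- config@dispersion * (1 - config@subjectIcc)

  ## --- sampling design --------------------------------------------------
  basePre <- ifelse(stats::runif(n) < 0.7, "pre_0d", "pre_1wk")
  bothPre <- stats::runif(n) < 0.15
  tpList <- lapply(seq_len(n), function(i) {
    pre <- if (bothPre[i]) .PRE_TIMEPOINTS else basePre[i]
    post <- .POST_TIMEPOINTS[stats::runif(4) < config@postProbs]
    c(pre, post)
  })
  meta <- do.call(rbind, lapply(seq_len(n), function(i) {
    expand.grid(subject_id = subjects[i], fluid = .FLUIDS,
                timepoint = tpList[[i]], stringsAsFactors = FALSE)
  }))
  meta$hth <- hth[match(meta$subject_id, subjects)]
  meta$fought <- fought[match(meta$subject_id, subjects)]
  meta$sample_id <- sprintf("%s_%s_%s", meta$subject_id, meta$fluid,
                            meta$timepoint)
  rownames(meta) <- meta$sample_id
  m <- nrow(meta)

  ## --- planted log2 effects per feature x sample ------------------------
  eff <- matrix(0, p, m, dimnames = list(features, meta$sample_id))
  isPost <- meta$timepoint %in% .POST_TIMEPOINTS
  subjIx <- match(meta$subject_id, subjects)
  hthPos <- meta$fought & meta$hth >= 2L

  doseIdx <- which(archetype == "dose")
  if (length(doseIdx)) {
    cols <- which(isPost)
    eff[doseIdx, cols] <- outer(doseSign[doseIdx] * config@doseSlope,
                                meta$hth[cols])
  }
  asrIdx <- which(archetype == "asr")
  if (length(asrIdx)) {
    acute <- which(isPost & hthPos & meta$fluid == "saliva" &
                   meta$timepoint == "post_0d")
    eff[asrIdx, acute] <- eff[asrIdx, acute] +
      rep(config@asrAmplitude, length(asrIdx)) %o% ampMod[subjIx[acute]]
    dipW <- c(post_0d = 0, post_2_3d = 0.4, post_1wk = 0.5, post_3wk = 0)
    dip <- which(isPost & hthPos & meta$fluid == "serum")
    dipFeat <- asrIdx[serumDip[asrIdx]]
    if (length(dipFeat) && length(dip))
      eff[dipFeat, dip] <- eff[dipFeat, dip] -
        config@asrAmplitude *
          outer(rep(1, length(dipFeat)),
                dipW[meta$timepoint[dip]] * ampMod[subjIx[dip]])
  }
  dsrIdx <- which(archetype == "dsr")
  if (length(dsrIdx)) {
    rampW <- c(post_0d = 0, post_2_3d = 0.5, post_1wk = 1, post_3wk = 0)
    ramp <- which(isPost & hthPos & meta$fluid == "serum")
    if (length(ramp))
      eff[dsrIdx, ramp] <- eff[dsrIdx, ramp] +
        (dsrSign[dsrIdx] * config@dsrAmplitude) %o%
          (rampW[meta$timepoint[ramp]] * ampMod[subjIx[ramp]])
  }
  if (config@eventEffect != 0) {     # nonspecific day-of-event contamination
    ev <- which(meta$timepoint == "post_0d")
    eff[asrIdx, ev] <- eff[asrIdx, ev] + config@eventEffect
  }

  ## --- counts -----------------------------------------------------------
  libSize <- stats::runif(m, config@librarySizeRange[1],
                          config@librarySizeRange[2])
  log2mu <- log2(abundance) + t(subjEff)[, subjIx, drop = FALSE] + eff +
    serumOffset %o% as.numeric(meta$fluid == "serum")
  mu <- 2^log2mu * rep(libSize / 3e5, each = p)
  counts <- matrix(
    if (phiVisit > 0) stats::rnbinom(p * m, mu = mu, size = 1 / phiVisit)
    else stats::rpois(p * m, mu),
    p, m, dimnames = dimnames(eff))
  ## the reference is invariant by construction: technical noise only
  counts[refIdx, ] <- stats::rpois(m, mu[refIdx, ])
  counts[refIdx, ] <- pmax(counts[refIdx, ], 1L)
  if (config@dropoutFraction > 0) {
    drop <- matrix(stats::runif(p * m) < config@dropoutFraction, p, m)
    drop[refIdx, ] <- FALSE
    counts[drop] <- NA
  }
  storage.mode(counts) <- "integer"

  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(meta[, c("sample_id", "subject_id", "fluid",
                                 "timepoint", "hth", "fought")],
                        row.names = meta$sample_id))

  ## --- functional difference scores ------------------------------------
  fun <- do.call(rbind, lapply(seq_len(n), function(i) {
    posts <- intersect(.POST_TIMEPOINTS, tpList[[i]])
    if (!length(posts)) return(NULL)
    data.frame(subject_id = subjects[i], timepoint = posts,
               session = seq_along(posts), stringsAsFactors = FALSE)
  }))
  sevW <- c(post_0d = 1, post_2_3d = 0.6, post_1wk = 0.3, post_3wk = 0)
  scores <- matrix(stats::rnorm(nrow(fun) * length(FUNCTIONAL_MEASURES),
                                0, config@noiseSdFunctional),
                   nrow(fun), length(FUNCTIONAL_MEASURES),
                   dimnames = list(NULL, FUNCTIONAL_MEASURES))
  sFun <- sev[match(fun$subject_id, subjects)]
  for (mm in .SWAY_SENSITIVE)
    scores[, mm] <- scores[, mm] + 1.2 * sFun * sevW[fun$timepoint]
  scores[, "TMB_Dual_Bal"] <- scores[, "TMB_Dual_Bal"] +
    0.6 * sFun * sevW[fun$timepoint]
  acute <- fun$timepoint == "post_0d"
  scores[acute, "TMA_Cog"] <- scores[acute, "TMA_Cog"] + 0.8 * sFun[acute]
  for (mm in .LEARNING_TASKS)
    scores[, mm] <- scores[, mm] - config@learningRate * fun$session
  for (mm in c("DSB_Bal", "DSB_Cog"))                 # headphone tasks
    scores[stats::runif(nrow(fun)) < 0.12, mm] <- NA
  functional <- cbind(fun[, c("subject_id", "timepoint")],
                      as.data.frame(scores))

  ## --- protein panel ----------------------------------------------------
  protSubj <- subjects[order(!fought)][seq_len(min(24L, n))]
  prot <- do.call(rbind, lapply(seq_len(nrow(.PROTEIN_PANEL)), function(a) {
    pp <- .PROTEIN_PANEL[a, ]
    pre <- stats::rlnorm(length(protSubj), pp$preMeanLog, pp$preSdLog)
    hthP <- hth[match(protSubj, subjects)]
    post <- if (pp$analyte == "UCHL1") {
      pre + 25 * hthP + stats::rnorm(length(protSubj), 0, 250)
    } else {
      pre * pp$foldShift * exp(stats::rnorm(length(protSubj), 0, 0.25))
    }
    post <- pmax(post, 0.01)
    data.frame(subject_id = protSubj, analyte = pp$analyte, pre = pre,
               post = post, lod = pp$lod, hth = hthP,
               stringsAsFactors = FALSE)
  }))
  prot$pre_below_lod <- prot$pre < prot$lod
  prot$post_below_lod <- prot$post < prot$lod
  prot$pre[prot$pre_below_lod] <- NA
  prot$post[prot$post_below_lod] <- NA
  rownames(prot) <- NULL

  ## --- tissue atlas -----------------------------------------------------
  cns <- c("frontal_cortex", "cerebellum", "brainstem", "hippocampus",
           "spinal_cord")
  nonCns <- c("liver", "kidney", "lung", "heart", "spleen", "muscle",
              "skin", "tonsil", "uterus", "adipose")
  atlas <- matrix(stats::rlnorm(p * 15, log(20), 1), p, 15,
                  dimnames = list(features, c(cns, nonCns)))
  enrichPool <- c(asrIdx[seq_len(min(4L, length(asrIdx)))],
                  doseIdx[seq_len(min(2L, length(doseIdx)))])
  for (i in enrichPool)
    atlas[i, cns] <- max(atlas[i, nonCns]) * stats::runif(length(cns), 2, 6)

  truth <- list(archetype = archetype, effectSize = effectSize,
                hth = stats::setNames(hth, subjects),
                fought = stats::setNames(fought, subjects),
                severity = stats::setNames(sev, subjects),
                serumDip = stats::setNames(serumDip & archetype == "asr",
                                           features),
                brainEnriched = features[enrichPool],
                config = config)

  new("MirCohort", counts = se, functionalScores = functional,
      proteins = prot, tissueAtlas = atlas, cnsSources = cns,
      groundTruth = truth)
}

#' Write a simulated cohort as standard pipeline input files
#'
#' Writes \code{counts.saliva.tsv} and \code{counts.serum.tsv} (features x
#' samples, integer counts, NA = not detected), \code{samples.tsv},
#' \code{functional.tsv}, \code{proteins.tsv}, \code{tissue_atlas.tsv}
#' (last column \code{is_cns} flagging CNS sources transposed as a header
#' comment) and \code{truth.yaml}.
#'
#' @param cohort a [MirCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cd <- as.data.frame(sampleMeta(cohort))
  cnt <- assay(mirCounts(cohort), "counts")
  files <- character()
  for (fl in .FLUIDS) {
    sub <- cnt[, cd$fluid == fl, drop = FALSE]
    f <- file.path(dir, paste0("counts.", fl, ".tsv"))
    utils::write.table(data.frame(feature = rownames(sub), sub,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  tab <- list(samples = cd, functional = functionalScores(cohort),
              proteins = proteinTable(cohort))
  for (nm in names(tab)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  atl <- data.frame(feature = rownames(tissueAtlas(cohort)),
                    tissueAtlas(cohort), check.names = FALSE)
  f <- file.path(dir, "tissue_atlas.tsv")
  cat(sprintf("# cns_sources: %s\n",
              paste(cnsSources(cohort), collapse = ",")), file = f)
  suppressWarnings(utils::write.table(atl, f, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  files <- c(files, f)
  gt <- groundTruth(cohort)
  gt$config <- NULL                    # S4 objects do not serialize to YAML
  f <- file.path(dir, "truth.yaml")
  yaml::write_yaml(lapply(gt, function(x) as.list(x)), f)
  invisible(c(files, f))
}
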