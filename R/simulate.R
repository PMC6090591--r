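# Synthetic brood-swap experiments with known ground truth. The generator
# emulates the two-transition design: per transition, controls coded time 0
# with 4 replicates and treatment time points 12/24/48/96 h with 8 replicates
# each, colony batch effects, per-sample library-size factors, negative
# binomial counts (variance mu + alpha * mu^2) around planted piecewise-
# linear log2 trajectories, and optionally 6-h samples carrying a shared
# disturbance shock for exercising the outlier screen.

# Planted per-transition "phase position" anchors on the 0..96 h design grid:
# 1 = reproductive state, 0 = brood-care state. With timing asymmetry the RB
# transition places its largest change in the first or second interval and
# the BR transition in the last; without it, both progress linearly.
.phaseAnchors <- function(transition, asymmetric, variant = 1L) {
  t0 <- c(0, 12, 24, 48, 96)
  y <- if (asymmetric) {
    if (transition == "RB") {
      if (variant == 1L) c(1, 0.70, 0.45, 0.25, 0.05)
      else               c(1, 0.90, 0.55, 0.30, 0.05)
    } else {
      if (variant == 1L) c(0, 0.02, 0.05, 0.15, 0.90)
      else               c(0, 0.05, 0.10, 0.30, 0.95)
    }
  } else {
    if (transition == "RB") c(1, 0.75, 0.5, 0.25, 0) else c(0, 0.25, 0.5, 0.75, 1)
  }
  list(t = t0, y = y)
}

.phaseAt <- function(times, transition, asymmetric, variant = 1L) {
  a <- .phaseAnchors(transition, asymmetric, variant)
  stats::approx(a$t, a$y, xout = times, rule = 2)$y
}

#' Specification of a synthetic brood-swap experiment
#'
#' Defaults reproduce the study design: two transitions, 4 control replicates
#' coded time 0, 8 replicates at each of 12/24/48/96 h, 8 colonies, negative
#' binomial dispersions drawn uniformly from `dispersionRange`, multiplicative
#' log-normal colony batch effects and library-size factors, a fraction
#' `fracInteractionDegs` of genes with planted transition-specific
#' trajectories of magnitude `effectSizeLog2`, and asymmetric timing (early
#' changes in RB, late changes in BR).
#'
#' @param nGenes number of genes.
#' @param nClustersPerTransition planted co-expression clusters per transition.
#' @param timePoints design times in hours, strictly increasing from 0.
#' @param nControlReps control replicates (time 0).
#' @param nRepsPerTimepoint replicates per non-zero time point.
#' @param nColonies colonies (batch levels).
#' @param dispersionRange range of per-gene NB dispersions alpha.
#' @param colonyEffectSd log-scale sd of gene x colony batch effects.
#' @param sizeFactorSd log-scale sd of per-sample library-size factors.
#' @param fracInteractionDegs fraction of genes with transition-specific
#'   trajectories.
#' @param effectSizeLog2 magnitude (log2 units) of planted trajectory changes.
#' @param timingAsymmetry logical; early RB / late BR changes when TRUE.
#' @param add6h add 6-h samples (4 replicates per transition) carrying a
#'   shared disturbance shock in 10 percent of genes.
#' @param seed RNG seed.
#' @return validated list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nGenes = 2000L, nClustersPerTransition = 6L,
                           timePoints = c(0, 12, 24, 48, 96),
                           nControlReps = 4L, nRepsPerTimepoint = 8L,
                           nColonies = 8L, dispersionRange = c(0.01, 0.2),
                           colonyEffectSd = 0.15, sizeFactorSd = 0.15,
                           fracInteractionDegs = 0.1, effectSizeLog2 = 2,
                           timingAsymmetry = TRUE, add6h = FALSE, seed = 1L) {
  spec <- list(nGenes = as.integer(nGenes),
               nClustersPerTransition = as.integer(nClustersPerTransition),
               timePoints = timePoints, nControlReps = as.integer(nControlReps),
               nRepsPerTimepoint = as.integer(nRepsPerTimepoint),
               nColonies = as.integer(nColonies),
               dispersionRange = dispersionRange,
               colonyEffectSd = colonyEffectSd, sizeFactorSd = sizeFactorSd,
               fracInteractionDegs = fracInteractionDegs,
               effectSizeLog2 = effectSizeLog2,
               timingAsymmetry = isTRUE(timingAsymmetry),
               add6h = isTRUE(add6h), seed = as.integer(seed))
  with(spec, {
    if (nGenes < 1L || nClustersPerTransition < 1L || nControlReps < 1L ||
        nRepsPerTimepoint < 1L || nColonies < 1L)
      stop("all design counts must be >= 1")
    if (fracInteractionDegs < 0 || fracInteractionDegs > 1)
      stop("fracInteractionDegs must lie in [0, 1]")
    if (timePoints[1L] != 0 || any(diff(timePoints) <= 0))
      stop("timePoints must be strictly increasing and begin at 0")
    if (any(dispersionRange <= 0)) stop("dispersions must be positive")
  })
  class(spec) <- "SimulationSpec"
  spec
}

.sampleSheet <- function(spec) {
  rows <- list()
  for (tr in VALID_TRANSITIONS) {
    rows[[length(rows) + 1L]] <- data.frame(
      transition = tr, time_h = 0,
      replicate = seq_len(spec$nControlReps),
      colony_id = paste0("col", ((seq_len(spec$nControlReps) - 1L) %%
                                   spec$nColonies) + 1L))
    tts <- setdiff(spec$timePoints, 0)
    if (spec$add6h) tts <- sort(c(6, tts))
    for (t0 in tts) {
      nrep <- if (t0 == 6) min(4L, spec$nRepsPerTimepoint)
              else spec$nRepsPerTimepoint
      rows[[length(rows) + 1L]] <- data.frame(
        transition = tr, time_h = t0, replicate = seq_len(nrep),
        colony_id = paste0("col", ((seq_len(nrep) - 1L) %% spec$nColonies) + 1L))
    }
  }
  sheet <- do.call(rbind, rows)
  sheet$lineage_id <- ifelse(
    as.integer(sub("col", "", sheet$colony_id)) <= spec$nColonies / 2,
    "MLL1", "MLL4")
  sheet$sample_id <- sprintf("%s_%03dh_r%d", sheet$transition, sheet$time_h,
                             sheet$replicate)
  rownames(sheet) <- sheet$sample_id
  sheet[, c("sample_id", "transition", "time_h", "colony_id", "lineage_id",
            "replicate")]
}

#' Simulate a brood-swap time-course experiment
#'
#' Draws a count matrix and metadata per the design in `spec`, with ground
#' truth for every downstream stage: planted per-transition cluster labels
#' and mean trajectories, interaction-DEG flags, per-sample phase positions,
#' colony effects, size factors and dispersions.
#'
#' @param spec a [simulationSpec()].
#' @return list with `experiment` (a [PhaseExperiment-class]) and `truth`.
#' @export
simulateExperiment <- function(spec = simulationSpec()) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  sheet <- .sampleSheet(spec)
  genes <- sprintf("gene%05d", seq_len(spec$nGenes))
  K <- spec$nClustersPerTransition

  baseline <- runif(spec$nGenes, 3, 10)
  alpha <- runif(spec$nGenes, spec$dispersionRange[1L], spec$dispersionRange[2L])
  nDeg <- round(spec$fracInteractionDegs * spec$nGenes)
  isDeg <- setNames(rep(FALSE, spec$nGenes), genes)
  if (nDeg > 0) isDeg[sample.int(spec$nGenes, nDeg)] <- TRUE

  # cluster shapes: direction alternates and the shape variant alternates so
  # the largest planted change sits in the first or second interval (RB) and
  # the last interval (BR); every planted trajectory spans effectSizeLog2
  # log2 units. Each interaction DEG is dynamic in exactly one transition
  # (its cluster's curve) and flat in the other: a transition-specific
  # expression change.
  dirs <- rep_len(c(1, -1), K)
  variants <- rep_len(c(1L, 2L), K)
  dynTransition <- setNames(rep(NA_character_, spec$nGenes), genes)
  if (nDeg > 0)
    dynTransition[isDeg] <- sample(VALID_TRANSITIONS, nDeg, replace = TRUE)

  labels <- list()
  trajLog2 <- list()
  tps <- sort(unique(sheet$time_h))
  for (tr in VALID_TRANSITIONS) {
    lab <- setNames(integer(spec$nGenes), genes)   # 0 = flat background
    dyn <- which(!is.na(dynTransition) & dynTransition == tr)
    if (length(dyn)) lab[dyn] <- sample.int(K, length(dyn), replace = TRUE)
    labels[[tr]] <- lab
    phase <- vapply(seq_len(K), function(k)
      .phaseAt(tps, tr, spec$timingAsymmetry, variants[k]), numeric(length(tps)))
    traj <- matrix(baseline, spec$nGenes, length(tps),
                   dimnames = list(genes, tps))
    for (k in seq_len(K)) {
      gk <- which(lab == k)
      if (length(gk))
        traj[gk, ] <- traj[gk, ] + rep(spec$effectSizeLog2 * dirs[k],
                                       length(gk)) %o% phase[, k]
    }
    trajLog2[[tr]] <- traj
  }

  # disturbance shock at 6 h, shared across transitions and genes
  shockGenes <- character(0)
  if (spec$add6h && 6 %in% tps) {
    shockGenes <- sample(genes, max(1L, round(0.1 * spec$nGenes)))
    shock <- sample(c(-2, 2), length(shockGenes), replace = TRUE)
    for (tr in VALID_TRANSITIONS)
      trajLog2[[tr]][shockGenes, as.character(6)] <-
        trajLog2[[tr]][shockGenes, as.character(6)] + shock
  }

  colEff <- matrix(
    exp(rnorm(spec$nGenes * spec$nColonies, -spec$colonyEffectSd^2 / 2,
              spec$colonyEffectSd)),
    spec$nGenes, spec$nColonies,
    dimnames = list(genes, paste0("col", seq_len(spec$nColonies))))
  sf <- setNames(exp(rnorm(nrow(sheet), -spec$sizeFactorSd^2 / 2,
                           spec$sizeFactorSd)), sheet$sample_id)

  cts <- matrix(0L, spec$nGenes, nrow(sheet),
                dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    tr <- sheet$transition[j]
    mu <- 2^trajLog2[[tr]][, as.character(sheet$time_h[j])] *
      colEff[, sheet$colony_id[j]] * sf[j]
    cts[, j] <- rnbinom(spec$nGenes, mu = mu, size = 1 / alpha)
  }

  phasePos <- setNames(vapply(seq_len(nrow(sheet)), function(j)
    .phaseAt(sheet$time_h[j], sheet$transition[j], spec$timingAsymmetry, 1L),
    numeric(1)), sheet$sample_id)

  truth <- list(genes = genes, isDeg = isDeg,
                clusterRB = labels$RB, clusterBR = labels$BR,
                trajLog2RB = trajLog2$RB, trajLog2BR = trajLog2$BR,
                dynTransition = dynTransition, clusterDirections = dirs,
                phasePosition = phasePos, colonyEffects = colEff,
                sizeFactors = sf, dispersion = setNames(alpha, genes),
                shockGenes = shockGenes, spec = spec)
  list(experiment = PhaseExperiment(cts, sheet), truth = truth)
}

#' Simulate ovary activation scores from planted phase positions
#'
#' Scores are `4 * phasePosition + noise`, clipped to \[0, 4\]: a monotone
#' map of the planted reproductive state (0 = no ovary activation, 4 = fully
#' developed eggs), so reproductive-phase controls receive the maximum score
#' when `noiseSd = 0`.
#'
#' @param truth ground-truth list from [simulateExperiment()].
#' @param noiseSd Gaussian noise sd on the score scale (default 0.3).
#' @param seed RNG seed.
#' @return named numeric vector of scores per sample.
#' @export
simulateOvaryScores <- function(truth, noiseSd = 0.3, seed = 1L) {
  set.seed(seed)
  sc <- 4 * truth$phasePosition + rnorm(length(truth$phasePosition), 0, noiseSd)
  pmin(pmax(sc, 0), 4)
}

#' Simulate promoter sequences with planted motif sites
#'
#' Background sequences are i.i.d. uniform over A/C/G/T; each gene in
#' `siteGenes` receives one embedded copy of the motif's maximum-probability
#' word at a uniformly random position.
#'
#' @param genes gene identifiers (one promoter each).
#' @param pwm a [PositionWeightMatrix-class].
#' @param siteGenes genes that carry a planted site (subset of `genes`).
#' @param length promoter length in bases (must be >= the motif length).
#' @param seed RNG seed.
#' @return named [Biostrings::DNAStringSet].
#' @export
simulatePromoters <- function(genes, pwm, siteGenes = character(0),
                              length = 500L, seed = 1L) {
  w <- ncol(pwmProbs(pwm))
  if (length < w) stop("promoter length must be at least the motif length")
  stopifnot(all(siteGenes %in% genes))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- paste(bases[apply(pwmProbs(pwm), 2, which.max)], collapse = "")
  seqs <- vapply(genes, function(g) {
    s <- sample(bases, length, replace = TRUE)
    if (g %in% siteGenes) {
      at <- sample.int(length - w + 1L, 1L)
      s[at:(at + w - 1L)] <- strsplit(consensus, "")[[1L]]
    }
    paste(s, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, genes))
}
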