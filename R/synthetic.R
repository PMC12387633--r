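## Seeded synthetic four-block studies emulating a four-condition (CG glass,
## CPT polystyrene, CPDMS PDMS-coated, CP planktonic) diatom culture design:
## 5 replicates per condition, three LC/GC-MS intensity blocks with
## log-normal baselines and zero inflation, and a binned 1H NMR block built
## from Lorentzian peaks.  Group structure is planted along three contrasts
## (CP vs rest, CG vs rest, CPT vs CPDMS) so the downstream model, selection
## and direction-assignment stages can be checked against ground truth.

.CONTRASTS <- list(
  C1 = list(up = "CP", down = c("CG", "CPT", "CPDMS")),
  C2 = list(up = "CG", down = c("CPT", "CPDMS", "CP")),
  C3 = list(up = "CPT", down = "CPDMS"))

## masked-bin positions for an arbitrary uniform binning of 0.2-9.0 ppm
.nmrMaskedBins <- function(nbins, spec) {
  w <- spec$binWidth
  starts <- spec$ppmRange[1] + (seq_len(nbins) - 1L) * w
  eps <- w * 1e-6
  masked <- rep(FALSE, nbins)
  for (ex in spec$exclude)
    masked <- masked | (starts >= ex[1] - eps & (starts + w) <= ex[2] + eps)
  masked
}

## disjoint planted variable sets: MS blocks use contiguous leading index
## ranges; NMR plants sit on evenly spaced unmasked bins in the middle of
## the spectrum, with alternating +/- effect signs so "increased in" is
## exercised both ways
.defaultPlantedSets <- function(blockDims, plantedCounts, effectSize, nmrSpec) {
  sets <- list()
  nbins <- blockDims[["X4"]]
  masked <- .nmrMaskedBins(nbins, nmrSpec)
  cand <- which(!masked)
  totX4 <- sum(vapply(plantedCounts, function(ct) ct[["X4"]], numeric(1)))
  pos <- cand[round(seq(0.2, 0.8, length.out = totX4) * length(cand))]
  pos <- unique(pos)
  if (length(pos) < totX4)
    stop("X4 has too few unmasked bins for the requested planted sets")
  x4used <- 0L
  for (ctName in names(plantedCounts)) {
    ct <- plantedCounts[[ctName]]
    sets[[ctName]] <- list()
    for (b in names(blockDims)) {
      k <- ct[[b]]
      if (k < 1) next
      if (b == "X4") {
        idx <- pos[(x4used + 1L):(x4used + k)]
        x4used <- x4used + k
      } else {
        used <- sum(vapply(sets, function(s)
          if (!is.null(s[[b]])) length(s[[b]]$idx) else 0L, numeric(1)))
        if (used + k > blockDims[[b]])
          stop(sprintf("block %s too small for the requested planted sets", b))
        idx <- (used + 1L):(used + k)
      }
      eff <- effectSize * rep_len(c(1, -1), k)
      sets[[ctName]][[b]] <- list(idx = as.integer(idx), effect = eff)
    }
  }
  sets
}

#' Synthetic study configuration
#'
#' Defaults reproduce the reference study shape: 4 conditions (CG, CPT,
#' CPDMS, CP) x 5 replicates, block widths 1049 (LC-HRMS2), 26 and 42
#' (GC-MS), 8800 (NMR bins), with group effects of 2 within-group SD planted
#' on disjoint variable sets for the three contrasts CP-vs-rest, CG-vs-rest
#' and CPT-vs-CPDMS.
#'
#' @param nPerGroup replicates per condition (default 5).
#' @param groups ordered condition labels.
#' @param blockDims named per-block variable counts.
#' @param plantedCounts list (per contrast) of named per-block planted
#'   variable counts.
#' @param effectSize planted effect in multiples of the within-group SD.
#' @param plantedSets explicit planted sets (overrides
#'   \code{plantedCounts}/\code{effectSize}).
#' @param dilutionRange per-sample multiplicative dilution interval.
#' @param zeroRate fraction of MS-block entries set to exact 0.
#' @param noiseSd within-group SD on the log10 scale.
#' @param seed integer master seed; per-block child seeds derive from it as
#'   \code{(seed mod 2146483) * 1000 + blockIndex}.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nPerGroup = 5,
                            groups = c("CG", "CPT", "CPDMS", "CP"),
                            blockDims = c(X1 = 1049, X2 = 26, X3 = 42, X4 = 8800),
                            plantedCounts = list(
                              C1 = c(X1 = 40, X2 = 20, X3 = 20, X4 = 40),
                              C2 = c(X1 = 40, X2 = 3,  X3 = 11, X4 = 40),
                              C3 = c(X1 = 40, X2 = 3,  X3 = 11, X4 = 40)),
                            effectSize = 2,
                            plantedSets = NULL,
                            dilutionRange = c(0.7, 1.3),
                            zeroRate = 0.05,
                            noiseSd = 0.3,
                            seed = 20314) {
  blockDims <- stats::setNames(as.integer(blockDims), names(blockDims))
  nmrSpec <- binningSpec(binWidth = (9.0 - 0.2) / blockDims[["X4"]])
  if (is.null(plantedSets))
    plantedSets <- .defaultPlantedSets(blockDims, plantedCounts, effectSize, nmrSpec)
  new("SyntheticConfig", nPerGroup = as.integer(nPerGroup), groups = groups,
      blockDims = blockDims, plantedSets = plantedSets,
      dilutionRange = as.numeric(dilutionRange), zeroRate = as.numeric(zeroRate),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

.childSeed <- function(seed, k) (seed %% 2146483L) * 1000L + k

## signed per-sample effect matrix (log10 scale) for one block
.effectMatrix <- function(config, block, condition) {
  n <- length(condition)
  p <- config@blockDims[[block]]
  E <- matrix(0, n, p)
  for (ctName in names(config@plantedSets)) {
    ps <- config@plantedSets[[ctName]][[block]]
    if (is.null(ps)) next
    up <- condition %in% .CONTRASTS[[ctName]]$up
    E[up, ps$idx] <- E[up, ps$idx] +
      rep(ps$effect * config@noiseSd, each = sum(up))
  }
  E
}

## intensity-dependent dropout: lowest-signal entries are the most likely
## to fall below the detection limit
.injectZeros <- function(X, zeroRate, logX) {
  if (zeroRate <= 0) return(X)
  r <- rank(logX, ties.method = "first") / length(logX)
  p <- pmin(1, 2 * zeroRate * (1 - r))
  X[stats::runif(length(X)) < p] <- 0
  X
}

#' Generate a synthetic four-block study
#'
#' Produces raw (pre-preprocessing) block matrices, the study design, and a
#' ground-truth record of the planted structure.  MS blocks (X1--X3) are
#' zero-inflated positive intensities with log-normal baselines; the NMR
#' block (X4) is synthesized as Lorentzian peaks on a continuous ppm axis
#' and binned through \code{\link{binSpectrum}}.  A per-sample
#' multiplicative dilution factor (shared across blocks) is applied last.
#' Identical configurations produce bit-identical output.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{blocks} (named list of raw
#'   \linkS4class{BlockMatrix}), \code{design} (\linkS4class{StudyDesign}),
#'   \code{truth} (planted ids per contrast per block, contrast definitions,
#'   dilution factors) and \code{config}.
#' @examples
#' study <- generateStudy(syntheticConfig(blockDims = c(X1 = 30, X2 = 10,
#'   X3 = 10, X4 = 200), plantedCounts = list(C1 = c(X1 = 4, X2 = 2, X3 = 2,
#'   X4 = 4), C2 = c(X1 = 2, X2 = 2, X3 = 2, X4 = 2),
#'   C3 = c(X1 = 2, X2 = 2, X3 = 2, X4 = 2))))
#' length(study$design)
#' @export
generateStudy <- function(config = syntheticConfig()) {
  validObject(config)
  groups <- config@groups
  condition <- rep(groups, each = config@nPerGroup)
  samples <- paste0(condition, "_", rep(seq_len(config@nPerGroup), times = length(groups)))
  design <- StudyDesign(samples, condition, levels = groups)
  n <- length(samples)
  blocks <- list()

  for (bi in seq_along(config@blockDims)) {
    b <- names(config@blockDims)[bi]
    set.seed(.childSeed(config@seed, bi))
    if (b != "X4") {
      p <- config@blockDims[[b]]
      mu <- stats::runif(p, 4, 7)
      L <- matrix(rep(mu, each = n), n, p) +
        .effectMatrix(config, b, condition) +
        matrix(stats::rnorm(n * p, 0, config@noiseSd), n, p)
      X <- 10^L
      X <- .injectZeros(X, config@zeroRate, L)
      dimnames(X) <- list(samples, sprintf("%s_v%04d", b, seq_len(p)))
      blocks[[b]] <- BlockMatrix(X, b)
    } else {
      blocks[[b]] <- .generateNmrBlock(config, condition, samples)
    }
  }

  set.seed(.childSeed(config@seed, length(config@blockDims) + 1L))
  dil <- stats::runif(n, config@dilutionRange[1], config@dilutionRange[2])
  blocks <- lapply(blocks, applyDilution, factors = dil)

  truth <- list(
    planted = lapply(config@plantedSets, function(ct)
      lapply(ct, function(ps) list(
        idx = ps$idx, effect = ps$effect))),
    contrasts = .CONTRASTS[names(config@plantedSets)],
    dilution = stats::setNames(dil, samples))
  list(blocks = blocks, design = design, truth = truth, config = config)
}

## NMR block: baseline Lorentzian peaks shared by all samples (log-normal
## per-sample amplitude jitter) + one narrow peak per planted bin whose
## amplitude carries the group effect; a small positive noise floor keeps
## every bin strictly positive
.generateNmrBlock <- function(config, condition, samples) {
  nbins <- config@blockDims[["X4"]]
  spec <- binningSpec(binWidth = (9.0 - 0.2) / nbins)
  w <- spec$binWidth
  n <- length(samples)
  axisStep <- w / 4
  ppm <- seq(0.2 + axisStep / 2, 9.0 - axisStep / 2, by = axisStep)

  plantedBins <- integer(); plantedEff <- list()
  for (ctName in names(config@plantedSets)) {
    ps <- config@plantedSets[[ctName]][["X4"]]
    if (is.null(ps)) next
    up <- .CONTRASTS[[ctName]]$up
    for (k in seq_along(ps$idx)) {
      plantedBins <- c(plantedBins, ps$idx[k])
      plantedEff[[length(plantedEff) + 1L]] <-
        list(up = up, effect = ps$effect[k] * config@noiseSd)
    }
  }
  plantedCenters <- 0.2 + (plantedBins - 0.5) * w

  nBase <- 60L
  baseCenters <- numeric(0)
  tries <- 0L
  while (length(baseCenters) < nBase && tries < 5000L) {
    cand <- stats::runif(1, 0.3, 8.9)
    bad <- any(abs(cand - plantedCenters) < 0.05) ||
      any(vapply(spec$exclude, function(ex)
        cand > ex[1] - 0.05 && cand < ex[2] + 0.05, logical(1)))
    if (!bad) baseCenters <- c(baseCenters, cand)
    tries <- tries + 1L
  }
  nBaseK <- length(baseCenters)
  baseAmp <- 10^stats::runif(nBaseK, 4.5, 5.5)
  baseGamma <- stats::runif(nBaseK, 0.001, 0.004)
  plantAmp <- rep(1e5, length(plantedBins))
  plantGamma <- rep(w / 3, length(plantedBins))
  # per-sample, per-peak log-normal amplitude jitter of SD noiseSd
  baseJitter <- matrix(stats::rnorm(n * nBaseK, 0, config@noiseSd), n, nBaseK)

  lorentz <- function(x, x0, gamma) gamma^2 / ((x - x0)^2 + gamma^2)

  X <- matrix(0, n, nbins, dimnames = list(samples, NULL))
  for (i in seq_len(n)) {
    spectrum <- abs(stats::rnorm(length(ppm), 0, 1))
    for (k in seq_len(nBaseK)) {
      win <- which(abs(ppm - baseCenters[k]) < 0.05)
      amp <- baseAmp[k] * 10^baseJitter[i, k]
      spectrum[win] <- spectrum[win] +
        amp * lorentz(ppm[win], baseCenters[k], baseGamma[k])
    }
    for (k in seq_along(plantedBins)) {
      pe <- plantedEff[[k]]
      shift <- if (condition[i] %in% pe$up) pe$effect else 0
      amp <- plantAmp[k] * 10^(shift + stats::rnorm(1, 0, config@noiseSd))
      win <- which(abs(ppm - plantedCenters[k]) < 0.03)
      spectrum[win] <- spectrum[win] +
        amp * lorentz(ppm[win], plantedCenters[k], plantGamma[k])
    }
    X[i, ] <- binSpectrum(ppm, spectrum, spec)
  }
  colnames(X) <- names(binSpectrum(ppm, rep(0, length(ppm)), spec))
  BlockMatrix(X, "X4")
}
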