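## Seeded generators for AFM-style height profiles and staged interfacial
## rheology sweeps, with exported ground truth for recovery tests.

#' Generate a synthetic periodic height profile
#'
#' Emulates a 1-D AFM scan across a porous nanosheet: plateau segments at
#' discrete duplex-layer heights (`layerPattern` recycled across segments)
#' separated by Gaussian-shaped pore dips at regular spacing, plus
#' Gaussian height noise.
#'
#' @param spacingNm pore-to-pore spacing, nm (default 25).
#' @param nPores number of pores (default 8).
#' @param layerPattern integer vector of duplex layer counts per plateau
#'   segment, recycled (default 1).
#' @param layerHeightNm duplex layer height, nm (default 2).
#' @param noiseNm Gaussian height noise sigma, nm (default 0.1).
#' @param pixelNm sample spacing, nm (default 0.5; must be < spacing).
#' @param poreWidthNm full width at half maximum of a pore dip, nm
#'   (default 4).
#' @param seed integer RNG seed.
#' @param path optional basename; when given, the profile is written to
#'   `<path>.csv` with a `<path>.ground_truth.json` sidecar.
#' @return list with `profile` ([HeightProfile-class]) and `groundTruth`.
#' @examples
#' gen <- generateHeightProfile(spacingNm = 25, nPores = 6, seed = 2)
#' analyzeHeightProfile(gen$profile)$meanSpacingNm
#' @export
generateHeightProfile <- function(spacingNm = 25, nPores = 8,
                                  layerPattern = 1, layerHeightNm = 2.0,
                                  noiseNm = 0.1, pixelNm = 0.5,
                                  poreWidthNm = 4, seed = 1, path = NULL) {
  stopifnot(spacingNm > pixelNm, all(layerPattern >= 0), nPores >= 0)
  .with_seed(seed, {
    total <- (nPores + 1) * spacingNm
    x <- seq(0, total, by = pixelNm)
    pores <- if (nPores > 0) spacingNm * seq_len(nPores) else numeric(0)
    nseg <- nPores + 1
    levels <- rep_len(layerPattern, nseg) * layerHeightNm
    seg_of <- pmin(floor(x / spacingNm) + 1, nseg)
    plateau <- levels[seg_of]
    dip <- rep(0, length(x))
    sig <- poreWidthNm / (2 * sqrt(2 * log(2)))
    for (p in pores) dip <- dip + exp(-((x - p)^2) / (2 * sig^2))
    h <- plateau * (1 - pmin(dip, 1))
    if (noiseNm > 0) h <- h + stats::rnorm(length(h), 0, noiseNm)
    prof <- HeightProfile(x, h, pixelNm)
    gt <- list(seed = seed, spacingNm = spacingNm,
               porePositionsNm = pores,
               layerPattern = rep_len(layerPattern, nseg),
               layerHeightNm = layerHeightNm, noiseNm = noiseNm,
               poreWidthNm = poreWidthNm)
    if (!is.null(path)) {
      writeHeightProfile(prof, paste0(path, ".csv"))
      jsonlite::write_json(gt, paste0(path, ".ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(profile = prof, groundTruth = gt)
  })
}

#' Default staged rheology phase plan
#'
#' A four-phase plan emulating stepwise nanosheet assembly at a
#' liquid/liquid interface: anchored C-strand baseline (about 1e-4 N/m),
#' AB addition raising the storage modulus to the 10 mN/m scale, heating
#' to 45 degC with crosslinking above 100 mN/m, and annealing back to
#' 25 degC reaching 300 mN/m with a more than tenfold storage/loss gap.
#'
#' @param phaseDurationS duration of each phase, s (default 1800).
#' @return data.frame with columns `durationS`, `gpPlateau`, `gppPlateau`,
#'   `temperatureC`.
#' @export
defaultRheologyPlan <- function(phaseDurationS = 1800) {
  data.frame(
    durationS = phaseDurationS,
    gpPlateau = c(1e-4, 1e-2, 1e-1, 3e-1),
    gppPlateau = c(8e-5, 1e-3, 8e-3, 1.5e-2),
    temperatureC = c(25, 25, 45, 25))
}

#' Generate a staged synthetic rheology time sweep
#'
#' Piecewise plateaus with smooth sigmoidal transitions at each phase
#' boundary (transition time 2% of the phase duration, so plateaus are
#' fully established well before the trailing window) and multiplicative
#' log-normal noise of the given coefficient of variation.
#'
#' @param phasePlan data.frame with columns `durationS`, `gpPlateau`,
#'   `gppPlateau`, `temperatureC`; see [defaultRheologyPlan()].
#' @param noiseCv multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param dtS sampling interval, s (default 5).
#' @param seed integer RNG seed.
#' @param path optional basename; writes `<path>.csv` and a ground-truth
#'   JSON sidecar when given.
#' @return list with `sweep` ([RheologySweep-class]) and `groundTruth`.
#' @export
generateRheologySweep <- function(phasePlan = defaultRheologyPlan(),
                                  noiseCv = 0.05, dtS = 5, seed = 1,
                                  path = NULL) {
  stopifnot(all(phasePlan$gpPlateau >= 0), all(phasePlan$gppPlateau >= 0),
            all(phasePlan$durationS > 0))
  .with_seed(seed, {
    rows <- list()
    t0 <- 0
    for (i in seq_len(nrow(phasePlan))) {
      D <- phasePlan$durationS[i]
      tt <- seq(dtS, D, by = dtS)
      ramp <- function(from, to) {
        if (i == 1) return(rep(to, length(tt)))
        tau <- 0.02 * D
        s <- 1 / (1 + exp(-(tt - 5 * tau) / tau))
        from + (to - from) * s
      }
      gp <- ramp(phasePlan$gpPlateau[max(1, i - 1)], phasePlan$gpPlateau[i])
      gpp <- ramp(phasePlan$gppPlateau[max(1, i - 1)], phasePlan$gppPlateau[i])
      rows[[i]] <- data.frame(
        time = t0 + tt, storageModulus = gp, lossModulus = gpp,
        temperature = phasePlan$temperatureC[i], frequency = 0.1,
        strain = 0.01, phase = paste0("phase", i))
      t0 <- t0 + D
    }
    d <- do.call(rbind, rows)
    if (noiseCv > 0) {
      d$storageModulus <- d$storageModulus *
        exp(stats::rnorm(nrow(d), 0, noiseCv))
      d$lossModulus <- d$lossModulus * exp(stats::rnorm(nrow(d), 0, noiseCv))
    }
    sweep <- RheologySweep(d)
    gt <- list(seed = seed, noiseCv = noiseCv, dtS = dtS,
               phaseBoundariesS = cumsum(phasePlan$durationS),
               gpPlateaus = phasePlan$gpPlateau,
               gppPlateaus = phasePlan$gppPlateau,
               temperaturesC = phasePlan$temperatureC)
    if (!is.null(path)) {
      writeTimeSweep(sweep, paste0(path, ".csv"))
      jsonlite::write_json(gt, paste0(path, ".ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(sweep = sweep, groundTruth = gt)
  })
}
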