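## Interfacial shear rheology: time-sweep handling, phase plateaus and the
## extrapolation of interfacial storage moduli to bulk Young's moduli.

#' Read an interfacial rheology time sweep
#'
#' Expects a delimited table with columns `time_s`, `Gp_N_per_m`,
#' `Gpp_N_per_m`, `temperature_C` and optionally `frequency_Hz`, `strain`
#' and `phase`.
#'
#' @param path CSV file path.
#' @return a [RheologySweep-class].
#' @export
readTimeSweep <- function(path) {
  d <- utils::read.csv(path)
  cols <- c(time_s = "time", Gp_N_per_m = "storageModulus",
            Gpp_N_per_m = "lossModulus", temperature_C = "temperature")
  for (nm in names(cols)) {
    if (!nm %in% names(d)) {
      pretty <- c(time_s = "time", Gp_N_per_m = "storage_modulus",
                  Gpp_N_per_m = "loss_modulus", temperature_C = "temperature")
      stop(sprintf("%s column absent", pretty[[nm]]))
    }
  }
  out <- data.frame(time = d$time_s, storageModulus = d$Gp_N_per_m,
                    lossModulus = d$Gpp_N_per_m, temperature = d$temperature_C)
  if ("frequency_Hz" %in% names(d)) out$frequency <- d$frequency_Hz
  if ("strain" %in% names(d)) out$strain <- d$strain
  if ("phase" %in% names(d)) out$phase <- d$phase
  if (any(out$storageModulus < 0) || any(out$lossModulus < 0)) {
    stop("negative modulus in time sweep")
  }
  if (nrow(out) > 1 && any(diff(out$time) <= 0)) {
    stop("times out of order in time sweep")
  }
  RheologySweep(out)
}

#' Write a rheology sweep to CSV
#'
#' @param sweep a [RheologySweep-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTimeSweep <- function(sweep, path) {
  d <- sweep@data
  out <- data.frame(time_s = d$time, Gp_N_per_m = d$storageModulus,
                    Gpp_N_per_m = d$lossModulus, temperature_C = d$temperature)
  if (!is.null(d$frequency)) out$frequency_Hz <- d$frequency
  if (!is.null(d$strain)) out$strain <- d$strain
  if (!is.null(d$phase)) out$phase <- d$phase
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Segment a time sweep into protocol phases and extract plateau moduli
#'
#' Phases are delimited either by explicit boundary times or by a
#' temperature trigger (consecutive runs of samples at or above the
#' trigger temperature form their own phases).  The plateau of each phase
#' is the mean of G' and G'' over the trailing fraction of the phase.
#'
#' @param sweep a [RheologySweep-class].
#' @param boundaries numeric vector of phase boundary times (s), or `NULL`.
#' @param temperatureTrigger temperature (degC) splitting the sweep at
#'   crossings, or `NULL`.
#' @param trailingFraction fraction of each phase over which the plateau is
#'   averaged (default 0.25).
#' @return data.frame with one row per phase: `phase`, `tStart`, `tEnd`,
#'   `n`, `meanGp`, `meanGpp`, `meanTemperature`.
#' @export
segmentTimeSweep <- function(sweep, boundaries = NULL,
                             temperatureTrigger = NULL,
                             trailingFraction = 0.25) {
  d <- sweep@data
  if (!is.null(boundaries)) {
    if (any(boundaries <= min(d$time)) || any(boundaries >= max(d$time))) {
      stop("phase boundaries must lie strictly within the sweep time range")
    }
    phase_id <- findInterval(d$time, sort(boundaries)) + 1L
  } else if (!is.null(temperatureTrigger)) {
    above <- d$temperature >= temperatureTrigger
    phase_id <- cumsum(c(TRUE, diff(above) != 0))
  } else if (!is.null(d$phase)) {
    phase_id <- cumsum(c(TRUE, d$phase[-1] != d$phase[-nrow(d)]))
  } else {
    phase_id <- rep(1L, nrow(d))
  }
  out <- lapply(unique(phase_id), function(p) {
    idx <- which(phase_id == p)
    if (!length(idx)) stop("empty phase ", p)
    k <- max(1L, ceiling(trailingFraction * length(idx)))
    tail_idx <- idx[(length(idx) - k + 1L):length(idx)]
    data.frame(phase = p, tStart = d$time[idx[1]], tEnd = d$time[idx[length(idx)]],
               n = length(idx),
               meanGp = mean(d$storageModulus[tail_idx]),
               meanGpp = mean(d$lossModulus[tail_idx]),
               meanTemperature = mean(d$temperature[idx]))
  })
  do.call(rbind, out)
}

#' Extrapolate an interfacial shear modulus to a bulk Young's modulus
#'
#' For a thin sheet of thickness t, the interfacial shear storage modulus
#' G' (N/m) corresponds to a bulk shear modulus G'/t (Pa); with Poisson's
#' ratio nu the Young's modulus is `E = 2 (1 + nu) G' / t`.  The defaults
#' (nu = 0.5, t = 2 nm = one duplex diameter) give E = 3 G'/t: 0.300 N/m
#' on a single-duplex-thick sheet extrapolates to 450 MPa.
#'
#' @param Gs interfacial storage modulus, N/m (non-negative).
#' @param params an [ExtrapolationParams-class].
#' @return Young's modulus in Pa.
#' @examples
#' bulkYoungModulus(0.300) / 1e6  # 450 MPa
#' @export
bulkYoungModulus <- function(Gs, params = ExtrapolationParams()) {
  stopifnot(Gs >= 0)
  if (params@thicknessNm <= 0) stop("thickness must be positive")
  2 * (1 + params@poissonRatio) * Gs / (params@thicknessNm * 1e-9)
}

#' Porosity-corrected (load-bearing) Young's modulus
#'
#' Scales a sheet-average modulus by the inverse load-bearing area
#' fraction, `E_unit = E / (1 - phi)`; for porosity above the given phi
#' the result is a lower bound on the per-unit modulus.
#'
#' @param E sheet-average Young's modulus, Pa.
#' @param porosityFraction open-area fraction phi in `[0, 1)`.
#' @return corrected modulus in Pa.
#' @examples
#' porosityCorrectedModulus(450e6, 0.40) / 1e6  # 750 MPa
#' @export
porosityCorrectedModulus <- function(E, porosityFraction) {
  if (porosityFraction < 0 || porosityFraction >= 1) {
    stop("porosity must lie in [0, 1)")
  }
  E / (1 - porosityFraction)
}

#' Elastic gap between storage and loss moduli, in decades
#'
#' @param Gp,Gpp interfacial storage and loss moduli, N/m (positive).
#' @return `log10(Gp / Gpp)`.
#' @examples
#' elasticGapOrders(0.1, 0.005)  # 1.301
#' @export
elasticGapOrders <- function(Gp, Gpp) {
  if (any(c(Gp, Gpp) <= 0)) stop("moduli must be positive")
  log10(Gp / Gpp)
}

#' Full interfacial-to-bulk extrapolation
#'
#' Chains [bulkYoungModulus()] and [porosityCorrectedModulus()] into an
#' [ExtrapolationResult-class].
#'
#' @inheritParams bulkYoungModulus
#' @return an [ExtrapolationResult-class].
#' @examples
#' extrapolateModulus(0.300)
#' @export
extrapolateModulus <- function(Gs, params = ExtrapolationParams()) {
  E <- bulkYoungModulus(Gs, params)
  new("ExtrapolationResult", interfacialModulus = Gs,
      bulkYoungModulusPa = E,
      porosityCorrectedModulusPa = porosityCorrectedModulus(E, params@porosityFraction),
      params = params)
}
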