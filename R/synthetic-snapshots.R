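## Seeded generators for coarse-grained F-unit and nanopore configurations.
## These are statistical emulations for testing analysis code: beads are
## placed pairwise across duplex center-lines (no helical twist, which the
## midpoint-based metrics cannot see), with controllable out-of-plane tilt
## and positional noise, and every artifact carries its ground truth.

#' Distortion parameters for synthetic snapshots
#'
#' @slot uniformTiltDeg out-of-plane tilt applied to the junction tripods
#'   (F-unit: both junctions' arm directions are raised onto a cone at
#'   elevation +/- tilt, so the planarity metric is exactly sin(tilt);
#'   pore: fold angle about the X-Z diagonal).  Degrees, in [0, 90).
#' @slot positionalNoiseNm per-nucleotide isotropic Gaussian sigma, nm.
#' @slot junctionAngleOverrides optional named numeric azimuth overrides
#'   (degrees) for arms e1/e2 relative to the core.
#' @slot seed integer RNG seed.
#' @export
setClass("DistortionParams", representation(
  uniformTiltDeg = "numeric", positionalNoiseNm = "numeric",
  junctionAngleOverrides = "numeric", seed = "numeric"))

setValidity("DistortionParams", function(object) {
  msg <- character()
  if (object@positionalNoiseNm < 0) msg <- c(msg, "noise must be >= 0")
  if (object@uniformTiltDeg < 0 || object@uniformTiltDeg >= 90) {
    msg <- c(msg, "tilt must lie in [0, 90) degrees")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct DistortionParams
#' @param uniformTiltDeg tilt in degrees, `[0, 90)`.
#' @param positionalNoiseNm Gaussian positional noise sigma, nm.
#' @param junctionAngleOverrides named numeric azimuth overrides (degrees).
#' @param seed integer RNG seed.
#' @return a [DistortionParams-class] object.
#' @export
DistortionParams <- function(uniformTiltDeg = 0, positionalNoiseNm = 0,
                             junctionAngleOverrides = numeric(0), seed = 1) {
  new("DistortionParams", uniformTiltDeg = uniformTiltDeg,
      positionalNoiseNm = positionalNoiseNm,
      junctionAngleOverrides = junctionAngleOverrides, seed = seed)
}

#' Relaxation pseudo-trajectory parameters
#'
#' Frame k carries tilt
#' `phi_k = phi_eq + (phi_0 - phi_eq) exp(-t_k / tau) + eps_k`,
#' `eps_k ~ N(0, noiseDeg)`, emulating the approach to equilibrium of the
#' junction planarity in a relaxation run.
#'
#' @slot nFrames number of frames (>= 4).
#' @slot frameDtTauB frame spacing, Brownian time units.
#' @slot initialTiltDeg,equilibriumTiltDeg start/equilibrium tilt, degrees.
#' @slot relaxationTimeTauB relaxation time tau (> 0).
#' @slot noiseDeg per-frame Gaussian tilt noise, degrees.
#' @slot seed integer RNG seed.
#' @export
setClass("RelaxationParams", representation(
  nFrames = "numeric", frameDtTauB = "numeric", initialTiltDeg = "numeric",
  equilibriumTiltDeg = "numeric", relaxationTimeTauB = "numeric",
  noiseDeg = "numeric", seed = "numeric"))

setValidity("RelaxationParams", function(object) {
  msg <- character()
  if (object@nFrames < 4) msg <- c(msg, "need at least 4 frames")
  if (object@relaxationTimeTauB <= 0) msg <- c(msg, "relaxation time must be > 0")
  if (object@noiseDeg < 0) msg <- c(msg, "noise must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct RelaxationParams
#' @param nFrames number of frames.
#' @param frameDtTauB frame spacing, Brownian time units.
#' @param initialTiltDeg,equilibriumTiltDeg start and equilibrium tilt, deg.
#' @param relaxationTimeTauB relaxation time, Brownian time units.
#' @param noiseDeg Gaussian tilt noise per frame, degrees.
#' @param seed integer RNG seed.
#' @return a [RelaxationParams-class] object.
#' @export
RelaxationParams <- function(nFrames = 200, frameDtTauB = 1,
                             initialTiltDeg = 60,
                             equilibriumTiltDeg = asin(0.2) * 180 / pi,
                             relaxationTimeTauB = 10, noiseDeg = 1, seed = 1) {
  new("RelaxationParams", nFrames = nFrames, frameDtTauB = frameDtTauB,
      initialTiltDeg = initialTiltDeg, equilibriumTiltDeg = equilibriumTiltDeg,
      relaxationTimeTauB = relaxationTimeTauB, noiseDeg = noiseDeg, seed = seed)
}

## perpendicular unit vector to a direction (used to offset the two beads
## of a pair around the duplex center-line)
.perp_of <- function(d) {
  p <- .cross3(d, c(0, 0, 1))
  if (sqrt(sum(p^2)) < 1e-6) p <- .cross3(d, c(1, 0, 0))
  .unitv(p)
}

## direction from azimuth (deg, in the sheet plane) and elevation (deg)
.dir_azel <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180; el <- el_deg * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

## Build the noiseless F-unit bead coordinates (nm) for a given tilt.
## Returns positions, a1, a3 (n x 3, nm / unit) plus junction ground truth.
.funit_coords <- function(design, tilt_deg, azimuths = c(e1 = 150, e2 = -120)) {
  lay <- .funit_layout(design)
  rise <- design@riseNm
  w2 <- .sheetkit_const$pair_separation_nm / 2
  twist <- .sheetkit_const$twist_deg_per_bp * pi / 180
  n <- sum(lay$strand_lengths)
  pos <- matrix(NA_real_, n, 3)
  a1 <- matrix(NA_real_, n, 3)
  a3 <- matrix(NA_real_, n, 3)
  J1 <- c(0, 0, 0)
  ## tripods on cones: +tilt at J1, -tilt at J2, so the three unit arm
  ## vectors of each junction share the elevation and d_p = sin(tilt)
  d_core <- .dir_azel(0, tilt_deg)
  d_e1 <- .dir_azel(azimuths[["e1"]], tilt_deg)
  d_e2 <- .dir_azel(azimuths[["e2"]], tilt_deg)
  J2 <- J1 + design@coreBp * rise * d_core
  d_e4 <- .dir_azel(azimuths[["e1"]] + 180, -tilt_deg)
  d_e5 <- .dir_azel(azimuths[["e2"]] + 180, -tilt_deg)
  lk <- stats::setNames(c(lay$pairs[, 2], lay$pairs[, 1]),
                        c(lay$pairs[, 1], lay$pairs[, 2]))
  place_duplex <- function(ref_idx, origin, dir) {
    ## beads of each pair sit on a helix about the center-line (twist per
    ## bp), so their midpoint is exactly on the axis and paired a1 versors
    ## are exactly anti-aligned while neighboring pairs differ by the twist
    p <- .perp_of(dir)
    for (k in seq_along(ref_idx)) {
      m <- origin + (k - 0.5) * rise * dir
      u <- as.numeric(.rotation_matrix(dir, (k - 1) * twist) %*% p)
      i <- ref_idx[k]; j <- lk[[as.character(i)]]
      pos[i, ] <<- m - w2 * u; pos[j, ] <<- m + w2 * u
      a1[i, ] <<- u; a1[j, ] <<- -u
      a3[i, ] <<- dir; a3[j, ] <<- -dir
    }
  }
  place_ss <- function(idx, origin, dir, outward) {
    ## idx in 5'->3' strand order; `outward` TRUE when that order runs
    ## away from the arm tip.  Unpaired beads lie on the center-line with
    ## a1 along the axis, perpendicular to every duplex a1.
    nss <- length(idx)
    for (k in seq_along(idx)) {
      step <- if (outward) k else nss - k + 1L
      pos[idx[k], ] <<- origin + (step - 0.5) * rise * dir
      a1[idx[k], ] <<- dir
      a3[idx[k], ] <<- dir
    }
  }
  place_duplex(lay$A$core, J1, d_core)
  place_duplex(lay$junction1$e1, J1, d_e1)
  place_duplex(lay$junction1$e2, J1, d_e2)
  place_duplex(lay$junction2$e4, J2, d_e4)
  place_duplex(lay$junction2$e5, J2, d_e5)
  La <- design@armBp * rise
  place_ss(lay$A$se1, J1 + La * d_e1, d_e1, outward = FALSE)  # SE1: 5' end distal
  place_ss(lay$B$se2s, J1 + La * d_e2, d_e2, outward = TRUE)
  place_ss(lay$B$se1s, J2 + La * d_e4, d_e4, outward = FALSE)
  place_ss(lay$A$se2, J2 + La * d_e5, d_e5, outward = TRUE)
  list(positions = pos, a1 = a1, a3 = a3, layout = lay,
       junctions = rbind(J1 = J1, J2 = J2),
       armDirections = list(e1 = d_e1, e2 = d_e2, e3 = d_core,
                            e4 = d_e4, e5 = d_e5, e6 = -d_core))
}

.funit_topology <- function(design) {
  lay <- .funit_layout(design)
  if (!length(design@sequences)) {
    stop("design needs sequences to build a topology")
  }
  seqs <- design@sequences
  bases <- unlist(strsplit(c(seqs$A, seqs$B, rep(seqs$C, 4)), ""))
  lens <- unname(lay$strand_lengths)
  strand <- rep(seq_along(lens), lens)
  n <- length(bases)
  idx <- seq_len(n)
  first <- !duplicated(strand)
  last <- !duplicated(strand, fromLast = TRUE)
  ## records run 5'->3' per strand: n5 = previous, n3 = next
  n5 <- ifelse(first, NA_integer_, idx - 1L)
  n3 <- ifelse(last, NA_integer_, idx + 1L)
  Topology(strand, bases, n3, n5)
}

#' Generate a synthetic single F-unit configuration
#'
#' Builds the canonical six-strand F-unit topology (strands A, B and four
#' C copies) and a near-planar configuration: duplex base pairs are placed
#' pairwise across segment center-lines, sticky ends are rendered
#' single-stranded, the junction tripods are raised onto cones at
#' elevation +/- `uniformTiltDeg` (so the planarity metric equals
#' sin(tilt) exactly) and Gaussian positional noise is added.  The output
#' is a pure function of (design, distortion): identical inputs give
#' identical objects.
#'
#' @param design a [FUnitDesign-class]; placeholder sequences are drawn
#'   with the distortion seed when the design carries none.
#' @param distortion a [DistortionParams-class].
#' @return list with `topology`, `snapshot`, `junctions` (list of two
#'   [JunctionSpec-class]), `pairing` ([BasePairMap-class], ground truth)
#'   and `groundTruth` (list of injected parameters).
#' @examples
#' gen <- generateFUnitSnapshot(FUnitDesign(),
#'                              DistortionParams(uniformTiltDeg = 30))
#' junctionPlanarity(gen$snapshot, gen$pairing, gen$junctions[[1]])  # 0.5
#' @export
generateFUnitSnapshot <- function(design, distortion = DistortionParams()) {
  validObject(distortion)
  .with_seed(distortion@seed, {
    if (!length(design@sequences)) {
      design <- makeDesignSequences(design, seed = distortion@seed)
    }
    az <- c(e1 = 150, e2 = -120)
    ov <- distortion@junctionAngleOverrides
    az[names(ov)] <- ov
    geo <- .funit_coords(design, distortion@uniformTiltDeg, az)
    top <- .funit_topology(design)
    pos <- geo$positions
    if (distortion@positionalNoiseNm > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos), 0,
                                       distortion@positionalNoiseNm),
                          ncol = 3)
    }
    ext <- max(abs(pos)) + 20
    snap <- Snapshot(time = 0, box = rep(fromNanometers(2 * ext), 3),
                     positions = fromNanometers(pos),
                     a1 = geo$a1, a3 = geo$a3)
    lay <- geo$layout
    j1 <- JunctionSpec(1, lay$junction1,
                       c(e1 = FALSE, e2 = TRUE, e3 = NA))
    j2 <- JunctionSpec(2, lay$junction2,
                       c(e4 = FALSE, e5 = TRUE, e6 = NA))
    gt <- list(seed = distortion@seed,
               uniformTiltDeg = distortion@uniformTiltDeg,
               positionalNoiseNm = distortion@positionalNoiseNm,
               azimuthsDeg = as.list(az),
               junctionsNm = list(J1 = geo$junctions["J1", ],
                                  J2 = geo$junctions["J2", ]),
               armDirections = geo$armDirections,
               expectedDp = sin(distortion@uniformTiltDeg * pi / 180))
    list(topology = top, snapshot = snap, junctions = list(j1, j2),
         pairing = BasePairMap(lay$pairs, "ground-truth"),
         groundTruth = gt)
  })
}

#' Generate a synthetic four-F-unit nanopore configuration
#'
#' Builds an idealized pore quadrilateral: four corner junctions X, Y, Z, W
#' in a parallelogram with side contours of `arm + SE + core + arm` (63 bp
#' for the default design, long side) and `arm + SE + arm` (42 bp, short
#' side), each side a straight duplex chain, plus an outward 16-bp arm at
#' each corner.  The strand decomposition is per segment (one duplex per
#' side/arm) -- a geometric emulation of the assembled state, not the
#' strand-level architecture of the constituent units.  Distortion: the
#' `uniformTiltDeg` folds the sheet about the X-Z diagonal by that angle;
#' positional noise is per-bead Gaussian.
#'
#' @param design a [FUnitDesign-class].
#' @param junctionAngleDeg parallelogram angle at corner X (default 80).
#' @param distortion a [DistortionParams-class].
#' @return list with `topology`, `snapshot`, `pore` ([PoreSpec-class]),
#'   `pairing` and `groundTruth`.
#' @export
generatePoreSnapshot <- function(design, junctionAngleDeg = 80,
                                 distortion = DistortionParams()) {
  validObject(distortion)
  if (junctionAngleDeg <= 0 || junctionAngleDeg >= 180) {
    stop("junction angle must lie in (0, 180)")
  }
  .with_seed(distortion@seed, {
    rise <- design@riseNm
    w2 <- .sheetkit_const$pair_separation_nm / 2
    twist <- .sheetkit_const$twist_deg_per_bp * pi / 180
    aBp <- design@armBp + design@seBp + design@coreBp + design@armBp
    bBp <- design@armBp + design@seBp + design@armBp
    th <- junctionAngleDeg * pi / 180
    u <- c(1, 0, 0); v <- c(cos(th), sin(th), 0)
    corners <- rbind(X = c(0, 0, 0), Y = aBp * rise * u,
                     Z = aBp * rise * u + bBp * rise * v,
                     W = bBp * rise * v)
    segs <- list(
      XY = list(origin = corners["X", ], dir = u, nBp = aBp),
      YZ = list(origin = corners["Y", ], dir = v, nBp = bBp),
      ZW = list(origin = corners["Z", ], dir = -u, nBp = aBp),
      WX = list(origin = corners["W", ], dir = -v, nBp = bBp))
    outdirs <- list(
      X = -.unitv(u + v), Y = -.unitv(v - u),
      Z = .unitv(u + v), W = .unitv(u - v))
    for (nm in names(outdirs)) {
      segs[[paste0("arm", nm)]] <- list(origin = corners[nm, ],
                                        dir = outdirs[[nm]],
                                        nBp = design@armBp)
    }
    ## strands: per segment a sense strand (5'->3' along the segment) and
    ## its antiparallel complement
    strand <- integer(0); bases <- character(0)
    n3 <- integer(0); n5 <- integer(0)
    pos <- NULL; a1 <- NULL; a3 <- NULL
    pairs <- NULL
    seg_ref <- list()   # sense-strand global indices per segment
    sid <- 0L
    for (nm in names(segs)) {
      s <- segs[[nm]]
      nb <- s$nBp
      sense <- sample(c("A", "C", "G", "T"), nb, replace = TRUE)
      anti <- rev(.base_complement[sense])
      off <- length(bases)
      idx_sense <- off + seq_len(nb)
      idx_anti <- off + nb + seq_len(nb)
      bases <- c(bases, sense, anti)
      strand <- c(strand, rep(sid + 1L, nb), rep(sid + 2L, nb))
      sid <- sid + 2L
      for (ii in list(idx_sense, idx_anti)) {
        n5 <- c(n5, NA_integer_, ii[-length(ii)])
        n3 <- c(n3, ii[-1], NA_integer_)
      }
      p <- .perp_of(s$dir)
      mids <- t(vapply(seq_len(nb), function(k) s$origin + (k - 0.5) * rise * s$dir,
                       numeric(3)))
      uu <- t(vapply(seq_len(nb), function(k) {
        as.numeric(.rotation_matrix(s$dir, (k - 1) * twist) %*% p)
      }, numeric(3)))
      pos <- rbind(pos, mids - w2 * uu, (mids + w2 * uu)[nb:1, , drop = FALSE])
      a1 <- rbind(a1, uu, -uu[nb:1, , drop = FALSE])
      a3 <- rbind(a3, matrix(s$dir, nb, 3, byrow = TRUE),
                  matrix(-s$dir, nb, 3, byrow = TRUE))
      pairs <- rbind(pairs, cbind(idx_sense, rev(idx_anti)))
      seg_ref[[nm]] <- idx_sense
    }
    ## fold about the X-Z diagonal by the tilt angle; whole base pairs move
    ## together (side membership decided by the pair midpoint, so pairs
    ## sitting on the fold axis stay put)
    if (distortion@uniformTiltDeg != 0) {
      axis <- .unitv(corners["Z", ] - corners["X", ])
      side_normal <- .cross3(axis, c(0, 0, 1))
      w_sign <- sum((corners["W", ] - corners["X", ]) * side_normal)
      mids <- (pos[pairs[, 1], , drop = FALSE] +
                 pos[pairs[, 2], , drop = FALSE]) / 2
      comp <- as.numeric(sweep(mids, 2, corners["X", ]) %*% side_normal) * w_sign
      fold_pairs <- comp > 1e-9
      on_w_side <- rep(FALSE, nrow(pos))
      on_w_side[as.vector(pairs[fold_pairs, ])] <- TRUE
      R <- .rotation_matrix(axis, distortion@uniformTiltDeg * pi / 180)
      shifted <- sweep(pos[on_w_side, , drop = FALSE], 2, corners["X", ])
      pos[on_w_side, ] <- sweep(shifted %*% t(R), 2, corners["X", ], "+")
      a1[on_w_side, ] <- a1[on_w_side, , drop = FALSE] %*% t(R)
      a3[on_w_side, ] <- a3[on_w_side, , drop = FALSE] %*% t(R)
    }
    if (distortion@positionalNoiseNm > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos), 0,
                                       distortion@positionalNoiseNm), ncol = 3)
    }
    top <- Topology(strand, bases, n3, n5)
    ext <- max(abs(pos)) + 20
    snap <- Snapshot(time = 0, box = rep(fromNanometers(2 * ext), 3),
                     positions = fromNanometers(pos), a1 = a1, a3 = a3)
    nArm <- design@armBp
    corner_specs <- list(); internal <- list()
    cyc <- c("X", "Y", "Z", "W")
    out_seg <- c(X = "XY", Y = "YZ", Z = "ZW", W = "WX")   # side leaving
    in_seg <- c(X = "WX", Y = "XY", Z = "YZ", W = "ZW")    # side arriving
    for (i in seq_along(cyc)) {
      nm <- cyc[i]
      leave <- seg_ref[[out_seg[nm]]][seq_len(nArm)]
      arrive_idx <- seg_ref[[in_seg[nm]]]
      arrive <- rev(utils::tail(arrive_idx, nArm))
      outward <- seg_ref[[paste0("arm", nm)]]
      arms <- list(side_out = leave, side_in = arrive, outward = outward)
      corner_specs[[nm]] <- JunctionSpec(i, arms,
                                         c(side_out = NA, side_in = NA,
                                           outward = NA))
      internal[[nm]] <- c("side_out", "side_in")
    }
    pore <- PoreSpec(corner_specs, internal)
    gt <- list(seed = distortion@seed,
               junctionAngleDeg = junctionAngleDeg,
               foldAngleDeg = distortion@uniformTiltDeg,
               positionalNoiseNm = distortion@positionalNoiseNm,
               cornersNm = apply(corners, 1, identity, simplify = FALSE),
               sideLongBp = aBp, sideShortBp = bBp,
               expectedDiagXZNm = sqrt(sum((corners["X", ] - corners["Z", ])^2)),
               expectedDiagYWNm = sqrt(sum((corners["Y", ] - corners["W", ])^2)))
    list(topology = top, snapshot = snap, pore = pore,
         pairing = BasePairMap(pairs, "ground-truth"), groundTruth = gt)
  })
}

#' Generate a synthetic relaxation pseudo-trajectory
#'
#' Writes an oxDNA topology/trajectory pair in which the F-unit tilt
#' relaxes exponentially from `initialTiltDeg` to `equilibriumTiltDeg`
#' with time constant `relaxationTimeTauB`, plus per-frame Gaussian tilt
#' noise; the junction planarity of frame k is sin(phi_k).  A ground-truth
#' JSON sidecar records the injected parameters.
#'
#' @param design a [FUnitDesign-class].
#' @param relax a [RelaxationParams-class].
#' @param dir output directory (created if needed).
#' @param basename file basename (default "relaxation").
#' @return list with `topologyPath`, `trajectoryPath`, `groundTruthPath`,
#'   `trajectory` ([Trajectory-class]), `junctions`, `pairing` and
#'   `groundTruth`.
#' @export
generateRelaxationTrajectory <- function(design, relax = RelaxationParams(),
                                         dir = tempdir(),
                                         basename = "relaxation") {
  validObject(relax)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .with_seed(relax@seed, {
    if (!length(design@sequences)) {
      design <- makeDesignSequences(design, seed = relax@seed)
    }
    tt <- (seq_len(relax@nFrames) - 1) * relax@frameDtTauB
    phi <- relax@equilibriumTiltDeg +
      (relax@initialTiltDeg - relax@equilibriumTiltDeg) *
      exp(-tt / relax@relaxationTimeTauB)
    if (relax@noiseDeg > 0) {
      phi <- phi + stats::rnorm(length(phi), 0, relax@noiseDeg)
    }
    phi <- pmin(pmax(phi, 0), 89.9)
    top <- .funit_topology(design)
    lay <- .funit_layout(design)
    snaps <- vector("list", relax@nFrames)
    box <- rep(fromNanometers(2 * (design@coreBp + 2 * design@armBp +
                                     2 * design@seBp) * design@riseNm + 40), 3)
    for (k in seq_len(relax@nFrames)) {
      geo <- .funit_coords(design, phi[k])
      snaps[[k]] <- Snapshot(time = tt[k], box = box,
                             positions = fromNanometers(geo$positions),
                             a1 = geo$a1, a3 = geo$a3)
    }
    traj <- Trajectory(top, snaps)
    top_path <- file.path(dir, paste0(basename, ".top"))
    traj_path <- file.path(dir, paste0(basename, ".dat"))
    gt_path <- file.path(dir, paste0(basename, ".ground_truth.json"))
    writeTopology(top, top_path)
    writeTrajectory(traj, traj_path)
    j1 <- JunctionSpec(1, lay$junction1, c(e1 = FALSE, e2 = TRUE, e3 = NA))
    j2 <- JunctionSpec(2, lay$junction2, c(e4 = FALSE, e5 = TRUE, e6 = NA))
    gt <- list(seed = relax@seed, nFrames = relax@nFrames,
               frameDtTauB = relax@frameDtTauB,
               initialTiltDeg = relax@initialTiltDeg,
               equilibriumTiltDeg = relax@equilibriumTiltDeg,
               relaxationTimeTauB = relax@relaxationTimeTauB,
               noiseDeg = relax@noiseDeg,
               expectedEquilibriumDp = sin(relax@equilibriumTiltDeg * pi / 180),
               tiltDegByFrame = phi,
               junctionArms = list(J1 = lay$junction1, J2 = lay$junction2),
               pairs = lay$pairs)
    jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
    list(topologyPath = top_path, trajectoryPath = traj_path,
         groundTruthPath = gt_path, trajectory = traj,
         junctions = list(j1, j2),
         pairing = BasePairMap(lay$pairs, "ground-truth"),
         groundTruth = gt)
  })
}
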