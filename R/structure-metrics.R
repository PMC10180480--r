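## Geometry metrics on coarse-grained configurations: junction planarity,
## inter-arm angles, pore quadrilateral measures and equilibration stats.
## Metric extraction consumes base-pair midpoints, so the results are
## invariant to how the two beads of a pair are arranged around the helix
## axis.

.pair_lookup <- function(pairing) {
  p <- pairing@pairs
  lk <- integer(0)
  if (nrow(p)) {
    lk <- stats::setNames(c(p[, 2], p[, 1]), c(p[, 1], p[, 2]))
  }
  lk
}

## Midpoints of the base pairs whose reference-side indices are `idx`.
.bp_midpoints <- function(snapshot, pairing, idx) {
  lk <- .pair_lookup(pairing)
  partner <- lk[as.character(idx)]
  if (anyNA(partner)) {
    stop("missing base-pair partner for nucleotide(s): ",
         paste(idx[is.na(partner)], collapse = ", "))
  }
  (snapshot@positions[idx, , drop = FALSE] +
     snapshot@positions[partner, , drop = FALSE]) / 2
}

#' Direction of a DNA arm from a configuration
#'
#' Fits a total-least-squares line through the arm's base-pair midpoints
#' and returns its unit direction, sign-fixed to point from the proximal
#' to the distal end of the index list, together with the midpoint
#' centroid as origin.
#'
#' @param snapshot a [Snapshot-class].
#' @param pairing a [BasePairMap-class].
#' @param arm integer vector of reference-side nucleotide indices, ordered
#'   proximal to distal (at least 2 base pairs).
#' @return list with `direction` (unit 3-vector) and `origin` (3-vector,
#'   snapshot units).
#' @export
armAxis <- function(snapshot, pairing, arm) {
  if (length(arm) < 2) stop("an arm needs at least 2 base pairs")
  mids <- .bp_midpoints(snapshot, pairing, arm)
  d <- .tls_direction(mids)
  k <- length(arm)
  half <- floor(k / 2)
  trend <- colMeans(mids[(k - half + 1):k, , drop = FALSE]) -
    colMeans(mids[1:half, , drop = FALSE])
  if (sum(trend * d) < 0) d <- -d
  list(direction = as.numeric(d), origin = colMeans(mids))
}

#' Position of a three-arm junction
#'
#' Default (`"centroid"`): centroid of the three arms' proximal base-pair
#' midpoints.  `"axes"`: least-squares intersection point of the three
#' total-least-squares arm axes, which recovers the exact junction point
#' of an idealized construction.
#'
#' @param snapshot a [Snapshot-class].
#' @param pairing a [BasePairMap-class].
#' @param junction a [JunctionSpec-class].
#' @param method `"centroid"` or `"axes"`.
#' @return 3-vector in snapshot units.
#' @export
junctionPosition <- function(snapshot, pairing, junction,
                             method = c("centroid", "axes")) {
  method <- match.arg(method)
  if (method == "centroid") {
    prox <- vapply(junction@arms,
                   function(a) .bp_midpoints(snapshot, pairing, a[1])[1, ],
                   numeric(3))
    return(rowMeans(prox))
  }
  axes <- lapply(junction@arms, function(a) armAxis(snapshot, pairing, a))
  .ls_line_intersection(
    origins = do.call(rbind, lapply(axes, `[[`, "origin")),
    dirs = do.call(rbind, lapply(axes, `[[`, "direction")))
}

#' Junction planarity metric d_p
#'
#' The distance from the junction point to the plane through the tips of
#' the three unit arm vectors drawn from it.  `d_p = 0` when the three
#' arms are coplanar; a uniform out-of-plane tilt phi of all three arms
#' gives `d_p = sin(phi)` exactly.  The metric is dimensionless (unit arm
#' vectors) and lies in `[0, 1)`.
#'
#' @param junctionPoint 3-vector.
#' @param e1,e2,e3 unit arm direction vectors.
#' @return dimensionless scalar.
#' @examples
#' planarityDp(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, -1, 0) / sqrt(2))
#' @export
planarityDp <- function(junctionPoint, e1, e2, e3) {
  for (e in list(e1, e2, e3)) {
    if (abs(sqrt(sum(e^2)) - 1) > 1e-6) stop("arm vectors must be unit length")
  }
  tips <- rbind(junctionPoint + e1, junctionPoint + e2, junctionPoint + e3)
  pl <- tryCatch(.plane_through3(tips[1, ], tips[2, ], tips[3, ]),
                 error = function(e) stop("degenerate plane: arm tips are collinear"))
  .point_plane_distance(junctionPoint, pl)
}

#' Junction planarity from a configuration
#'
#' Convenience wrapper: computes the three arm axes and the junction point
#' of a [JunctionSpec-class] and evaluates [planarityDp()].
#'
#' @inheritParams junctionPosition
#' @return dimensionless d_p.
#' @export
junctionPlanarity <- function(snapshot, pairing, junction,
                              method = c("centroid", "axes")) {
  axes <- lapply(junction@arms, function(a) {
    armAxis(snapshot, pairing, a)$direction
  })
  J <- junctionPosition(snapshot, pairing, junction, method = method)
  planarityDp(J, axes[[1]], axes[[2]], axes[[3]])
}

#' Angles between consecutive pairs of arm vectors
#'
#' For arm unit vectors named e1..e3 (junction 1) and/or e4..e6
#' (junction 2), returns the inter-arm angles `alpha_ij = acos(e_i . e_j)`
#' in degrees for the consecutive pairs (12, 13, 23) and (45, 46, 56).
#'
#' @param armAxes named list of unit 3-vectors (names among e1..e6).
#' @return named numeric vector of angles in degrees, names "alpha_ij".
#' @examples
#' interArmAngles(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0), e3 = c(0, 0, 1)))
#' @export
interArmAngles <- function(armAxes) {
  for (e in armAxes) {
    if (abs(sqrt(sum(e^2)) - 1) > 1e-6) {
      stop("arm vectors must be unit length within 1e-6")
    }
  }
  pairs <- list(c("e1", "e2"), c("e1", "e3"), c("e2", "e3"),
                c("e4", "e5"), c("e4", "e6"), c("e5", "e6"))
  out <- numeric(0)
  for (p in pairs) {
    if (all(p %in% names(armAxes))) {
      ang <- .angle_deg(armAxes[[p[1]]], armAxes[[p[2]]])
      out[paste0("alpha_", sub("e", "", p[1]), sub("e", "", p[2]))] <- ang
    }
  }
  out
}

#' Trailing-window equilibrium statistics of a metric series
#'
#' Mean and standard deviation over the trailing fraction of frames
#' ("late times" of a relaxation run).
#'
#' @param series a [MetricSeries-class].
#' @param lastFraction fraction of frames forming the trailing window
#'   (default 0.5).
#' @return the series with `equilibriumMean`, `equilibriumSd` and `window`
#'   filled in; read them with [equilibriumMean()] / [equilibriumSd()].
#' @export
equilibriumStats <- function(series, lastFraction = 0.5) {
  n <- length(series@values)
  k <- ceiling(lastFraction * n)
  if (k < 4) stop("too few frames in the equilibrium window (need >= 4)")
  idx <- (n - k + 1):n
  series@equilibriumMean <- mean(series@values[idx])
  series@equilibriumSd <- stats::sd(series@values[idx])
  series@window <- c(series@times[idx[1]], series@times[n])
  series
}

#' Planarity time series of a junction over a trajectory
#'
#' @param trajectory a [Trajectory-class].
#' @param pairing a [BasePairMap-class].
#' @param junction a [JunctionSpec-class].
#' @param method junction-point method, see [junctionPosition()].
#' @return a [MetricSeries-class] named `d_p<junctionId>`.
#' @export
planaritySeries <- function(trajectory, pairing, junction,
                            method = c("centroid", "axes")) {
  vals <- vapply(trajectory@snapshots, function(s) {
    junctionPlanarity(s, pairing, junction, method = method)
  }, numeric(1))
  MetricSeries(paste0("d_p", junction@junctionId),
               times = frameTimes(trajectory), values = vals,
               units = "dimensionless")
}

#' Pore quadrilateral corners and diagonals
#'
#' Resolves the four corner junctions X, Y, Z, W of a nanopore and returns
#' the two diagonals `|X - Z|` and `|Y - W|` in nanometers.  The default
#' corner resolution intersects the three arm axes of each corner
#' (`method = "axes"`), which recovers idealized corner points exactly.
#'
#' @param snapshot a [Snapshot-class].
#' @param pairing a [BasePairMap-class].
#' @param pore a [PoreSpec-class].
#' @param method junction-point method, see [junctionPosition()].
#' @return list with `diagXZNm`, `diagYWNm` and `corners` (4 x 3 matrix in
#'   nm, rows X, Y, Z, W).
#' @export
poreQuadrilateral <- function(snapshot, pairing, pore,
                              method = c("axes", "centroid")) {
  method <- match.arg(method)
  corners <- t(vapply(names(pore@corners), function(nm) {
    tryCatch(junctionPosition(snapshot, pairing, pore@corners[[nm]],
                              method = method),
             error = function(e) stop("cannot resolve pore corner ", nm, ": ",
                                      conditionMessage(e)))
  }, numeric(3)))
  corners_nm <- toNanometers(corners)
  list(diagXZNm = sqrt(sum((corners_nm["X", ] - corners_nm["Z", ])^2)),
       diagYWNm = sqrt(sum((corners_nm["Y", ] - corners_nm["W", ])^2)),
       corners = corners_nm)
}

#' Internal angles of the pore quadrilateral
#'
#' At each corner, the angle between the axes of the two arms internal to
#' the pore (those running along the adjacent pore sides).
#'
#' @inheritParams poreQuadrilateral
#' @return named numeric: angles alpha, beta, gamma, delta (degrees) at
#'   corners X, Y, Z, W.
#' @export
poreInternalAngles <- function(snapshot, pairing, pore) {
  greek <- c(X = "alpha", Y = "beta", Z = "gamma", W = "delta")
  out <- vapply(names(pore@corners), function(nm) {
    ia <- pore@internalArms[[nm]]
    if (length(ia) != 2) stop("missing internal-arm designation for corner ", nm)
    spec <- pore@corners[[nm]]
    a1 <- armAxis(snapshot, pairing, spec@arms[[ia[1]]])$direction
    a2 <- armAxis(snapshot, pairing, spec@arms[[ia[2]]])$direction
    .angle_deg(a1, a2)
  }, numeric(1))
  stats::setNames(out, greek[names(pore@corners)])
}

#' Planarity of a quadrilateral from corner-plane normals
#'
#' For each corner, the corner plane passes through the corner and its two
#' cyclic neighbors (plane (W, X, Y) for corner X and so on).  The metric
#' is the unsigned angle `acos(|n_a . n_b|)` between every pair of unit
#' corner-plane normals: a perfectly planar quadrilateral yields all six
#' angles equal to 0 degrees.
#'
#' @param corners 4 x 3 numeric matrix of corner positions in cyclic order
#'   (rows X, Y, Z, W).
#' @return named numeric(6): pairwise normal angles in degrees, in [0, 90].
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' cornerPlanePlanarity(sq)  # all zero
#' @export
cornerPlanePlanarity <- function(corners) {
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4, 3))) stop("corners must be a 4 x 3 matrix")
  nm <- rownames(corners)
  if (is.null(nm)) nm <- c("X", "Y", "Z", "W")
  normals <- matrix(NA_real_, 4, 3)
  for (i in 1:4) {
    prev <- corners[((i - 2) %% 4) + 1, ]
    this <- corners[i, ]
    nxt <- corners[(i %% 4) + 1, ]
    pl <- tryCatch(.plane_through3(prev, this, nxt), error = function(e) {
      stop(sprintf("collinear corner triple at corner %s", nm[i]))
    })
    normals[i, ] <- pl$normal
  }
  out <- numeric(0)
  for (i in 1:3) for (j in (i + 1):4) {
    ## unsigned angle via atan2 (accurate near coplanarity); folding the
    ## normal sign keeps the result in [0, 90]
    na <- normals[i, ]; nb <- normals[j, ]
    if (sum(na * nb) < 0) nb <- -nb
    ang <- atan2(sqrt(sum(.cross3(na, nb)^2)), sum(na * nb)) * 180 / pi
    out[paste0(nm[i], "-", nm[j])] <- ang
  }
  out
}
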