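#' @import methods
NULL

## ---------------------------------------------------------------------------
## Coarse-grained model containers (oxDNA-style)
## ---------------------------------------------------------------------------

#' Topology of a coarse-grained DNA system
#'
#' Strand connectivity at single-nucleotide resolution, mirroring the classic
#' oxDNA topology file: one record per nucleotide with its strand id, base
#' identity and intra-strand 3'/5' neighbors.  Indices are 1-based inside R
#' objects; file I/O converts to the 0-based oxDNA convention.
#'
#' @slot records data.frame with columns `strand` (integer, contiguous
#'   1..n_strands), `base` (one of A/C/G/T), `n3` and `n5` (integer index of
#'   the 3'/5' neighbor, `NA` at strand termini).
#' @export
setClass("Topology", representation(records = "data.frame"))

setValidity("Topology", function(object) {
  r <- object@records
  msg <- character()
  need <- c("strand", "base", "n3", "n5")
  if (!all(need %in% names(r))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  if (!all(r$base %in% c("A", "C", "G", "T"))) {
    msg <- c(msg, "bases must be A, C, G or T")
  }
  sid <- unique(r$strand)
  if (!identical(sort(sid), seq_along(sid))) {
    msg <- c(msg, "strand ids must form a contiguous 1..n_strands set")
  }
  n <- nrow(r)
  idx <- seq_len(n)
  if (any(r$n3 == idx | r$n5 == idx, na.rm = TRUE)) {
    msg <- c(msg, "a nucleotide cannot be its own neighbor")
  }
  has3 <- which(!is.na(r$n3))
  bad3 <- has3[r$n3[has3] < 1 | r$n3[has3] > n]
  has5 <- which(!is.na(r$n5))
  bad5 <- has5[r$n5[has5] < 1 | r$n5[has5] > n]
  if (length(bad3) || length(bad5)) {
    msg <- c(msg, "neighbor indices out of range")
  } else {
    ## reciprocal chain: i's 3' neighbor must name i as its 5' neighbor
    if (any(r$n5[r$n3[has3]] != has3, na.rm = TRUE) ||
        any(is.na(r$n5[r$n3[has3]]))) {
      msg <- c(msg, "inconsistent neighbor chain (3'/5' links not reciprocal)")
    }
    if (any(r$n3[r$n5[has5]] != has5, na.rm = TRUE) ||
        any(is.na(r$n3[r$n5[has5]]))) {
      msg <- c(msg, "inconsistent neighbor chain (5'/3' links not reciprocal)")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a Topology
#'
#' @param strand integer vector of strand ids (contiguous, 1-based).
#' @param base character vector of bases (A/C/G/T).
#' @param n3,n5 integer vectors of 3'/5' neighbor indices (`NA` for none).
#' @return a [Topology-class] object.
#' @export
Topology <- function(strand, base, n3, n5) {
  new("Topology", records = data.frame(
    strand = as.integer(strand), base = as.character(base),
    n3 = as.integer(n3), n5 = as.integer(n5)))
}

#' Single configuration frame of a coarse-grained system
#'
#' One oxDNA configuration block: simulation time (Brownian time units),
#' box lengths, energies and per-nucleotide position plus the two
#' orientation versors (`a1`, backbone-base axis; `a3`, stacking normal).
#' All lengths are in oxDNA simulation units (1 su = 0.8518 nm).
#'
#' @slot time numeric(1), frame time in Brownian time units.
#' @slot box numeric(3) box edge lengths, simulation units.
#' @slot energies numeric(3) total/potential/kinetic energies (0 if unknown).
#' @slot positions,a1,a3 n x 3 numeric matrices.
#' @slot velocities,angularVelocities n x 3 matrices, may be 0 x 3 when absent.
#' @export
setClass("Snapshot", representation(
  time = "numeric", box = "numeric", energies = "numeric",
  positions = "matrix", a1 = "matrix", a3 = "matrix",
  velocities = "matrix", angularVelocities = "matrix"))

setValidity("Snapshot", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (length(object@time) != 1L) msg <- c(msg, "time must be a scalar")
  if (length(object@box) != 3L) msg <- c(msg, "box must have 3 lengths")
  if (length(object@energies) != 3L) msg <- c(msg, "energies must have 3 values")
  for (nm in c("positions", "a1", "a3")) {
    m <- slot(object, nm)
    if (ncol(m) != 3L || nrow(m) != n) msg <- c(msg, sprintf("%s must be n x 3", nm))
  }
  for (nm in c("a1", "a3")) {
    m <- slot(object, nm)
    if (nrow(m) > 0) {
      norms <- sqrt(rowSums(m^2))
      if (any(abs(norms - 1) > 1e-6)) {
        msg <- c(msg, sprintf("%s versors must be unit length within 1e-6", nm))
      }
    }
  }
  for (nm in c("velocities", "angularVelocities")) {
    m <- slot(object, nm)
    if (nrow(m) != 0 && (nrow(m) != n || ncol(m) != 3L)) {
      msg <- c(msg, sprintf("%s must be empty or n x 3", nm))
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a Snapshot
#'
#' @param time frame time (Brownian time units).
#' @param box numeric(3) box lengths, simulation units.
#' @param positions,a1,a3 n x 3 matrices (simulation units / unit versors).
#' @param energies numeric(3), defaults to zeros.
#' @param velocities,angularVelocities optional n x 3 matrices.
#' @return a [Snapshot-class] object.
#' @export
Snapshot <- function(time, box, positions, a1, a3,
                     energies = c(0, 0, 0),
                     velocities = matrix(0, 0, 3),
                     angularVelocities = matrix(0, 0, 3)) {
  new("Snapshot", time = as.numeric(time), box = as.numeric(box),
      energies = as.numeric(energies),
      positions = as.matrix(positions), a1 = as.matrix(a1),
      a3 = as.matrix(a3), velocities = as.matrix(velocities),
      angularVelocities = as.matrix(angularVelocities))
}

#' Ordered set of configuration frames sharing one topology
#'
#' @slot topology a [Topology-class].
#' @slot snapshots list of [Snapshot-class] with strictly increasing times
#'   and record counts matching the topology.
#' @export
setClass("Trajectory", representation(topology = "Topology", snapshots = "list"))

setValidity("Trajectory", function(object) {
  n <- nrow(object@topology@records)
  msg <- character()
  if (!all(vapply(object@snapshots, is, logical(1), "Snapshot"))) {
    return("snapshots must all be Snapshot objects")
  }
  counts <- vapply(object@snapshots, function(s) nrow(s@positions), integer(1))
  if (any(counts != n)) msg <- c(msg, "snapshot record counts must match topology")
  tt <- vapply(object@snapshots, function(s) s@time, numeric(1))
  if (length(tt) > 1 && any(diff(tt) <= 0)) {
    msg <- c(msg, "snapshot times must be strictly increasing")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a Trajectory
#' @param topology a [Topology-class].
#' @param snapshots list of [Snapshot-class] objects, times strictly increasing.
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(topology, snapshots) {
  new("Trajectory", topology = topology, snapshots = snapshots)
}

#' Watson-Crick base-pair assignment
#'
#' Set of unordered nucleotide index pairs flagged as paired, with a record
#' of how the pairing was obtained (`"design"` from domain complementarity,
#' `"geometric"` from distance/orientation criteria, or `"ground-truth"`
#' from a synthetic generator).
#'
#' @slot pairs integer matrix, one row per pair (1-based nucleotide indices).
#' @slot provenance character(1).
#' @export
setClass("BasePairMap", representation(pairs = "matrix", provenance = "character"))

setValidity("BasePairMap", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must be an n x 2 matrix")
  if (nrow(p) && any(duplicated(as.vector(p)))) {
    return("a nucleotide may appear in at most one pair")
  }
  TRUE
})

#' Construct a BasePairMap
#' @param pairs integer n x 2 matrix of paired nucleotide indices (1-based).
#' @param provenance one of "design", "geometric", "ground-truth".
#' @return a [BasePairMap-class] object.
#' @export
BasePairMap <- function(pairs, provenance = "design") {
  p <- matrix(as.integer(pairs), ncol = 2)
  new("BasePairMap", pairs = p, provenance = provenance)
}

## ---------------------------------------------------------------------------
## Design-side containers
## ---------------------------------------------------------------------------

#' F-unit design
#'
#' The minimal nanosheet assembly unit built from three strands A, B and C:
#' one core duplex (A:B), four arm duplexes (A:C or B:C) and four
#' single-stranded sticky ends (SE1/SE1*, SE2/SE2*) whose hybridization
#' links units into a porous two-dimensional lattice.  Hydrophobic
#' (cholesterol) anchors sit at the 3' termini of the C strands.
#'
#' @slot coreBp,armBp,seBp base-pair counts of core, arm and sticky-end
#'   duplexes (defaults 21, 16, 10).
#' @slot riseNm helical rise per base pair, nm (default 0.34).
#' @slot duplexWidthNm duplex diameter, nm (default 2.0).
#' @slot sequences named list with elements `A`, `B`, `C` (character DNA
#'   sequences) or an empty list when sequences are not specified.
#' @slot stoichiometry numeric(3) concentration ratios (m, n, p) for strands
#'   A:B:C, or numeric(0) if unspecified.  The design rule is m = n and
#'   p = 10 m.
#' @slot cholesterolSites data.frame with columns `strand`, `terminus`.
#' @export
setClass("FUnitDesign", representation(
  coreBp = "numeric", armBp = "numeric", seBp = "numeric",
  riseNm = "numeric", duplexWidthNm = "numeric",
  sequences = "list", stoichiometry = "numeric",
  cholesterolSites = "data.frame"))

setValidity("FUnitDesign", function(object) {
  msg <- character()
  for (nm in c("coreBp", "armBp", "seBp")) {
    v <- slot(object, nm)
    if (length(v) != 1 || v < 1 || v != round(v)) {
      msg <- c(msg, sprintf("%s must be a positive integer count", nm))
    }
  }
  if (object@riseNm < 0) msg <- c(msg, "riseNm must be non-negative")
  if (object@duplexWidthNm <= 0) msg <- c(msg, "duplexWidthNm must be positive")
  if (length(object@stoichiometry) &&
      length(object@stoichiometry) != 3) {
    msg <- c(msg, "stoichiometry must have 3 entries (m, n, p)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Annealing temperature schedule
#'
#' Stepwise temperature protocol; ramp segments ("-1 degC / 5 min") are
#' expanded into 1-degree holds so the schedule is a flat list of
#' (temperature, duration) steps whose total time equals the protocol time.
#'
#' @slot name protocol label ("FAP-A", "FAP-B", "FAP-C", "SAP-A", "SAP-B"
#'   or "custom").
#' @slot steps data.frame with columns `temperatureC`, `durationMin`.
#' @export
setClass("AnnealingProtocol", representation(name = "character", steps = "data.frame"))

setValidity("AnnealingProtocol", function(object) {
  s <- object@steps
  if (!all(c("temperatureC", "durationMin") %in% names(s))) {
    return("steps must have columns temperatureC and durationMin")
  }
  if (nrow(s) && any(s$durationMin <= 0)) return("durations must be positive")
  TRUE
})

#' Per-domain duplex melting temperatures
#'
#' @slot tmCore,tmArm,tmSe1,tmSe2 melting temperatures, degrees C.
#' @slot conditions named list: `strandConcM` (total strand concentration,
#'   molar), `monovalentM`, `divalentM` (salt concentrations, molar).
#' @export
setClass("DomainTmSet", representation(
  tmCore = "numeric", tmArm = "numeric", tmSe1 = "numeric", tmSe2 = "numeric",
  conditions = "list"))

setValidity("DomainTmSet", function(object) {
  tms <- c(object@tmCore, object@tmArm, object@tmSe1, object@tmSe2)
  if (any(!is.finite(tms))) return("melting temperatures must be finite")
  cn <- object@conditions
  if (any(unlist(cn[c("strandConcM", "monovalentM")]) <= 0)) {
    return("strand and monovalent salt concentrations must be positive")
  }
  TRUE
})

#' Idealized nanopore lattice geometry
#'
#' Parallelogram unit-cell geometry of the nanosheet lattice implied by the
#' F-unit design: contour side lengths in base pairs and nanometers, the
#' junction angle between adjacent sides, the two pore diagonals, and the
#' open-area (porosity) fraction.
#'
#' @slot sideLongBp,sideShortBp contour lengths of the two sides, base pairs.
#' @slot sideLongNm,sideShortNm side lengths, nm (bp x rise).
#' @slot junctionAngleDeg angle between adjacent sides, degrees.
#' @slot diagLongNm,diagShortNm parallelogram diagonals, nm.
#' @slot porosityFraction open-area fraction of the unit cell (0..1).
#' @export
setClass("LatticeGeometry", representation(
  sideLongBp = "numeric", sideShortBp = "numeric",
  sideLongNm = "numeric", sideShortNm = "numeric",
  junctionAngleDeg = "numeric",
  diagLongNm = "numeric", diagShortNm = "numeric",
  porosityFraction = "numeric"))

setValidity("LatticeGeometry", function(object) {
  msg <- character()
  if (object@junctionAngleDeg <= 0 || object@junctionAngleDeg >= 180) {
    msg <- c(msg, "junction angle must lie in (0, 180) degrees")
  }
  if (length(object@porosityFraction) && is.finite(object@porosityFraction) &&
      (object@porosityFraction < 0 || object@porosityFraction >= 1)) {
    msg <- c(msg, "porosity must lie in [0, 1)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Idealized F-unit center-line model
#'
#' Segment center-lines (core, four arms, four sticky-end stubs), the two
#' junction points, unit arm direction vectors and cholesterol attachment
#' coordinates, all in nanometers.
#'
#' @slot segments named list of 2 x 3 matrices (segment endpoints, nm).
#' @slot junctions 2 x 3 matrix with rows J1, J2.
#' @slot armDirections named list of unit 3-vectors (e1, e2, e3 at J1;
#'   e4, e5, e6 at J2; e3/e6 point along the core).
#' @slot cholesterolSites named list of 3-vectors (attachment coordinates).
#' @export
setClass("IdealUnitModel", representation(
  segments = "list", junctions = "matrix",
  armDirections = "list", cholesterolSites = "list"))

## ---------------------------------------------------------------------------
## Metric extraction specs and series
## ---------------------------------------------------------------------------

#' Index map defining a three-arm junction
#'
#' Maps a junction of an F-unit to nucleotide indices: three ordered arm
#' index lists (proximal to distal, indices of the reference strand whose
#' base-pair partners are resolved through a [BasePairMap-class]).
#'
#' @slot junctionId integer label (1 or 2).
#' @slot arms named list of three integer vectors; names follow the arm
#'   labels (e1, e2, e3 for junction 1; e4, e5, e6 for junction 2).
#' @slot cholesterolProximal named logical, one flag per arm.
#' @export
setClass("JunctionSpec", representation(
  junctionId = "numeric", arms = "list", cholesterolProximal = "logical"))

setValidity("JunctionSpec", function(object) {
  msg <- character()
  if (length(object@arms) != 3) msg <- c(msg, "a junction has exactly three arms")
  lens <- lengths(object@arms)
  if (any(lens < 2)) msg <- c(msg, "each arm needs at least 2 base pairs")
  all_idx <- unlist(object@arms)
  if (any(duplicated(all_idx))) msg <- c(msg, "arms must be disjoint")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a JunctionSpec
#' @param junctionId integer label.
#' @param arms named list of three integer index vectors (proximal to distal).
#' @param cholesterolProximal named logical flags per arm.
#' @return a [JunctionSpec-class] object.
#' @export
JunctionSpec <- function(junctionId, arms, cholesterolProximal = NULL) {
  if (is.null(cholesterolProximal)) {
    cholesterolProximal <- stats::setNames(rep(NA, length(arms)), names(arms))
  }
  new("JunctionSpec", junctionId = junctionId, arms = arms,
      cholesterolProximal = as.logical(cholesterolProximal))
}

#' Index map defining a nanopore quadrilateral
#'
#' Four junction specs in cyclic order (corners X, Y, Z, W of the pore) and,
#' per corner, the two arms internal to the pore (those running along the
#' adjacent pore sides).
#'
#' @slot corners named list of four [JunctionSpec-class] (X, Y, Z, W).
#' @slot internalArms named list; per corner, character(2) naming the two
#'   pore-internal arms of that corner's spec.
#' @export
setClass("PoreSpec", representation(corners = "list", internalArms = "list"))

setValidity("PoreSpec", function(object) {
  if (!identical(names(object@corners), c("X", "Y", "Z", "W"))) {
    return("corners must be named X, Y, Z, W in cyclic order")
  }
  for (nm in names(object@corners)) {
    spec <- object@corners[[nm]]
    ia <- object@internalArms[[nm]]
    if (length(ia) != 2 || !all(ia %in% names(spec@arms))) {
      return(sprintf("corner %s: internal arms must name 2 arms of its spec", nm))
    }
  }
  TRUE
})

#' Construct a PoreSpec
#' @param corners named list of four [JunctionSpec-class] (X, Y, Z, W).
#' @param internalArms named list of character(2) per corner.
#' @return a [PoreSpec-class] object.
#' @export
PoreSpec <- function(corners, internalArms) {
  new("PoreSpec", corners = corners, internalArms = internalArms)
}

#' Per-frame metric time series with equilibrium statistics
#'
#' @slot metric metric name (e.g. "d_p1", "alpha_12", "diag_XZ").
#' @slot times frame times, Brownian time units.
#' @slot values metric values.
#' @slot units one of "dimensionless", "degrees", "nm".
#' @slot equilibriumMean,equilibriumSd trailing-window statistics (NA until
#'   computed with [equilibriumStats()]).
#' @slot window numeric(2) time window used for the equilibrium statistics.
#' @export
setClass("MetricSeries", representation(
  metric = "character", times = "numeric", values = "numeric",
  units = "character", equilibriumMean = "numeric",
  equilibriumSd = "numeric", window = "numeric"))

setValidity("MetricSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values)) {
    msg <- c(msg, "times and values must have equal length")
  }
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a MetricSeries
#' @param metric metric name.
#' @param times,values numeric vectors of equal length.
#' @param units unit string.
#' @return a [MetricSeries-class] object.
#' @export
MetricSeries <- function(metric, times, values, units = "dimensionless") {
  new("MetricSeries", metric = metric, times = as.numeric(times),
      values = as.numeric(values), units = units,
      equilibriumMean = NA_real_, equilibriumSd = NA_real_,
      window = c(NA_real_, NA_real_))
}

#' One-dimensional AFM-style height profile
#'
#' @slot positions sample positions along the scan line, nm, uniformly spaced.
#' @slot heights measured heights, nm.
#' @slot pixelSize sample spacing, nm.
#' @export
setClass("HeightProfile", representation(
  positions = "numeric", heights = "numeric", pixelSize = "numeric"))

setValidity("HeightProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@heights)) {
    msg <- c(msg, "positions and heights must have equal length")
  }
  d <- diff(object@positions)
  if (any(d <= 0)) msg <- c(msg, "positions must be increasing")
  if (length(d) && (max(d) - min(d)) > 1e-6) {
    msg <- c(msg, "sampling must be uniform within 1e-6 nm")
  }
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a positive scalar")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a HeightProfile
#' @param positions,heights numeric vectors (nm); positions uniformly spaced.
#' @param pixelSize sample spacing in nm (defaults to the median spacing).
#' @return a [HeightProfile-class] object.
#' @export
HeightProfile <- function(positions, heights, pixelSize = stats::median(diff(positions))) {
  new("HeightProfile", positions = as.numeric(positions),
      heights = as.numeric(heights), pixelSize = pixelSize)
}

## ---------------------------------------------------------------------------
## Interfacial mechanics containers
## ---------------------------------------------------------------------------

#' Interfacial shear rheology time sweep
#'
#' @slot data data.frame with columns `time` (s), `storageModulus` and
#'   `lossModulus` (interfacial G' and G'', N/m), `temperature` (degC), and
#'   optionally `frequency` (Hz), `strain` (fraction), `phase` (labels).
#' @export
setClass("RheologySweep", representation(data = "data.frame"))

setValidity("RheologySweep", function(object) {
  d <- object@data
  need <- c("time", "storageModulus", "lossModulus", "temperature")
  if (!all(need %in% names(d))) {
    return(paste("data must have columns", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (any(d$storageModulus < 0) || any(d$lossModulus < 0)) {
    msg <- c(msg, "moduli must be non-negative")
  }
  if (nrow(d) > 1 && any(diff(d$time) <= 0)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a RheologySweep
#' @param data data.frame with at least `time`, `storageModulus`,
#'   `lossModulus`, `temperature` columns.
#' @return a [RheologySweep-class] object.
#' @export
RheologySweep <- function(data) new("RheologySweep", data = data)

#' Parameters for interfacial-to-bulk modulus extrapolation
#'
#' @slot thicknessNm nanosheet thickness t in nm (default 2, one duplex
#'   diameter).
#' @slot poissonRatio Poisson's ratio nu (default 0.5, incompressible).
#' @slot porosityFraction open-area fraction phi used for the load-bearing
#'   correction (default 0.40).
#' @export
setClass("ExtrapolationParams", representation(
  thicknessNm = "numeric", poissonRatio = "numeric", porosityFraction = "numeric"))

setValidity("ExtrapolationParams", function(object) {
  msg <- character()
  if (object@thicknessNm <= 0) msg <- c(msg, "thickness must be positive")
  if (object@poissonRatio < 0 || object@poissonRatio > 0.5) {
    msg <- c(msg, "Poisson ratio must lie in [0, 0.5]")
  }
  if (object@porosityFraction < 0 || object@porosityFraction >= 1) {
    msg <- c(msg, "porosity must lie in [0, 1)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct ExtrapolationParams
#' @param thicknessNm sheet thickness, nm.
#' @param poissonRatio Poisson's ratio.
#' @param porosityFraction open-area fraction.
#' @return an [ExtrapolationParams-class] object.
#' @export
ExtrapolationParams <- function(thicknessNm = 2, poissonRatio = 0.5,
                                porosityFraction = 0.40) {
  new("ExtrapolationParams", thicknessNm = thicknessNm,
      poissonRatio = poissonRatio, porosityFraction = porosityFraction)
}

#' Result of interfacial-to-bulk modulus extrapolation
#'
#' @slot interfacialModulus input interfacial storage modulus, N/m.
#' @slot bulkYoungModulusPa sheet-average Young's modulus, Pa.
#' @slot porosityCorrectedModulusPa per-unit (load-bearing) Young's modulus
#'   lower bound, Pa.
#' @slot params the [ExtrapolationParams-class] used.
#' @export
setClass("ExtrapolationResult", representation(
  interfacialModulus = "numeric", bulkYoungModulusPa = "numeric",
  porosityCorrectedModulusPa = "numeric", params = "ExtrapolationParams"))

setValidity("ExtrapolationResult", function(object) {
  if (object@params@porosityFraction > 0 &&
      object@porosityCorrectedModulusPa < object@bulkYoungModulusPa) {
    return("porosity-corrected modulus must be >= bulk modulus when phi > 0")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Pipeline containers
## ---------------------------------------------------------------------------

#' Structured report of a pipeline run
#'
#' @slot command the pipeline command that produced the report.
#' @slot sections named list of per-stage result blocks; every numeric entry
#'   carries a unit in its name or an accompanying `units` field.
#' @slot provenance named list (config hash, seed, package version).
#' @export
setClass("RunReport", representation(
  command = "character", sections = "list", provenance = "list"))
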