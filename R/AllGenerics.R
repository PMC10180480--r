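#' @name sheetkit-accessors
#' @title Accessors for sheetkit classes
#' @description Accessor generics for the package's S4 containers.
#' @param x an object.
#' @param object an object (for show methods).
#' @return the requested component.
NULL

#' @rdname sheetkit-accessors
#' @export
setGeneric("nNucleotides", function(x) standardGeneric("nNucleotides"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("nStrands", function(x) standardGeneric("nStrands"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("strandIds", function(x) standardGeneric("strandIds"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("a1Versors", function(x) standardGeneric("a1Versors"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("a3Versors", function(x) standardGeneric("a3Versors"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("getSnapshot", function(x, i) standardGeneric("getSnapshot"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("pairedIndices", function(x) standardGeneric("pairedIndices"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("metricTimes", function(x) standardGeneric("metricTimes"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("equilibriumMean", function(x) standardGeneric("equilibriumMean"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("equilibriumSd", function(x) standardGeneric("equilibriumSd"))

#' @rdname sheetkit-accessors
#' @export
setGeneric("sweepData", function(x) standardGeneric("sweepData"))

## ---- methods ----

#' @rdname sheetkit-accessors
setMethod("nNucleotides", "Topology", function(x) nrow(x@records))

#' @rdname sheetkit-accessors
setMethod("nStrands", "Topology", function(x) length(unique(x@records$strand)))

#' @rdname sheetkit-accessors
setMethod("strandIds", "Topology", function(x) x@records$strand)

#' @rdname sheetkit-accessors
setMethod("positions", "Snapshot", function(x) x@positions)

#' @rdname sheetkit-accessors
setMethod("a1Versors", "Snapshot", function(x) x@a1)

#' @rdname sheetkit-accessors
setMethod("a3Versors", "Snapshot", function(x) x@a3)

#' @rdname sheetkit-accessors
setMethod("frameTime", "Snapshot", function(x) x@time)

#' @rdname sheetkit-accessors
setMethod("nFrames", "Trajectory", function(x) length(x@snapshots))

#' @rdname sheetkit-accessors
setMethod("frameTimes", "Trajectory",
          function(x) vapply(x@snapshots, function(s) s@time, numeric(1)))

#' @rdname sheetkit-accessors
setMethod("getSnapshot", "Trajectory", function(x, i) x@snapshots[[i]])

#' @rdname sheetkit-accessors
setMethod("pairedIndices", "BasePairMap", function(x) x@pairs)

#' @rdname sheetkit-accessors
setMethod("metricTimes", "MetricSeries", function(x) x@times)

#' @rdname sheetkit-accessors
setMethod("metricValues", "MetricSeries", function(x) x@values)

#' @rdname sheetkit-accessors
setMethod("equilibriumMean", "MetricSeries", function(x) x@equilibriumMean)

#' @rdname sheetkit-accessors
setMethod("equilibriumSd", "MetricSeries", function(x) x@equilibriumSd)

#' @rdname sheetkit-accessors
setMethod("sweepData", "RheologySweep", function(x) x@data)

## ---- show methods ----

#' @rdname sheetkit-accessors
setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d nucleotides in %d strand(s)\n",
              nNucleotides(object), nStrands(object)))
  lens <- table(object@records$strand)
  cat("  strand lengths:", paste(as.integer(lens), collapse = ", "), "\n")
})

#' @rdname sheetkit-accessors
setMethod("show", "Snapshot", function(object) {
  cat(sprintf("Snapshot at t = %g tau_B: %d nucleotides, box %s (su)\n",
              object@time, nrow(object@positions),
              paste(signif(object@box, 4), collapse = " x ")))
})

#' @rdname sheetkit-accessors
setMethod("show", "Trajectory", function(object) {
  tt <- frameTimes(object)
  cat(sprintf("Trajectory: %d frame(s), t = %g..%g tau_B, %d nucleotides\n",
              length(tt), min(tt), max(tt), nNucleotides(object@topology)))
})

#' @rdname sheetkit-accessors
setMethod("show", "BasePairMap", function(object) {
  cat(sprintf("BasePairMap (%s): %d pairs\n", object@provenance, nrow(object@pairs)))
})

#' @rdname sheetkit-accessors
setMethod("show", "FUnitDesign", function(object) {
  cat(sprintf("FUnitDesign: core %d bp, arms %d bp, sticky ends %d bp\n",
              object@coreBp, object@armBp, object@seBp))
  cat(sprintf("  rise %.2f nm/bp, duplex width %.1f nm\n",
              object@riseNm, object@duplexWidthNm))
  if (length(object@stoichiometry)) {
    cat("  stoichiometry A:B:C =",
        paste(object@stoichiometry, collapse = ":"), "\n")
  }
  cat("  sequences:", if (length(object@sequences)) "set" else "unset", "\n")
})

#' @rdname sheetkit-accessors
setMethod("show", "AnnealingProtocol", function(object) {
  cat(sprintf("AnnealingProtocol %s: %d steps, total %.0f min\n",
              object@name, nrow(object@steps), sum(object@steps$durationMin)))
})

#' @rdname sheetkit-accessors
setMethod("show", "DomainTmSet", function(object) {
  cat(sprintf("DomainTmSet (degC): core %.1f, arm %.1f, SE1 %.1f, SE2 %.1f\n",
              object@tmCore, object@tmArm, object@tmSe1, object@tmSe2))
})

#' @rdname sheetkit-accessors
setMethod("show", "LatticeGeometry", function(object) {
  cat(sprintf("LatticeGeometry: sides %d bp (%.2f nm) / %d bp (%.2f nm), theta %.1f deg\n",
              object@sideLongBp, object@sideLongNm,
              object@sideShortBp, object@sideShortNm, object@junctionAngleDeg))
  cat(sprintf("  diagonals %.2f / %.2f nm", object@diagLongNm, object@diagShortNm))
  if (length(object@porosityFraction) && is.finite(object@porosityFraction)) {
    cat(sprintf(", porosity %.1f%%", 100 * object@porosityFraction))
  }
  cat("\n")
})

#' @rdname sheetkit-accessors
setMethod("show", "MetricSeries", function(object) {
  cat(sprintf("MetricSeries '%s' (%s): %d frames",
              object@metric, object@units, length(object@times)))
  if (is.finite(object@equilibriumMean)) {
    cat(sprintf(", equilibrium %.4g +/- %.2g", object@equilibriumMean,
                object@equilibriumSd))
  }
  cat("\n")
})

#' @rdname sheetkit-accessors
setMethod("show", "HeightProfile", function(object) {
  cat(sprintf("HeightProfile: %d samples over %.1f nm (pixel %.2f nm)\n",
              length(object@positions), diff(range(object@positions)),
              object@pixelSize))
})

#' @rdname sheetkit-accessors
setMethod("show", "RheologySweep", function(object) {
  d <- object@data
  cat(sprintf("RheologySweep: %d points, t = %.0f..%.0f s, G' %.3g..%.3g N/m\n",
              nrow(d), min(d$time), max(d$time),
              min(d$storageModulus), max(d$storageModulus)))
})

#' @rdname sheetkit-accessors
setMethod("show", "ExtrapolationResult", function(object) {
  cat(sprintf(
    "ExtrapolationResult: G' = %.3g N/m -> E = %.1f MPa (sheet), >= %.1f MPa (per unit)\n",
    object@interfacialModulus, object@bulkYoungModulusPa / 1e6,
    object@porosityCorrectedModulusPa / 1e6))
  p <- object@params
  cat(sprintf("  t = %g nm, nu = %g, porosity = %g\n",
              p@thicknessNm, p@poissonRatio, p@porosityFraction))
})

#' @rdname sheetkit-accessors
setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport for command '%s': sections %s\n", object@command,
              paste(names(object@sections), collapse = ", ")))
})
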