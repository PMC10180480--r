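## Physical constants used throughout the package.  Kept in one table so a
## change propagates everywhere.
.sheetkit_const <- list(
  ## oxDNA simulation length unit expressed in nanometers
  oxdna_length_nm = 0.8518,
  ## helical rise of B-form DNA per base pair, nm
  rise_nm         = 0.34,
  ## diameter of a B-form duplex, nm
  duplex_width_nm = 2.0,
  ## center-of-mass separation of a bound base pair in the coarse-grained
  ## model, nm (beads sit on a helix of this diameter about the axis)
  pair_separation_nm = 0.7,
  ## helical twist per base pair, degrees
  twist_deg_per_bp = 34.3,
  ## gas constant, cal / (mol K) -- nearest-neighbor thermodynamics
  gas_constant    = 1.987
)

#' Convert oxDNA simulation length units to nanometers
#'
#' oxDNA expresses all lengths in its own simulation unit
#' (1 su = 0.8518 nm).  The conversion is linear and applies
#' component-wise to vectors and matrices.
#'
#' @param x numeric scalar, vector or matrix in simulation units.
#' @return `x` scaled to nanometers.
#' @examples
#' toNanometers(1)        # 0.8518
#' toNanometers(c(1, 2, 3))
#' @export
toNanometers <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * .sheetkit_const$oxdna_length_nm
}

#' Convert nanometers to oxDNA simulation length units
#'
#' Inverse of [toNanometers()].
#'
#' @param x numeric scalar, vector or matrix in nanometers.
#' @return `x` scaled to simulation units.
#' @export
fromNanometers <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x / .sheetkit_const$oxdna_length_nm
}
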