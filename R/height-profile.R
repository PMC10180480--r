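## 1-D AFM-style height profile analysis: pore detection, pore spacing and
## discrete duplex-layer quantization.

## Local maxima of a signal with a prominence criterion (plateaus collapse
## to their central sample).  Prominence of a peak: height above the larger
## of the two minima separating it from the nearest higher terrain (or the
## signal edge) on each side.
.find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ## candidate maxima, collapsing flat tops
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]
    ## walk left to previous strictly-higher sample (or edge)
    lv <- x[seq_len(p - 1L)]
    higher <- which(lv > x[p])
    lmin <- if (length(higher)) min(x[(max(higher) + 1L):(p - 1L)]) else min(lv)
    rv <- x[(p + 1L):n]
    higher <- which(rv > x[p])
    rmin <- if (length(higher)) min(x[(p + 1L):(p + min(higher) - 1L)]) else min(rv)
    keep[k] <- (x[p] - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

#' Number of discrete duplex layers implied by a plateau height
#'
#' @param heightNm plateau height(s), nm.
#' @param layerHeightNm height of one duplex layer, nm (default 2).
#' @return integer layer count(s), `round(height / layerHeight)`, floored
#'   at zero.
#' @examples
#' layerCount(c(1.8, 4.1))  # 1, 2
#' @export
layerCount <- function(heightNm, layerHeightNm = 2.0) {
  pmax(0L, as.integer(round(heightNm / layerHeightNm)))
}

#' Analyze a 1-D height profile for pore spacing and layer thickness
#'
#' Detects pores as prominent local extrema of the profile (by default,
#' dips: local maxima of the inverted signal) using a prominence threshold
#' of half a duplex layer, reports the mean and standard deviation of
#' consecutive pore spacings, and quantizes the plateau segments between
#' pores into discrete duplex layer counts.
#'
#' @param profile a [HeightProfile-class].
#' @param layerHeightNm duplex layer height, nm (default 2).
#' @param minProminenceNm detection prominence threshold, nm (default
#'   half the layer height).
#' @param mode `"dips"` (pores are depressions, default) or `"peaks"`.
#' @return list with `peakPositionsNm`, `meanSpacingNm`, `sdSpacingNm`,
#'   `layerCounts` (one per plateau segment) and `segments` (data.frame of
#'   segment bounds and plateau heights).
#' @export
analyzeHeightProfile <- function(profile, layerHeightNm = 2.0,
                                 minProminenceNm = 0.5 * layerHeightNm,
                                 mode = c("dips", "peaks")) {
  mode <- match.arg(mode)
  if (length(profile@heights) < 3) stop("profile needs at least 3 samples")
  h <- profile@heights
  sig <- if (mode == "dips") max(h) - h else h
  pk <- .find_peaks(sig, minProminenceNm)
  pos <- profile@positions[pk]
  spacing <- diff(pos)
  ## plateau segments between consecutive detected pores (plus the edges)
  bounds <- c(1L, pk, length(h))
  seg <- data.frame(fromNm = numeric(0), toNm = numeric(0),
                    heightNm = numeric(0), layers = integer(0))
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (hi - lo < 2) next
    inner <- lo:hi
    ## central half of the segment avoids the pore walls
    q <- stats::quantile(inner, c(0.3, 0.7), type = 1)
    core_idx <- q[1]:q[2]
    hplat <- stats::median(h[core_idx])
    seg <- rbind(seg, data.frame(
      fromNm = profile@positions[lo], toNm = profile@positions[hi],
      heightNm = hplat, layers = layerCount(hplat, layerHeightNm)))
  }
  list(peakPositionsNm = pos,
       meanSpacingNm = if (length(spacing)) mean(spacing) else NA_real_,
       sdSpacingNm = if (length(spacing) > 1) stats::sd(spacing) else NA_real_,
       layerCounts = seg$layers,
       segments = seg)
}

#' Read a height profile from a delimited table
#'
#' @param path CSV file with columns `position_nm`, `height_nm`.
#' @return a [HeightProfile-class].
#' @export
readHeightProfile <- function(path) {
  d <- utils::read.csv(path)
  need <- c("position_nm", "height_nm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("height profile column absent: ", paste(miss, collapse = ", "))
  HeightProfile(d$position_nm, d$height_nm)
}

#' Write a height profile to CSV
#'
#' @param profile a [HeightProfile-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeHeightProfile <- function(profile, path) {
  utils::write.csv(data.frame(position_nm = profile@positions,
                              height_nm = profile@heights),
                   path, row.names = FALSE)
  invisible(path)
}
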