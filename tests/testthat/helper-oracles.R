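## Independent oracles and small utilities used across the test files.
## Each oracle is coded independently of the implementation path it checks.

## Brute-force point-to-plane distance: fit the plane n . x = 1 through the
## three tip points by solving a linear system (no cross products), then
## evaluate the normalized residual at the query point.
brute_dp <- function(J, e1, e2, e3) {
  tips <- rbind(J + e1, J + e2, J + e3)
  n <- solve(tips, c(1, 1, 1))
  abs(sum(n * J) - 1) / sqrt(sum(n^2))
}

## Independent nearest-neighbor Tm: dinucleotide counting via substring
## tabulation against the same published parameter table, recombined with
## the two-state formula written out again from scratch.
brute_tm <- function(seq, ct_M = 1e-6, na_M = 0.15) {
  dH_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
              CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
              CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
              CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
              CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
              CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
              CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  n <- nchar(seq)
  dimers <- substring(seq, 1:(n - 1), 2:n)
  counts <- table(factor(dimers, levels = names(dH_tab)))
  dH <- sum(counts * dH_tab)
  dS <- sum(counts * dS_tab)
  ends <- substring(seq, c(1, n), c(1, n))
  dH <- dH + sum(ifelse(ends %in% c("A", "T"), 2.3, 0.1))
  dS <- dS + sum(ifelse(ends %in% c("A", "T"), 4.1, -2.8))
  dS <- dS + 0.368 * (n - 1) * log(na_M)
  1000 * dH / (dS + 1.987 * log(ct_M / 4)) - 273.15
}

## Minute-by-minute brute-force scan of an annealing schedule: the binding
## event of a domain is the first minute at or below its Tm.
brute_schedule_scan <- function(tm, protocol) {
  steps <- protocol@steps
  temps <- rep(steps$temperatureC, steps$durationMin)  # one entry per minute
  minutes <- seq_along(temps) - 1
  hit <- which(temps <= tm)[1]
  if (is.na(hit)) NA_real_ else minutes[hit]
}

## Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Apply a rigid motion to a Snapshot.
transform_snapshot <- function(snapshot, R = diag(3), shift = c(0, 0, 0)) {
  s <- snapshot
  s@positions <- sweep(s@positions %*% t(R), 2, shift, "+")
  s@a1 <- s@a1 %*% t(R)
  s@a3 <- s@a3 %*% t(R)
  s
}

## Canonical form of a base-pair matrix for set comparison.
canon_pairs <- function(p) {
  p <- t(apply(p, 1, sort))
  p[order(p[, 1]), , drop = FALSE]
}

default_design <- function() FUnitDesign()
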