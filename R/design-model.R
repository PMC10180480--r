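#' Construct an F-unit design
#'
#' Default values encode the nanosheet design: a 21-bp core, 16-bp arms and
#' 10-bp sticky ends, B-form rise 0.34 nm/bp, duplex width 2 nm, strand
#' stoichiometry A:B:C = 1:1:10 and one cholesterol anchor at the 3' end of
#' each of the four C strands.
#'
#' @param coreBp,armBp,seBp duplex lengths in base pairs.
#' @param riseNm helical rise per base pair, nm.
#' @param duplexWidthNm duplex diameter, nm.
#' @param sequences named list with strands `A`, `B`, `C`, or `NULL`.
#' @param stoichiometry numeric(3) concentration ratios (m, n, p).
#' @param cholesterolSites data.frame(strand, terminus).
#' @return a [FUnitDesign-class] object.
#' @examples
#' d <- FUnitDesign()
#' validateDesign(d)
#' @export
FUnitDesign <- function(coreBp = 21, armBp = 16, seBp = 10,
                        riseNm = 0.34, duplexWidthNm = 2.0,
                        sequences = NULL, stoichiometry = c(1, 1, 10),
                        cholesterolSites = data.frame(
                          strand = paste0("C", 1:4), terminus = "3prime")) {
  new("FUnitDesign", coreBp = coreBp, armBp = armBp, seBp = seBp,
      riseNm = riseNm, duplexWidthNm = duplexWidthNm,
      sequences = if (is.null(sequences)) list() else sequences,
      stoichiometry = if (is.null(stoichiometry)) numeric(0) else stoichiometry,
      cholesterolSites = cholesterolSites)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Random sequence of length n with an exact GC count (balanced by default)
.random_domain <- function(n, gc_fraction = 0.5) {
  n_gc <- round(gc_fraction * n)
  letters <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste(sample(letters), collapse = "")
}

#' Generate placeholder strand sequences for a design
#'
#' Draws GC-balanced random domain sequences (core, arm, SE1, SE2) and
#' assembles the three strands with the complementarity the design requires:
#' A = SE1 + arm + core + arm + SE2, B = SE1* + arm + core* + arm + SE2*
#' (asterisk = reverse complement), C = reverse complement of the arm
#' segment.  Deterministic for a given seed.
#'
#' @param design a [FUnitDesign-class].
#' @param seed integer RNG seed.
#' @param gcFraction target GC fraction per domain (default 0.5).
#' @return the design with its `sequences` slot populated.
#' @export
makeDesignSequences <- function(design, seed = 1, gcFraction = 0.5) {
  seqs <- .with_seed(seed, {
    core <- .random_domain(design@coreBp, gcFraction)
    arm <- .random_domain(design@armBp, gcFraction)
    se1 <- .random_domain(design@seBp, gcFraction)
    se2 <- .random_domain(design@seBp, gcFraction)
    list(
      A = paste0(se1, arm, core, arm, se2),
      B = paste0(.revcomp(se1), arm, .revcomp(core), arm, .revcomp(se2)),
      C = .revcomp(arm))
  })
  design@sequences <- seqs
  design
}

## Index bookkeeping of the canonical single-F-unit topology:
## strand A (SE1 | armL | core | armR | SE2), strand B (SE1* | armL | core* |
## armR | SE2*), four C strands C1..C4 (one per arm duplex).  Global indices
## are 1-based over the concatenated strands A, B, C1..C4.
.funit_layout <- function(design) {
  se <- design@seBp; arm <- design@armBp; core <- design@coreBp
  lenAB <- 2 * se + 2 * arm + core
  offA <- 0L; offB <- lenAB
  offC <- 2L * lenAB + (0:3) * arm   # C1..C4 offsets
  dom <- function(off, from, to) off + seq.int(from, to)
  layout <- list(
    strand_lengths = c(A = lenAB, B = lenAB, C1 = arm, C2 = arm, C3 = arm, C4 = arm),
    A = list(se1 = dom(offA, 1, se),
             armL = dom(offA, se + 1, se + arm),
             core = dom(offA, se + arm + 1, se + arm + core),
             armR = dom(offA, se + arm + core + 1, se + 2 * arm + core),
             se2 = dom(offA, se + 2 * arm + core + 1, lenAB)),
    B = list(se1s = dom(offB, 1, se),
             armL = dom(offB, se + 1, se + arm),
             core = dom(offB, se + arm + 1, se + arm + core),
             armR = dom(offB, se + arm + core + 1, se + 2 * arm + core),
             se2s = dom(offB, se + 2 * arm + core + 1, lenAB)),
    C = lapply(1:4, function(k) dom(offC[k], 1, arm)))
  ## base pairs (antiparallel): reference index -> partner index
  pairs <- rbind(
    cbind(layout$A$core, rev(layout$B$core)),       # core A:B
    cbind(layout$A$armL, rev(layout$C[[1]])),       # e1 arm (J1)
    cbind(layout$B$armR, rev(layout$C[[2]])),       # e2 arm (J1)
    cbind(layout$B$armL, rev(layout$C[[3]])),       # e4 arm (J2)
    cbind(layout$A$armR, rev(layout$C[[4]])))       # e5 arm (J2)
  layout$pairs <- pairs
  ## junction index maps (reference-side indices, proximal -> distal)
  layout$junction1 <- list(e1 = rev(layout$A$armL), e2 = layout$B$armR,
                           e3 = layout$A$core)
  layout$junction2 <- list(e4 = rev(layout$B$armL), e5 = layout$A$armR,
                           e6 = rev(layout$A$core))
  layout
}

#' Design-implied base-pair map of a single F-unit topology
#'
#' @param topology a [Topology-class] laid out as the canonical single
#'   F-unit (strands A, B, C1..C4 produced by [generateFUnitSnapshot()]).
#' @param design the matching [FUnitDesign-class].
#' @return a [BasePairMap-class] with provenance "design".
#' @export
designBasePairMap <- function(topology, design) {
  lay <- .funit_layout(design)
  lens <- as.integer(table(topology@records$strand)[as.character(seq_len(nStrands(topology)))])
  if (!identical(lens, unname(as.integer(lay$strand_lengths)))) {
    stop("topology strand lengths do not match the design's F-unit layout")
  }
  BasePairMap(lay$pairs, "design")
}

#' Validate an F-unit design
#'
#' Runs the design's consistency checks and returns a report rather than
#' erroring: segment-length consistency, domain complementarity (core A:B,
#' arms against C, SE1 against SE1*, SE2 against SE2*) and the stoichiometry
#' rule m = n, p = 10 m.
#'
#' @param design a [FUnitDesign-class].
#' @return data.frame with columns `check`, `pass`, `message`.
#' @export
validateDesign <- function(design) {
  validObject(design)
  checks <- list()
  add <- function(check, pass, message = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, message = message)
  }
  add("segment_lengths", TRUE,
      sprintf("core %d bp, arm %d bp, SE %d bp", design@coreBp, design@armBp,
              design@seBp))
  if (length(design@stoichiometry) == 3) {
    st <- design@stoichiometry
    if (st[1] != st[2]) {
      add("stoichiometry", FALSE, "m must equal n")
    } else if (st[3] != 10 * st[1]) {
      add("stoichiometry", FALSE, "p must equal 10*m")
    } else {
      add("stoichiometry", TRUE,
          sprintf("A:B:C = %s (m = n = p/10)", paste(st, collapse = ":")))
    }
  } else {
    add("stoichiometry", NA, "not specified")
  }
  sq <- design@sequences
  if (length(sq)) {
    se <- design@seBp; arm <- design@armBp; core <- design@coreBp
    lenAB <- 2 * se + 2 * arm + core
    okA <- nchar(sq$A) == lenAB
    okB <- nchar(sq$B) == lenAB
    okC <- nchar(sq$C) == arm
    add("strand_lengths", okA && okB && okC,
        sprintf("A %d/%d, B %d/%d, C %d/%d nt", nchar(sq$A), lenAB,
                nchar(sq$B), lenAB, nchar(sq$C), arm))
    if (okA && okB && okC) {
      domA <- function(d) substr(sq$A, d[1], d[length(d)])
      domB <- function(d) substr(sq$B, d[1] - lenAB, d[length(d)] - lenAB)
      lay <- .funit_layout(design)
      cmp <- function(name, got, want) {
        if (identical(got, want)) {
          add(name, TRUE)
        } else {
          off <- which(strsplit(got, "")[[1]] != strsplit(want, "")[[1]])[1]
          add(name, FALSE, sprintf("mismatch in %s at offset %d", name, off))
        }
      }
      cmp("core_complementarity", domB(lay$B$core), .revcomp(domA(lay$A$core)))
      cmp("arm_vs_C", sq$C, .revcomp(domA(lay$A$armL)))
      armsame <- identical(domA(lay$A$armL), domA(lay$A$armR)) &&
        identical(domA(lay$A$armL), domB(lay$B$armL)) &&
        identical(domA(lay$A$armL), domB(lay$B$armR))
      add("arm_segments_identical", armsame,
          if (armsame) "" else "the four arm segments must share one sequence")
      cmp("se1_complementarity", domB(lay$B$se1s), .revcomp(domA(lay$A$se1)))
      cmp("se2_complementarity", domB(lay$B$se2s), .revcomp(domA(lay$A$se2)))
    }
  } else {
    add("sequences", NA, "no sequences specified; sequence checks skipped")
  }
  if (nrow(design@cholesterolSites)) {
    add("cholesterol_sites", TRUE,
        sprintf("%d site(s)", nrow(design@cholesterolSites)))
  } else {
    add("cholesterol_sites", NA, "no hydrophobic anchors defined")
  }
  do.call(rbind, checks)
}

## ---------------------------------------------------------------------------
## Annealing protocols
## ---------------------------------------------------------------------------

## Expand a "-1 degC / 5 min" ramp between two holds into stepwise holds.
.expand_ramp <- function(from_temp, to_temp, deg_per_step = 1, min_per_step = 5) {
  if (abs(from_temp - to_temp) <= deg_per_step) {
    return(data.frame(temperatureC = numeric(0), durationMin = numeric(0)))
  }
  dir <- sign(to_temp - from_temp)
  temps <- seq(from_temp + dir * deg_per_step, to_temp - dir * deg_per_step,
               by = dir * deg_per_step)
  data.frame(temperatureC = temps, durationMin = min_per_step)
}

.protocol_holds <- list(
  "FAP-A" = list(h = data.frame(temperatureC = c(90, 68, 59, 42, 25),
                                durationMin = c(5, 10, 10, 60, 30)),
                 ramps = 4L),  # ramp before the final hold only
  "FAP-B" = list(h = data.frame(temperatureC = c(90, 68, 59, 42, 25),
                                durationMin = c(5, 10, 10, 60, 60)),
                 ramps = 4L),
  "FAP-C" = list(h = data.frame(temperatureC = c(90, 68, 59, 42, 25),
                                durationMin = c(5, 10, 10, 60, 1440)),
                 ramps = 4L),
  "SAP-A" = list(h = data.frame(temperatureC = c(90, 68, 59, 42, 40, 4),
                                durationMin = c(5, 180, 180, 360, 360, 2)),
                 ramps = 1:4),
  "SAP-B" = list(h = data.frame(temperatureC = c(90, 68, 59, 42, 40, 4),
                                durationMin = c(5, 180, 180, 360, 360, 60)),
                 ramps = 1:4))

#' Build an annealing protocol
#'
#' The five named protocols are the fast (FAP-A/B/C) and slow (SAP-A/B)
#' schedules used to assemble the nanosheets; their "-1 degC / 5 min" ramps
#' are expanded into 1-degree, 5-minute stepwise holds, which preserves the
#' total protocol time.  A custom protocol is built from an explicit step
#' table.
#'
#' @param name one of "FAP-A", "FAP-B", "FAP-C", "SAP-A", "SAP-B", or
#'   "custom".
#' @param steps for `name = "custom"`, a data.frame with columns
#'   `temperatureC` and `durationMin`.
#' @return an [AnnealingProtocol-class].
#' @examples
#' annealingProtocol("FAP-A")
#' @export
annealingProtocol <- function(name = c("FAP-A", "FAP-B", "FAP-C", "SAP-A",
                                       "SAP-B", "custom"),
                              steps = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(steps)) stop("a custom protocol needs an explicit step table")
    return(new("AnnealingProtocol", name = name, steps = steps))
  }
  def <- .protocol_holds[[name]]
  h <- def$h
  out <- h[1, , drop = FALSE]
  for (i in seq_len(nrow(h) - 1)) {
    if (i %in% def$ramps) {
      out <- rbind(out, .expand_ramp(h$temperatureC[i], h$temperatureC[i + 1]))
    }
    out <- rbind(out, h[i + 1, , drop = FALSE])
  }
  rownames(out) <- NULL
  new("AnnealingProtocol", name = name, steps = out)
}

#' Hybridization order implied by melting temperatures and a schedule
#'
#' A sharp-threshold hybridization model: a domain duplex binds at the first
#' moment the schedule temperature falls to or below its melting
#' temperature.  With the design's duplex lengths this reproduces the
#' intended hierarchical order: core first, then arms, then sticky ends.
#'
#' @param tms a [DomainTmSet-class].
#' @param protocol an [AnnealingProtocol-class].
#' @return data.frame with columns `domain`, `timeMin` (schedule time at
#'   binding; `NA` when never reached), `temperatureC` and `bound`, sorted
#'   by event time (unbound domains last).
#' @export
assemblyOrder <- function(tms, protocol) {
  steps <- protocol@steps
  if (!nrow(steps)) stop("protocol has no steps")
  start <- cumsum(c(0, steps$durationMin))[seq_len(nrow(steps))]
  tm <- c(core = tms@tmCore, arm = tms@tmArm, se1 = tms@tmSe1, se2 = tms@tmSe2)
  rows <- lapply(names(tm), function(dom) {
    hit <- which(steps$temperatureC <= tm[[dom]])[1]
    if (is.na(hit)) {
      data.frame(domain = dom, timeMin = NA_real_, temperatureC = NA_real_,
                 bound = FALSE)
    } else {
      data.frame(domain = dom, timeMin = start[hit],
                 temperatureC = steps$temperatureC[hit], bound = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(is.na(out$timeMin), out$timeMin, out$domain), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Idealized geometry
## ---------------------------------------------------------------------------

## Three unit vectors with prescribed pairwise angles (alpha12, alpha13,
## alpha23), anchored with e3 along +x and e1 in the xy-plane.  When the
## angle set is planar-consistent the third vector has zero z-component;
## otherwise the unique (up to reflection) 3-D realization is returned.
.junction_tripod <- function(angles_deg) {
  a <- angles_deg * pi / 180
  e3 <- c(1, 0, 0)
  e1 <- c(cos(a[2]), sin(a[2]), 0)
  x <- cos(a[3])
  y <- (cos(a[1]) - cos(a[2]) * cos(a[3])) / sin(a[2])
  z2 <- 1 - x^2 - y^2
  if (z2 < -1e-9) {
    stop("impossible angle set: no unit-vector realization exists")
  }
  ## snap tiny negatives and tiny positives from a planar-consistent set
  z <- sqrt(max(z2, 0))
  if (z < 1e-7) z <- 0
  e2 <- c(x, y, z)
  e2 <- e2 / sqrt(sum(e2^2))
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Build the idealized F-unit center-line model
#'
#' Places the core along +x between junctions J1 and J2 and realizes, at
#' each junction, three unit arm directions with the requested pairwise
#' angles (alpha12, alpha13, alpha23); e3/e6 are the core directions and
#' the J2 tripod is the point-symmetric image of the J1 tripod.  A
#' planar-consistent angle set (sector angles summing to 360 degrees)
#' yields an exactly planar model; the default angles (80, 150, 120) are
#' the simulation equilibrium values, whose 350-degree sum implies a small
#' out-of-plane pucker that the construction reproduces.
#'
#' Sticky-end stubs extend the e1/e5-type arms collinearly; cholesterol
#' coordinates sit at the distal terminus of e1/e4-type arms and at the
#' junction (proximal terminus) of e2/e5-type arms.
#'
#' @param design a [FUnitDesign-class].
#' @param junctionAngles numeric(3): (alpha12, alpha13, alpha23) in degrees,
#'   applied to both junctions.  Default c(80, 150, 120).
#' @return an [IdealUnitModel-class]; all coordinates in nm.
#' @examples
#' m <- buildIdealFUnit(FUnitDesign())
#' m@junctions
#' @export
buildIdealFUnit <- function(design, junctionAngles = c(80, 150, 120)) {
  if (sum(junctionAngles) > 360 + 1e-9) {
    stop("impossible angle set: per-junction angles must sum to <= 360")
  }
  rise <- design@riseNm
  Lc <- design@coreBp * rise
  La <- design@armBp * rise
  Ls <- design@seBp * rise
  t1 <- .junction_tripod(junctionAngles)
  J1 <- c(0, 0, 0)
  J2 <- c(Lc, 0, 0)
  mirror <- function(v) c(-v[1], -v[2], v[3])  # 180 deg rotation about z
  dirs <- list(e1 = t1$e1, e2 = t1$e2, e3 = t1$e3,
               e4 = mirror(t1$e1), e5 = mirror(t1$e2), e6 = mirror(t1$e3))
  seg <- function(from, dir, len) rbind(from, from + len * dir)
  segments <- list(
    core = rbind(J1, J2),
    arm_e1 = seg(J1, dirs$e1, La), arm_e2 = seg(J1, dirs$e2, La),
    arm_e4 = seg(J2, dirs$e4, La), arm_e5 = seg(J2, dirs$e5, La),
    se_e1 = seg(J1 + La * dirs$e1, dirs$e1, Ls),
    se_e2 = seg(J1 + La * dirs$e2, dirs$e2, Ls),
    se_e4 = seg(J2 + La * dirs$e4, dirs$e4, Ls),
    se_e5 = seg(J2 + La * dirs$e5, dirs$e5, Ls))
  chol <- list(
    e1 = J1 + La * dirs$e1,   # distal terminus
    e2 = J1,                  # proximal terminus
    e4 = J2 + La * dirs$e4,
    e5 = J2)
  new("IdealUnitModel", segments = segments,
      junctions = rbind(J1 = J1, J2 = J2),
      armDirections = dirs, cholesterolSites = chol)
}

#' Idealized nanopore lattice geometry
#'
#' The pore quadrilateral implied by the design: the long side runs through
#' arm + sticky end + core + arm (63 bp for the default design), the short
#' side through arm + sticky end + arm (42 bp).  Side lengths in nm are
#' contour bp times the helical rise, and the two pore diagonals follow
#' from the parallelogram closed form
#' `d = sqrt(a^2 + b^2 +/- 2 a b cos(theta))`.
#'
#' @param design a [FUnitDesign-class].
#' @param junctionAngleDeg angle theta between adjacent sides (default 80,
#'   the simulation equilibrium inter-arm angle).
#' @param duplexWidthNm duplex width used for the porosity estimate.
#' @return a [LatticeGeometry-class] with the porosity filled in.
#' @examples
#' poreLatticeGeometry(FUnitDesign())
#' @export
poreLatticeGeometry <- function(design, junctionAngleDeg = 80,
                                duplexWidthNm = design@duplexWidthNm) {
  if (junctionAngleDeg <= 0 || junctionAngleDeg >= 180) {
    stop("junction angle must lie in (0, 180) degrees")
  }
  side_long_bp <- design@armBp + design@seBp + design@coreBp + design@armBp
  side_short_bp <- design@armBp + design@seBp + design@armBp
  a <- side_long_bp * design@riseNm
  b <- side_short_bp * design@riseNm
  th <- junctionAngleDeg * pi / 180
  dl <- sqrt(a^2 + b^2 + 2 * a * b * cos(th))
  ds <- sqrt(a^2 + b^2 - 2 * a * b * cos(th))
  geom <- new("LatticeGeometry",
              sideLongBp = side_long_bp, sideShortBp = side_short_bp,
              sideLongNm = a, sideShortNm = b,
              junctionAngleDeg = junctionAngleDeg,
              diagLongNm = dl, diagShortNm = ds,
              porosityFraction = NA_real_)
  geom@porosityFraction <- latticePorosity(geom, duplexWidthNm)
  geom
}

#' Open-area (porosity) fraction of the idealized lattice
#'
#' Each parallelogram unit cell (sides a, b, angle theta) owns one strip of
#' DNA of width w along its long side and one along its short side; the
#' corner overlap is counted once.  The open-area fraction is
#' `phi = 1 - ((a + b - w) w) / (a b sin(theta))`.
#'
#' @param lattice a [LatticeGeometry-class].
#' @param duplexWidthNm strut (duplex) width w in nm.
#' @return porosity fraction in `[0, 1)`.
#' @examples
#' latticePorosity(poreLatticeGeometry(FUnitDesign()), 2)
#' @export
latticePorosity <- function(lattice, duplexWidthNm = 2) {
  a <- lattice@sideLongNm
  b <- lattice@sideShortNm
  w <- duplexWidthNm
  if (w >= min(a, b)) stop("duplex width must be smaller than both sides")
  th <- lattice@junctionAngleDeg * pi / 180
  1 - ((a + b - w) * w) / (a * b * sin(th))
}

#' Distances between hydrophobic anchor sites across the lattice
#'
#' Builds the collinear-segment neighborhood of one F-unit (the unit plus
#' its four sticky-end-connected neighbors), places the cholesterol sites
#' (distal terminus on e1/e4-type arms, junction-proximal on e2/e5-type)
#' and measures Euclidean distances between the pairs of sites joined by a
#' single sticky-end bridge.  Under collinear bridges the e1-e4 bridge
#' distance is the sticky-end contour (se_bp x rise, about 3.4 nm for the
#' default design) and the e2-e5 bridge distance is the arm-SE-arm contour
#' ((2 arm_bp + se_bp) x rise, about 14.3 nm).
#'
#' @param design a [FUnitDesign-class] (must define cholesterol sites).
#' @param model optionally, a pre-built [IdealUnitModel-class] (e.g. a
#'   rigidly transformed one); defaults to [buildIdealFUnit()].
#' @return list with `minNm`, `maxNm` (over bridged pairs),
#'   `bridgeDistancesNm` (named per bridge), `sites` (coordinate matrix of
#'   all collected anchor sites, nm) and `allPairwiseNm` (full distance
#'   matrix).
#' @export
cholesterolSpacings <- function(design, model = buildIdealFUnit(design)) {
  if (!nrow(design@cholesterolSites)) {
    stop("design defines no cholesterol sites")
  }
  rise <- design@riseNm
  La <- design@armBp * rise
  Ls <- design@seBp * rise
  J <- model@junctions
  dirs <- model@armDirections
  own <- model@cholesterolSites
  ## neighbor sites reached through each arm's sticky-end bridge
  ## (segments collinear across the bridge):
  ##   e1/e4 arms: both anchors distal -> separated by the SE duplex alone
  ##   e2/e5 arms: both anchors proximal -> separated by arm + SE + arm
  nb <- list(
    e1 = J["J1", ] + (La + Ls) * dirs$e1,
    e2 = J["J1", ] + (2 * La + Ls) * dirs$e2,
    e4 = J["J2", ] + (La + Ls) * dirs$e4,
    e5 = J["J2", ] + (2 * La + Ls) * dirs$e5)
  bridge <- vapply(names(nb), function(a) {
    sqrt(sum((own[[a]] - nb[[a]])^2))
  }, numeric(1))
  sites <- rbind(do.call(rbind, own), do.call(rbind, nb))
  rownames(sites) <- c(paste0("own_", names(own)), paste0("nbr_", names(nb)))
  list(minNm = min(bridge), maxNm = max(bridge),
       bridgeDistancesNm = bridge, sites = sites,
       allPairwiseNm = as.matrix(stats::dist(sites)))
}
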