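## Reading and writing classic oxDNA text files.
##
## Topology: first line "N n_strands", then one line per nucleotide:
##   "strand base neighbor3 neighbor5" with -1 for no neighbor (0-based).
## Configuration: per frame three header lines
##   "t = <time>", "b = <Lx> <Ly> <Lz>", "E = <Etot> <U> <K>"
## followed by N rows of 9 (or 15, with velocities) whitespace-separated
## numbers: position, a1 versor, a3 versor [, velocity, angular velocity].

#' Read an oxDNA topology file
#'
#' @param path path to a topology (.top) text file.
#' @return a [Topology-class] object (indices converted to 1-based).
#' @examples
#' d <- FUnitDesign()
#' gen <- generateFUnitSnapshot(d)
#' tf <- tempfile(fileext = ".top")
#' writeTopology(gen$topology, tf)
#' top <- readTopology(tf)
#' nNucleotides(top)
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("parse error at line 1: expected two integers (nucleotide and strand counts)")
  }
  n <- as.integer(hdr[1]); ns <- as.integer(hdr[2])
  if (length(lines) - 1L != n) {
    stop(sprintf("parse error: header declares %d nucleotides but file has %d records",
                 n, length(lines) - 1L))
  }
  fields <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected 4 fields", bad[1] + 1L))
  }
  m <- do.call(rbind, fields)
  strand <- suppressWarnings(as.integer(m[, 1]))
  n3 <- suppressWarnings(as.integer(m[, 3]))
  n5 <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(strand) | is.na(n3) | is.na(n5))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-integer field", bad[1] + 1L))
  }
  ## 0-based file indices (-1 = none) -> 1-based with NA
  n3 <- ifelse(n3 < 0, NA_integer_, n3 + 1L)
  n5 <- ifelse(n5 < 0, NA_integer_, n5 + 1L)
  top <- Topology(strand = strand, base = m[, 2], n3 = n3, n5 = n5)
  if (nStrands(top) != ns) {
    stop(sprintf("validation error: header declares %d strands, records contain %d",
                 ns, nStrands(top)))
  }
  top
}

#' Write an oxDNA topology file
#'
#' @param topology a [Topology-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTopology <- function(topology, path) {
  r <- topology@records
  n3 <- ifelse(is.na(r$n3), -1L, r$n3 - 1L)
  n5 <- ifelse(is.na(r$n5), -1L, r$n5 - 1L)
  lines <- c(sprintf("%d %d", nrow(r), nStrands(topology)),
             sprintf("%d %s %d %d", r$strand, r$base, n3, n5))
  writeLines(lines, path)
  invisible(path)
}

.parse_config_block <- function(lines, start, n, frame_idx) {
  if (start + 2 + n - 1 > length(lines)) {
    stop(sprintf("truncated configuration: frame %d incomplete", frame_idx))
  }
  t_line <- lines[start]
  if (!grepl("^\\s*t\\s*=", t_line)) {
    stop(sprintf("parse error in frame %d: expected 't = <time>' header", frame_idx))
  }
  time <- as.numeric(sub("^\\s*t\\s*=\\s*", "", t_line))
  box <- as.numeric(strsplit(trimws(sub("^\\s*b\\s*=\\s*", "", lines[start + 1])),
                             "\\s+")[[1]])
  en <- as.numeric(strsplit(trimws(sub("^\\s*E\\s*=\\s*", "", lines[start + 2])),
                            "\\s+")[[1]])
  rows <- lines[(start + 3):(start + 2 + n)]
  if (any(grepl("^\\s*t\\s*=", rows))) {
    stop(sprintf("row count mismatch in frame %d: fewer rows than topology nucleotides",
                 frame_idx))
  }
  vals <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(vals)
  if (!all(nf %in% c(9L, 15L)) || length(unique(nf)) != 1L) {
    stop(sprintf("parse error in frame %d: rows must have 9 or 15 numbers", frame_idx))
  }
  m <- matrix(as.numeric(unlist(vals)), nrow = n, byrow = TRUE)
  if (anyNA(m)) stop(sprintf("parse error in frame %d: non-numeric value", frame_idx))
  vel <- if (ncol(m) == 15) m[, 10:12, drop = FALSE] else matrix(0, 0, 3)
  ang <- if (ncol(m) == 15) m[, 13:15, drop = FALSE] else matrix(0, 0, 3)
  list(snapshot = Snapshot(time = time, box = box,
                           positions = m[, 1:3, drop = FALSE],
                           a1 = m[, 4:6, drop = FALSE],
                           a3 = m[, 7:9, drop = FALSE],
                           energies = if (length(en) == 3) en else c(0, 0, 0),
                           velocities = vel, angularVelocities = ang),
       next_start = start + 3 + n)
}

#' Read an oxDNA configuration/trajectory file
#'
#' Parses one or more configuration blocks into a [Trajectory-class].
#' Frame times must be strictly increasing and each block must contain
#' exactly as many rows as the topology has nucleotides.
#'
#' @param path path to a configuration (.dat/.oxdna) text file.
#' @param topology the matching [Topology-class].
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- nNucleotides(topology)
  snaps <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    blk <- .parse_config_block(lines, pos, n, frame)
    snaps[[frame]] <- blk$snapshot
    pos <- blk$next_start
  }
  if (!length(snaps)) stop("no configuration frames found in ", path)
  tt <- vapply(snaps, function(s) s@time, numeric(1))
  if (length(tt) > 1 && any(diff(tt) <= 0)) {
    stop(sprintf("non-increasing frame times at frame %d", which(diff(tt) <= 0)[1] + 1L))
  }
  Trajectory(topology, snaps)
}

#' Read a single-configuration file
#'
#' Convenience wrapper returning the first (and typically only) frame.
#'
#' @inheritParams readTrajectory
#' @return a [Snapshot-class].
#' @export
readSnapshot <- function(path, topology) {
  getSnapshot(readTrajectory(path, topology), 1L)
}

.format_row <- function(m) {
  apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
}

#' Write one configuration frame in oxDNA format
#'
#' Values are written at full double precision so a read/write round trip
#' is numerically lossless.  Velocities are written as zeros when the
#' snapshot carries none.
#'
#' @param topology a [Topology-class] (for the record-count check).
#' @param snapshot a [Snapshot-class].
#' @param path output path.
#' @param append append as an additional frame instead of overwriting.
#' @return invisibly, `path`.
#' @export
writeSnapshot <- function(topology, snapshot, path, append = FALSE) {
  n <- nNucleotides(topology)
  if (nrow(snapshot@positions) != n) {
    stop(sprintf("record count mismatch: topology has %d nucleotides, snapshot %d",
                 n, nrow(snapshot@positions)))
  }
  vel <- snapshot@velocities
  ang <- snapshot@angularVelocities
  if (nrow(vel) == 0) vel <- matrix(0, n, 3)
  if (nrow(ang) == 0) ang <- matrix(0, n, 3)
  body <- .format_row(cbind(snapshot@positions, snapshot@a1, snapshot@a3, vel, ang))
  hdr <- c(sprintf("t = %.17g", snapshot@time),
           sprintf("b = %s", paste(sprintf("%.17g", snapshot@box), collapse = " ")),
           sprintf("E = %s", paste(sprintf("%.17g", snapshot@energies), collapse = " ")))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write a multi-frame trajectory in oxDNA format
#'
#' @param trajectory a [Trajectory-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTrajectory <- function(trajectory, path) {
  if (file.exists(path)) file.remove(path)
  for (s in trajectory@snapshots) {
    writeSnapshot(trajectory@topology, s, path, append = TRUE)
  }
  invisible(path)
}

.base_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Derive the base-pair map of a configuration
#'
#' In `"design"` mode the pairing is the exact map implied by the F-unit
#' domain complementarity (core A:B, each arm segment with its own C copy;
#' sticky ends unpaired in a single unit).  In `"geometric"` mode,
#' Watson-Crick-complementary nucleotides are paired when their centers lie
#' within `distanceNm` and their a1 versors are anti-aligned within
#' `angleDeg`; an ambiguous match (one nucleotide admitting two partners)
#' is an error.
#'
#' @param topology a [Topology-class].
#' @param snapshot a [Snapshot-class] (required for geometric mode).
#' @param mode `"design"` or `"geometric"`.
#' @param design a [FUnitDesign-class] (required for design mode).
#' @param distanceNm geometric center-distance threshold, nm (default 1.2).
#' @param angleDeg geometric a1 anti-alignment threshold, degrees (default 30).
#' @return a [BasePairMap-class].
#' @export
deriveBasePairs <- function(topology, snapshot = NULL,
                            mode = c("design", "geometric"),
                            design = NULL, distanceNm = 1.2, angleDeg = 30) {
  mode <- match.arg(mode)
  if (mode == "design") {
    if (is.null(design)) stop("design mode requires a FUnitDesign")
    return(designBasePairMap(topology, design))
  }
  if (is.null(snapshot)) stop("geometric mode requires a snapshot")
  pos <- snapshot@positions
  a1 <- snapshot@a1
  n <- nrow(pos)
  bases <- topology@records$base
  comp <- .base_complement[bases]
  dmax <- fromNanometers(distanceNm)
  cosmin <- cos(angleDeg * pi / 180)
  cand_i <- integer(0); cand_j <- integer(0)
  ## blockwise all-pairs scan keeps memory bounded for larger systems
  block <- 512L
  for (i0 in seq(1L, n, by = block)) {
    ii <- i0:min(i0 + block - 1L, n)
    d2 <- outer(rowSums(pos[ii, , drop = FALSE]^2), rowSums(pos^2), "+") -
      2 * pos[ii, , drop = FALSE] %*% t(pos)
    dotA1 <- a1[ii, , drop = FALSE] %*% t(a1)
    ok <- d2 <= dmax^2 & (-dotA1) >= cosmin &
      outer(comp[ii], bases, "==") &
      outer(ii, seq_len(n), "<")
    w <- which(ok, arr.ind = TRUE)
    if (nrow(w)) {
      cand_i <- c(cand_i, ii[w[, 1]])
      cand_j <- c(cand_j, w[, 2])
    }
  }
  if (!length(cand_i)) return(BasePairMap(matrix(integer(0), 0, 2), "geometric"))
  all_idx <- c(cand_i, cand_j)
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup)) {
    stop("ambiguous geometric pairing for nucleotide(s): ",
         paste(sort(dup), collapse = ", "))
  }
  BasePairMap(cbind(cand_i, cand_j), "geometric")
}
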