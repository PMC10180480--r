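test_that("a minimal hand-written topology parses into one two-nucleotide strand", {
  tf <- withr::local_tempfile(fileext = ".top")
  writeLines(c("2 1", "1 A -1 1", "1 T 0 -1"), tf)
  top <- readTopology(tf)
  expect_equal(nNucleotides(top), 2L)
  expect_equal(nStrands(top), 1L)
  expect_equal(top@records$n3, c(NA_integer_, 1L))
  expect_equal(top@records$n5, c(2L, NA_integer_))
})

test_that("malformed topology files fail with informative errors", {
  tf <- withr::local_tempfile(fileext = ".top")
  writeLines(c("2 1", "1 A -1 1"), tf)
  expect_error(readTopology(tf), "2 records|1 records")
  writeLines(c("2 1", "1 A -1 1", "1 T 0"), tf)
  expect_error(readTopology(tf), "line 3")
  ## broken reciprocity: 2's 3' neighbor is 1 but 1 does not point back
  writeLines(c("2 1", "1 A -1 -1", "1 T 0 -1"), tf)
  expect_error(readTopology(tf), "neighbor chain")
})

test_that("topology and snapshot round-trip through files losslessly", {
  gen <- generateFUnitSnapshot(default_design(),
                               DistortionParams(uniformTiltDeg = 12,
                                                positionalNoiseNm = 0.05,
                                                seed = 42))
  dir <- withr::local_tempdir()
  top_path <- file.path(dir, "u.top")
  dat_path <- file.path(dir, "u.dat")
  writeTopology(gen$topology, top_path)
  writeSnapshot(gen$topology, gen$snapshot, dat_path)
  top2 <- readTopology(top_path)
  expect_identical(top2@records, gen$topology@records)
  snap2 <- readSnapshot(dat_path, top2)
  expect_identical(snap2@positions, gen$snapshot@positions)
  expect_identical(snap2@a1, gen$snapshot@a1)
  expect_identical(snap2@a3, gen$snapshot@a3)
  expect_identical(snap2@time, gen$snapshot@time)
  expect_identical(snap2@box, gen$snapshot@box)
  ## versor norms preserved
  expect_lt(max(abs(sqrt(rowSums(snap2@a1^2)) - 1)), 1e-9)
  ## fractional times survive the round trip
  s3 <- gen$snapshot
  s3@time <- 3.5
  writeSnapshot(gen$topology, s3, dat_path)
  expect_identical(readSnapshot(dat_path, top2)@time, 3.5)
})

test_that("trajectory reading checks frame structure and time ordering", {
  gen <- generateRelaxationTrajectory(
    default_design(),
    RelaxationParams(nFrames = 10, noiseDeg = 0, seed = 1),
    dir = withr::local_tempdir())
  top <- readTopology(gen$topologyPath)
  traj <- readTrajectory(gen$trajectoryPath, top)
  expect_equal(nFrames(traj), 10L)
  expect_equal(frameTimes(traj), 0:9)
  ## truncated final frame names the frame index
  lines <- readLines(gen$trajectoryPath)
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(lines[1:(length(lines) - 5)], tf)
  expect_error(readTrajectory(tf, top), "frame 10")
  ## duplicated frame time is rejected
  n <- nNucleotides(top)
  block <- lines[1:(3 + n)]
  writeLines(c(block, block), tf)
  expect_error(readTrajectory(tf, top), "[Nn]on-increasing")
})

test_that("simulation-unit conversion is the documented linear map", {
  expect_equal(toNanometers(1), 0.8518)
  expect_equal(toNanometers(0), 0)
  v <- c(1, 2, 3)
  expect_equal(toNanometers(v), v * 0.8518)
  expect_equal(sqrt(sum(toNanometers(v)^2)), toNanometers(sqrt(sum(v^2))))
  expect_equal(fromNanometers(toNanometers(pi)), pi)
})

test_that("geometric base pairing reproduces the design pairing on ideal units", {
  d <- default_design()
  gen <- generateFUnitSnapshot(d, DistortionParams(seed = 7))
  design_map <- deriveBasePairs(gen$topology, mode = "design",
                                design = makeDesignSequences(d, seed = 7))
  expect_identical(canon_pairs(design_map@pairs), canon_pairs(gen$pairing@pairs))
  geo_map <- deriveBasePairs(gen$topology, gen$snapshot, mode = "geometric")
  expect_identical(canon_pairs(geo_map@pairs), canon_pairs(design_map@pairs))
  ## core + four arms
  expect_equal(nrow(geo_map@pairs), d@coreBp + 4 * d@armBp)
})

test_that("displacing one strand removes its geometric pairs", {
  d <- default_design()
  gen <- generateFUnitSnapshot(d, DistortionParams(seed = 7))
  snap <- gen$snapshot
  idx <- which(strandIds(gen$topology) == 3L)  # one C strand
  snap@positions[idx, ] <- snap@positions[idx, ] + fromNanometers(10)
  geo_map <- deriveBasePairs(gen$topology, snap, mode = "geometric")
  expect_equal(nrow(geo_map@pairs), d@coreBp + 3 * d@armBp)
  expect_false(any(idx %in% as.vector(geo_map@pairs)))
})
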