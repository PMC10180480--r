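test_that("generators are pure functions of their parameters and seed", {
  d <- default_design()
  g1 <- generateFUnitSnapshot(d, DistortionParams(positionalNoiseNm = 0.1, seed = 1))
  g2 <- generateFUnitSnapshot(d, DistortionParams(positionalNoiseNm = 0.1, seed = 1))
  g3 <- generateFUnitSnapshot(d, DistortionParams(positionalNoiseNm = 0.1, seed = 2))
  expect_identical(g1$snapshot@positions, g2$snapshot@positions)
  expect_false(identical(g1$snapshot@positions, g3$snapshot@positions))
  h1 <- generateHeightProfile(seed = 5)
  h2 <- generateHeightProfile(seed = 5)
  expect_identical(h1$profile@heights, h2$profile@heights)
  r1 <- generateRheologySweep(seed = 5)
  r2 <- generateRheologySweep(seed = 5)
  expect_identical(sweepData(r1$sweep), sweepData(r2$sweep))
  ## byte-identical files on re-generation
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- generateRelaxationTrajectory(d, RelaxationParams(nFrames = 5, seed = 9), d1)
  t2 <- generateRelaxationTrajectory(d, RelaxationParams(nFrames = 5, seed = 9), d2)
  expect_identical(readLines(t1$trajectoryPath), readLines(t2$trajectoryPath))
  expect_identical(readLines(t1$topologyPath), readLines(t2$topologyPath))
})

test_that("generated snapshots satisfy topology and snapshot invariants", {
  d <- default_design()
  for (gen in list(generateFUnitSnapshot(d, DistortionParams(seed = 3)),
                   generatePoreSnapshot(d, 80, DistortionParams(seed = 3)))) {
    expect_true(validObject(gen$topology, test = TRUE))
    expect_true(validObject(gen$snapshot, test = TRUE))
    expect_equal(nrow(gen$snapshot@positions), nNucleotides(gen$topology))
    ## every base pair is Watson-Crick complementary
    b <- gen$topology@records$base
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    p <- pairedIndices(gen$pairing)
    expect_true(all(b[p[, 1]] == comp[b[p[, 2]]]))
  }
})

test_that("injected tilt is recovered through the planarity metric", {
  d <- default_design()
  flat <- generateFUnitSnapshot(d, DistortionParams(uniformTiltDeg = 0, seed = 1))
  for (j in flat$junctions) {
    expect_equal(junctionPlanarity(flat$snapshot, flat$pairing, j), 0,
                 tolerance = 1e-9)
  }
  tilted <- generateFUnitSnapshot(d, DistortionParams(uniformTiltDeg = 30, seed = 1))
  for (j in tilted$junctions) {
    expect_equal(junctionPlanarity(tilted$snapshot, tilted$pairing, j), 0.5,
                 tolerance = 1e-6)
  }
  expect_error(DistortionParams(uniformTiltDeg = 95), "tilt")
})

test_that("the synthetic pore reproduces its closed-form geometry", {
  d <- default_design()
  gen <- generatePoreSnapshot(d, 80, DistortionParams(seed = 6))
  expect_equal(gen$groundTruth$sideLongBp, 63)
  quad <- poreQuadrilateral(gen$snapshot, gen$pairing, gen$pore)
  expect_equal(quad$diagXZNm, gen$groundTruth$expectedDiagXZNm, tolerance = 1e-6)
  expect_equal(quad$diagYWNm, gen$groundTruth$expectedDiagYWNm, tolerance = 1e-6)
  expect_equal(unname(poreInternalAngles(gen$snapshot, gen$pairing, gen$pore)),
               c(80, 100, 80, 100), tolerance = 1e-6)
  expect_equal(unname(cornerPlanePlanarity(quad$corners)), rep(0, 6),
               tolerance = 1e-6)
  ## folding about the X-Z diagonal makes the W-corner planes tilt
  folded <- generatePoreSnapshot(d, 80, DistortionParams(uniformTiltDeg = 20,
                                                         seed = 6))
  quad_f <- poreQuadrilateral(folded$snapshot, folded$pairing, folded$pore)
  ang_f <- cornerPlanePlanarity(quad_f$corners)
  expect_gt(max(ang_f), 5)
  ## the fold axis runs through X and Z, so that diagonal is preserved
  expect_equal(quad_f$diagXZNm, quad$diagXZNm, tolerance = 1e-6)
  expect_lt(quad_f$diagYWNm, quad$diagYWNm)
})

test_that("relaxation trajectories decay monotonically without noise and hit the limit", {
  d <- default_design()
  dir <- withr::local_tempdir()
  gen <- generateRelaxationTrajectory(
    d, RelaxationParams(nFrames = 20, initialTiltDeg = 60,
                        equilibriumTiltDeg = 10, relaxationTimeTauB = 3,
                        noiseDeg = 0, seed = 1), dir)
  tilts <- gen$groundTruth$tiltDegByFrame
  expect_true(all(diff(tilts) < 0))
  ## tau -> 0 limit: every frame at the equilibrium tilt
  gen0 <- generateRelaxationTrajectory(
    d, RelaxationParams(nFrames = 6, initialTiltDeg = 60,
                        equilibriumTiltDeg = 10,
                        relaxationTimeTauB = 1e-9, noiseDeg = 0, seed = 1),
    dir, basename = "limit")
  ## the first frame sits at t = 0 (exp(0) = 1 for any tau); every later
  ## frame is at the equilibrium tilt exactly
  expect_equal(gen0$groundTruth$tiltDegByFrame[-1], rep(10, 5))
  dp <- junctionPlanarity(getSnapshot(gen0$trajectory, 3), gen0$pairing,
                          gen0$junctions[[1]])
  expect_equal(dp, sin(10 * pi / 180), tolerance = 1e-9)
})

test_that("equilibrium planarity is recovered across seeds from full pipelines", {
  d <- default_design()
  dir <- withr::local_tempdir()
  means <- vapply(1:10, function(seed) {
    gen <- generateRelaxationTrajectory(
      d, RelaxationParams(seed = seed), dir,
      basename = paste0("relax", seed))
    top <- readTopology(gen$topologyPath)
    traj <- readTrajectory(gen$trajectoryPath, top)
    s <- equilibriumStats(planaritySeries(traj, gen$pairing, gen$junctions[[1]]))
    equilibriumMean(s)
  }, numeric(1))
  expect_true(all(abs(means - 0.20) <= 0.02))
})
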