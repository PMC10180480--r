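test_that("pore spacing is recovered from noisy periodic profiles", {
  for (seed in 1:5) {
    gen <- generateHeightProfile(spacingNm = 25, nPores = 8, noiseNm = 0.1,
                                 seed = seed)
    res <- analyzeHeightProfile(gen$profile)
    expect_equal(length(res$peakPositionsNm), 8)
    expect_lt(abs(res$meanSpacingNm - 25), 1)
  }
})

test_that("plateau heights quantize to discrete duplex layer counts", {
  expect_equal(layerCount(c(1.8, 4.1)), c(1L, 2L))
  expect_equal(layerCount(0.3), 0L)
  gen <- generateHeightProfile(layerPattern = c(1, 2, 1), nPores = 2,
                               noiseNm = 0, seed = 1)
  res <- analyzeHeightProfile(gen$profile)
  expect_equal(res$layerCounts, c(1L, 2L, 1L))
})

test_that("a flat zero profile yields no peaks and zero layers", {
  prof <- HeightProfile(seq(0, 50, by = 0.5), rep(0, 101))
  res <- analyzeHeightProfile(prof)
  expect_length(res$peakPositionsNm, 0)
  expect_true(is.na(res$meanSpacingNm))
  expect_equal(res$layerCounts, 0L)
})

test_that("profile containers enforce uniform increasing sampling", {
  expect_error(HeightProfile(c(0, 1, 1.5), c(0, 0, 0)), "uniform")
  expect_error(HeightProfile(c(0, -1, -2), c(0, 0, 0)), "increasing")
  expect_error(analyzeHeightProfile(HeightProfile(c(0, 1), c(0, 0))),
               "at least 3")
})

test_that("height profiles round-trip through CSV", {
  gen <- generateHeightProfile(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeHeightProfile(gen$profile, f)
  prof2 <- readHeightProfile(f)
  expect_equal(prof2@positions, gen$profile@positions)
  expect_equal(prof2@heights, gen$profile@heights)
})
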