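test_that("time sweeps round-trip through CSV and reject malformed tables", {
  gen <- generateRheologySweep(seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTimeSweep(gen$sweep, f)
  sw2 <- readTimeSweep(f)
  expect_equal(sweepData(sw2)$storageModulus, sweepData(gen$sweep)$storageModulus)
  expect_equal(sweepData(sw2)$time, sweepData(gen$sweep)$time)
  ## missing loss-modulus column
  d <- utils::read.csv(f)
  d$Gpp_N_per_m <- NULL
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(readTimeSweep(f), "loss_modulus column absent")
})

test_that("out-of-order times and negative moduli are rejected on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = c(0, 10, 5), Gp_N_per_m = 1,
                              Gpp_N_per_m = 0.1, temperature_C = 25),
                   f, row.names = FALSE)
  expect_error(readTimeSweep(f), "out of order")
  utils::write.csv(data.frame(time_s = c(0, 5, 10), Gp_N_per_m = -1,
                              Gpp_N_per_m = 0.1, temperature_C = 25),
                   f, row.names = FALSE)
  expect_error(readTimeSweep(f), "negative modulus")
})

test_that("phase plateaus are recovered within 2% from staged sweeps", {
  plan <- data.frame(durationS = 1800, gpPlateau = c(1e-4, 1e-3, 1e-2),
                     gppPlateau = c(1e-5, 1e-4, 1e-3), temperatureC = 25)
  for (seed in 1:10) {
    gen <- generateRheologySweep(plan, noiseCv = 0.05, seed = seed)
    seg <- segmentTimeSweep(gen$sweep,
                            boundaries = c(1800, 3600))
    expect_equal(seg$meanGp, plan$gpPlateau, tolerance = 0.02)
    expect_equal(seg$meanGpp, plan$gppPlateau, tolerance = 0.02)
  }
})

test_that("a single-phase constant sweep reports its constant", {
  plan <- data.frame(durationS = 600, gpPlateau = 0.05, gppPlateau = 0.01,
                     temperatureC = 25)
  gen <- generateRheologySweep(plan, noiseCv = 0, seed = 1)
  expect_true(all(sweepData(gen$sweep)$storageModulus == 0.05))
  seg <- segmentTimeSweep(gen$sweep)
  expect_equal(seg$meanGp, 0.05)
})

test_that("a temperature trigger splits a heat-and-cool sweep into three phases", {
  plan <- data.frame(durationS = 600,
                     gpPlateau = c(1e-2, 1e-1, 3e-1),
                     gppPlateau = c(1e-3, 8e-3, 1.5e-2),
                     temperatureC = c(25, 45, 25))
  gen <- generateRheologySweep(plan, noiseCv = 0, seed = 1)
  seg <- segmentTimeSweep(gen$sweep, temperatureTrigger = 45)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$meanTemperature, c(25, 45, 25))
})

test_that("interfacial-to-bulk extrapolation reproduces the closed forms", {
  ## 300 mN/m on a 2-nm incompressible sheet -> 450 MPa
  expect_equal(bulkYoungModulus(0.300), 450e6)
  ## poly(L-lysine) cross-check: 2 N/m at 10 nm and 6 nm
  expect_equal(bulkYoungModulus(2, ExtrapolationParams(thicknessNm = 10)), 600e6)
  expect_equal(bulkYoungModulus(2, ExtrapolationParams(thicknessNm = 6)), 1000e6)
  expect_equal(bulkYoungModulus(0), 0)
  ## linearity in Gs, inverse-linearity in t
  expect_equal(bulkYoungModulus(0.6), 2 * bulkYoungModulus(0.3))
  expect_equal(bulkYoungModulus(0.6, ExtrapolationParams(thicknessNm = 4)),
               bulkYoungModulus(0.3))
})

test_that("porosity correction scales by the load-bearing fraction", {
  expect_equal(porosityCorrectedModulus(450e6, 0.40), 750e6)
  expect_equal(porosityCorrectedModulus(123, 0), 123)
  expect_equal(porosityCorrectedModulus(100, 0.5), 200)
  expect_error(porosityCorrectedModulus(1, 1), "porosity")
  ## chained check through the result container
  res <- extrapolateModulus(0.300)
  expect_equal(res@bulkYoungModulusPa, 450e6)
  expect_equal(res@porosityCorrectedModulusPa, 750e6)
  expect_gte(res@porosityCorrectedModulusPa, res@bulkYoungModulusPa)
})

test_that("the elastic gap is measured in decades", {
  expect_equal(elasticGapOrders(0.1, 0.005), log10(20))
  expect_equal(elasticGapOrders(0.2, 0.2), 0)
  expect_error(elasticGapOrders(0, 1), "positive")
  ## annealed phase of the default plan carries a > 1 decade gap
  gen <- generateRheologySweep(seed = 4)
  seg <- segmentTimeSweep(gen$sweep,
                          boundaries = gen$groundTruth$phaseBoundariesS[1:3])
  last <- seg[nrow(seg), ]
  expect_gt(elasticGapOrders(last$meanGp, last$meanGpp), 1)
})
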