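test_that("nearest-neighbor Tm matches the independent oracle and frozen references", {
  ## frozen reference values computed with an independent implementation of
  ## the same unified parameter table and salt correction
  expect_equal(duplexTm("GCTAGCTAGG", 1e-6, 0.15), 34.361822, tolerance = 1e-3)
  ## ATATATATAT is self-complementary: symmetry-corrected reference value
  expect_equal(duplexTm("ATATATATAT", 1e-6, 0.15), 7.981481, tolerance = 1e-3)
  expect_equal(duplexTm("GCTAGCTAGG", 2e-6, 0.15), 36.156353, tolerance = 1e-3)
  expect_equal(duplexTm("GCTAGCTAGG", 1e-6, 0.50), 39.615516, tolerance = 1e-3)
  ## self-complementary duplex takes the symmetry correction
  expect_equal(duplexTm("GCGCGCGCGC", 1e-6, 0.15), 62.718699, tolerance = 1e-3)
  ## in-suite oracle agreement within 0.1 degC on random non-self-comp 10-mers
  set.seed(101)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    if (identical(s, sheetkit:::.revcomp(s))) next
    expect_equal(duplexTm(s, 1e-6, 0.15), brute_tm(s, 1e-6, 0.15),
                 tolerance = 0.1)
  }
})

test_that("Tm input validation rejects bad domains", {
  expect_error(duplexTm("ACGX"), "non-ACGT")
  expect_error(duplexTm("A"), "shorter than 2")
})

test_that("divalent salt raises Tm through the equivalent-monovalent heuristic", {
  t0 <- duplexTm("GCTAGCTAGG", 1e-6, 0.15, 0)
  t_mg <- duplexTm("GCTAGCTAGG", 1e-6, 0.15, 0.0125)
  expect_gt(t_mg, t0)
})

test_that("domain Tm ordering follows duplex length: core > arm > sticky ends", {
  for (seed in 1:100) {
    d <- makeDesignSequences(FUnitDesign(), seed = seed)
    tms <- domainMeltingTemperatures(d)
    expect_gt(tms@tmCore, tms@tmArm)
    expect_gt(tms@tmArm, tms@tmSe1)
    expect_gt(tms@tmArm, tms@tmSe2)
  }
})

test_that("appending a G:C pair never lowers the melting temperature", {
  set.seed(202)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    expect_gte(duplexTm(paste0(s, "G")), duplexTm(s))
  }
})
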