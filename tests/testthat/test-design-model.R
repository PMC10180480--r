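test_that("the default design passes every validation check", {
  rep <- validateDesign(makeDesignSequences(FUnitDesign(), seed = 3))
  expect_true(all(rep$pass[!is.na(rep$pass)]))
  expect_true(all(c("stoichiometry", "core_complementarity",
                    "se1_complementarity") %in% rep$check))
})

test_that("stoichiometry and complementarity violations are reported, not thrown", {
  d <- FUnitDesign(stoichiometry = c(1, 2, 10))
  rep <- validateDesign(d)
  row <- rep[rep$check == "stoichiometry", ]
  expect_false(row$pass)
  expect_match(row$message, "m must equal n")
  expect_true(validateDesign(FUnitDesign(stoichiometry = c(2, 2, 20)))[
    2, "pass"])  # scaled ratio still satisfies m = n = p/10
  expect_false(validateDesign(FUnitDesign(stoichiometry = c(1, 1, 12)))[
    2, "pass"])
  ## inject one mismatch into SE1* on strand B
  d2 <- makeDesignSequences(FUnitDesign(), seed = 3)
  b <- strsplit(d2@sequences$B, "")[[1]]
  b[4] <- setdiff(c("A", "C", "G", "T"), b[4])[1]
  d2@sequences$B <- paste(b, collapse = "")
  rep2 <- validateDesign(d2)
  row2 <- rep2[rep2$check == "se1_complementarity", ]
  expect_false(row2$pass)
  expect_match(row2$message, "se1_complementarity at offset 4")
})

test_that("named annealing protocols expand ramps into stepwise holds", {
  fap_a <- annealingProtocol("FAP-A")
  ## 5 + 10 + 10 + 60 + (16 ramp steps x 5) + 30
  expect_equal(sum(fap_a@steps$durationMin), 195)
  ramp <- fap_a@steps$temperatureC[5:20]
  expect_equal(ramp, seq(41, 26))
  expect_true(all(fap_a@steps$durationMin > 0))
  sap_a <- annealingProtocol("SAP-A")
  ## holds 5+180+180+360+360+2 = 1087; ramps 21+8+16+1 = 46 steps x 5 min
  expect_equal(sum(sap_a@steps$durationMin), 1087 + 46 * 5)
  expect_equal(annealingProtocol("FAP-C")@steps$durationMin[
    nrow(annealingProtocol("FAP-C")@steps)], 1440)
})

test_that("assembly order follows the melting hierarchy and matches a brute-force scan", {
  tms <- new("DomainTmSet", tmCore = 70, tmArm = 55, tmSe1 = 35, tmSe2 = 35,
             conditions = list(strandConcM = 1e-6, monovalentM = 0.15,
                               divalentM = 0))
  ord <- assemblyOrder(tms, annealingProtocol("FAP-A"))
  expect_equal(ord$domain[1], "core")
  expect_equal(ord$domain[2], "arm")
  expect_setequal(ord$domain[3:4], c("se1", "se2"))
  expect_true(all(diff(ord$timeMin) >= 0))
  ## never-bound case: held above every Tm
  hot <- annealingProtocol("custom",
                           data.frame(temperatureC = 95, durationMin = 60))
  ord_hot <- assemblyOrder(tms, hot)
  expect_true(all(!ord_hot$bound))
  expect_true(all(is.na(ord_hot$timeMin)))
  ## brute-force minute scan oracle over all five named protocols
  for (pname in c("FAP-A", "FAP-B", "FAP-C", "SAP-A", "SAP-B")) {
    prot <- annealingProtocol(pname)
    ord_p <- assemblyOrder(tms, prot)
    for (dom in ord_p$domain) {
      tm <- c(core = 70, arm = 55, se1 = 35, se2 = 35)[[dom]]
      expect_equal(ord_p$timeMin[ord_p$domain == dom],
                   brute_schedule_scan(tm, prot))
    }
  }
})

test_that("the ideal F-unit realizes requested angles; planar sets give a planar model", {
  d <- FUnitDesign()
  m <- buildIdealFUnit(d)
  expect_equal(unname(m@junctions["J2", ] - m@junctions["J1", ]),
               c(21 * 0.34, 0, 0))
  ang <- interArmAngles(m@armDirections)
  expect_equal(unname(ang), c(80, 150, 120, 80, 150, 120), tolerance = 1e-9)
  expect_equal(sum(ang[1:3]), 350)
  ## planar-consistent set: exactly planar, d_p = 0 at both junctions
  mp <- buildIdealFUnit(d, c(90, 150, 120))
  for (e in mp@armDirections) expect_equal(e[3], 0)
  expect_equal(planarityDp(m@junctions["J1", ], mp@armDirections$e1,
                           mp@armDirections$e2, mp@armDirections$e3), 0)
  expect_equal(planarityDp(m@junctions["J2", ], mp@armDirections$e4,
                           mp@armDirections$e5, mp@armDirections$e6), 0)
  angp <- interArmAngles(mp@armDirections)
  expect_equal(unname(angp[1:3]), c(90, 150, 120), tolerance = 1e-9)
  expect_error(buildIdealFUnit(d, c(170, 170, 170)), "impossible")
})

test_that("pore lattice geometry matches the parallelogram closed forms", {
  d <- FUnitDesign()
  lat <- poreLatticeGeometry(d, 80)
  expect_equal(lat@sideLongBp, 63)
  expect_equal(lat@sideShortBp, 42)
  expect_equal(lat@sideLongNm, 63 * 0.34)
  expect_equal(lat@sideShortNm, 42 * 0.34)
  a <- lat@sideLongNm; b <- lat@sideShortNm; th <- 80 * pi / 180
  expect_equal(lat@diagLongNm, sqrt(a^2 + b^2 + 2 * a * b * cos(th)))
  expect_equal(lat@diagShortNm, sqrt(a^2 + b^2 - 2 * a * b * cos(th)))
  ## parallelogram law
  expect_equal(lat@diagLongNm^2 + lat@diagShortNm^2, 2 * (a^2 + b^2),
               tolerance = 1e-9)
  ## right-angle limit: both diagonals collapse to sqrt(a^2 + b^2)
  sq <- poreLatticeGeometry(FUnitDesign(), 90)
  expect_equal(sq@diagLongNm, sq@diagShortNm)
  expect_equal(sq@diagLongNm, sqrt(sq@sideLongNm^2 + sq@sideShortNm^2))
})

test_that("lattice porosity follows the strip-ownership closed form and its limits", {
  d <- FUnitDesign()
  lat <- poreLatticeGeometry(d, 80)
  a <- lat@sideLongNm; b <- lat@sideShortNm
  phi <- latticePorosity(lat, 2)
  expect_equal(phi, 1 - ((a + b - 2) * 2) / (a * b * sin(80 * pi / 180)))
  expect_gte(phi, 0.40)
  ## w -> 0 gives phi -> 1
  expect_gt(latticePorosity(lat, 1e-9), 1 - 1e-6)
  ## a = b = 2w, theta = 90: phi = 1 - 3w^2 / 4w^2 = 0.25
  sq <- new("LatticeGeometry", sideLongBp = 4, sideShortBp = 4,
            sideLongNm = 4, sideShortNm = 4, junctionAngleDeg = 90,
            diagLongNm = 4 * sqrt(2), diagShortNm = 4 * sqrt(2),
            porosityFraction = NA_real_)
  expect_equal(latticePorosity(sq, 2), 0.25)
  expect_error(latticePorosity(sq, 5), "smaller than")
})

test_that("cholesterol spacings reproduce the sticky-end and arm-bridge contours", {
  d <- FUnitDesign()
  sp <- cholesterolSpacings(d)
  expect_equal(sp$minNm, 10 * 0.34)            # sticky-end bridge, ~3.4 nm
  expect_equal(sp$maxNm, (2 * 16 + 10) * 0.34) # arm-SE-arm bridge, ~14.3 nm
  ## rigid-motion invariance
  set.seed(9)
  R <- random_rotation(); shift <- rnorm(3, 0, 50)
  m <- buildIdealFUnit(d)
  m@junctions <- sweep(m@junctions %*% t(R), 2, shift, "+")
  m@armDirections <- lapply(m@armDirections, function(v) as.numeric(R %*% v))
  m@cholesterolSites <- lapply(m@cholesterolSites,
                               function(v) as.numeric(R %*% v) + shift)
  sp2 <- cholesterolSpacings(d, model = m)
  expect_equal(sp2$minNm, sp$minNm, tolerance = 1e-9)
  expect_equal(sp2$maxNm, sp$maxNm, tolerance = 1e-9)
  ## degenerate rise
  d0 <- FUnitDesign(riseNm = 0)
  expect_equal(cholesterolSpacings(d0)$maxNm, 0)
  ## missing anchors
  expect_error(
    cholesterolSpacings(FUnitDesign(cholesterolSites = data.frame())),
    "no cholesterol")
})
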