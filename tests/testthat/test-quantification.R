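test_that("slice areas follow pixel count times pixel area", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE     # 100 pixels
  expect_equal(sliceArea(m, c(1, 1)), 100)
  expect_equal(sliceArea(m, c(1.4, 1.4)), 196)
  expect_equal(sliceArea(m & FALSE, c(1.4, 1.4)), 0)
  expect_error(sliceArea(m, c(0, 1)), "positive")
})

test_that("total LGE volume and mass follow the stated arithmetic", {
  tot <- totalLGE(rep(200, 3), sliceThicknessMm = 8, densityGPerMl = 1.05)
  expect_equal(tot$totalVolumeMl, 4.8)
  expect_equal(tot$totalMassG, 5.04)
  expect_equal(totalLGE(numeric(0), 8)$totalMassG, 0)
  expect_equal(totalLGE(rep(0, 5), 8)$totalMassG, 0)
  # include-gap option adds the gap to the slice extent
  tg <- totalLGE(rep(200, 3), 8, 1.05, sliceGapMm = 2, includeGap = TRUE)
  expect_equal(tg$totalVolumeMl, 6.0)
})

test_that("phantom truth mass equals a one-line voxel-counting oracle", {
  ph <- generatePhantom(smallPhantomSpec(404))
  spec <- ph@spec
  npx <- sum(vapply(truthMasks(ph), sum, numeric(1)))
  oracle <- npx * prod(spec@pixelSpacingMm) * spec@sliceThicknessMm * 1.05 / 1000
  expect_equal(truthTotalMass(ph), oracle)
})

test_that("LV mass derives from the annulus area", {
  fx <- annulusFixture()
  slices <- lapply(1:3, function(i)
    lgeSlice(sliceImage(fx$pixels, pixelSpacing = 1, sliceThicknessMm = 8,
                        sliceGapMm = 2, sliceIndex = i),
             fx$contours, lgePositive = FALSE))
  st <- lgeStudy("annulus", slices)
  # three annuli of ~pi*300 px at 1 mm^2, 8 mm, 1.05 g/ml
  expect_lt(abs(lvMass(st) - 3 * pi * 300 * 8 * 1.05 / 1000) /
              (3 * pi * 300 * 8 * 1.05 / 1000), 0.02)
  expect_error(lvMass(lgeStudy("x", list())), "at least one slice")
})

test_that("lge percent saturates at 100 when LGE fills the myocardium", {
  fx <- annulusFixture()
  px <- fx$pixels
  px[fx$myo] <- 200
  slices <- lapply(1:2, function(i)
    lgeSlice(sliceImage(px, 1, 8, 2, i), fx$contours,
             roiCore = referenceROI(rectPolygon(fx$center[1] + 11,
                                                fx$center[1] + 18,
                                                fx$center[2] - 3,
                                                fx$center[2] + 3),
                                    "enhancement_core"),
             lgePositive = TRUE))
  st <- lgeStudy("full", slices)
  seg <- segmentStudy(st, "FWHM")        # threshold 100, all myocardium > 100
  res <- quantifyStudy(st, seg)
  expect_equal(res@lgePercentOfLv, 100)
  expect_equal(res@totalMassG, res@lvMassG)
})

test_that("totals are additive over any partition of the slices", {
  ph <- generatePhantom(smallPhantomSpec(77))
  st <- phantomStudy(ph)
  seg <- segmentPhantom(ph, methods = "STRM3")
  whole <- totalLGE(seg$lge_area_mm2, 8, 1.05)$totalMassG
  parts <- split(seg, seg$slice_index %% 2)
  expect_equal(whole, sum(vapply(parts, function(p)
    totalLGE(p$lge_area_mm2, 8, 1.05)$totalMassG, numeric(1))))
})

test_that("doubling the pixel spacing quadruples area and mass exactly", {
  withr::with_seed(8, {
    m <- matrix(runif(30 * 30) < 0.2, 30, 30)
    expect_equal(sliceArea(m, c(2.8, 2.8)), 4 * sliceArea(m, c(1.4, 1.4)))
    t1 <- totalLGE(sliceArea(m, 1), 8, 1.05)$totalMassG
    t2 <- totalLGE(sliceArea(m, 2), 8, 1.05)$totalMassG
    expect_equal(t2, 4 * t1)
  })
})

test_that("%LV is invariant under global SI rescaling", {
  ph <- generatePhantom(smallPhantomSpec(55))
  st <- phantomStudy(ph)
  pct <- function(study) {
    seg <- segmentStudy(study, c("STRM3", "FWHM", "OAT"))
    tt <- studyTotals(study, seg)
    tt$lge_pct[order(tt$method)]
  }
  scaled <- lgeStudy(studyId(st), lapply(studySlices(st), function(sl) {
    sl@image@pixels <- sl@image@pixels * 3.7
    sl
  }))
  expect_equal(pct(scaled), pct(st), tolerance = 1e-10)
})
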