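test_that("phantom generation is a pure function of spec and seed", {
  p1 <- generatePhantom(smallPhantomSpec(123))
  p2 <- generatePhantom(smallPhantomSpec(123))
  expect_identical(lapply(studySlices(phantomStudy(p1)), function(s) pixels(s@image)),
                   lapply(studySlices(phantomStudy(p2)), function(s) pixels(s@image)))
  expect_identical(truthMasks(p1), truthMasks(p2))
  expect_identical(truthTotalMass(p1), truthTotalMass(p2))
  p3 <- generatePhantom(smallPhantomSpec(124))
  expect_false(identical(truthMasks(p1), truthMasks(p3)))
})

test_that("truth masks live inside the myocardium and match the flags", {
  ph <- generatePhantom(smallPhantomSpec(31))
  st <- phantomStudy(ph)
  for (i in seq_along(studySlices(st))) {
    sl <- studySlices(st)[[i]]
    myo <- buildMyocardiumMask(sl@contours, dim(pixels(sl@image)))
    tr <- truthMasks(ph)[[i]]
    expect_true(all(myo | !tr))                       # truth subset of myocardium
    expect_equal(sl@lgePositive, any(tr))
    if (sl@lgePositive) {
      # auto ROIs respect the clinical rules
      remMask <- rasterizePolygon(sl@roiRemote@polygon, dim(myo)) & myo
      expect_gte(sum(remMask), 2)
      expect_false(any(remMask & tr))                 # remote ROI lesion-free
      coreMask <- rasterizePolygon(sl@roiCore@polygon, dim(myo)) & myo
      base_max <- max(pixels(sl@image)[tr])           # noisy, but core ROI must
      expect_true(any(coreMask & tr))                 # overlap the lesion
    }
  }
})

test_that("a zero-lesion spec yields an LGE-negative phantom", {
  ph <- generatePhantom(smallPhantomSpec(9, nLesions = 0))
  expect_true(all(!vapply(studySlices(phantomStudy(ph)),
                          function(s) s@lgePositive, logical(1))))
  expect_equal(truthTotalMass(ph), 0)
  seg <- segmentPhantom(ph)
  expect_true(all(seg$n_pixels == 0))
})

test_that("noise-free separable phantoms are recovered exactly by all methods", {
  spec <- smallPhantomSpec(61, borderZoneFraction = 0, remoteSdSi = 0,
                           shadingAmp = 0, probLgePositive = 1)
  ph <- generatePhantom(spec)
  st <- phantomStudy(ph)
  seg <- segmentPhantom(ph, methods = lgeMethods(includeManual = TRUE),
                        config = lgeConfig())
  for (i in seq_along(studySlices(st))) {
    sl <- studySlices(st)[[i]]
    if (!sl@lgePositive) next
    myo <- buildMyocardiumMask(sl@contours, dim(pixels(sl@image)))
    tr <- truthMasks(ph)[[i]]
    for (m in lgeMethods(includeManual = TRUE)) {
      r <- segmentSlice(sl, m, myoMask = myo, targetMask = tr)
      expect_identical(bareMask(lgeMask(r)), bareMask(tr),
                       label = sprintf("slice %d method %s", i, m))
    }
  }
  tt <- studyTotals(st, seg)
  expect_true(all(abs(tt$total_lge_g - truthTotalMass(ph)) < 1e-9))
})

test_that("observer simulation is deterministic and identity at zero perturbation", {
  ph <- generatePhantom(smallPhantomSpec(88))
  same <- simulateObserver(ph, roiJitterPx = 0, roiSizeScale = c(1, 1),
                           roiRotationRad = 0, seed = 4L)
  expect_equal(same@study, phantomStudy(ph))
  o1 <- simulateObserver(ph, seed = 42L)
  o2 <- simulateObserver(ph, seed = 42L)
  expect_equal(o1@study, o2@study)
  o3 <- simulateObserver(ph, seed = 43L)
  expect_false(identical(o1@study, o3@study))
})

test_that("observers agree exactly on a noise-free uniform-lesion phantom", {
  spec <- smallPhantomSpec(71, borderZoneFraction = 0, remoteSdSi = 0,
                           shadingAmp = 0, probLgePositive = 1)
  ph <- generatePhantom(spec)
  seg1 <- segmentPhantom(simulateObserver(ph, seed = 1L), lgeMethods())
  seg2 <- segmentPhantom(simulateObserver(ph, seed = 2L), lgeMethods())
  expect_equal(seg1$threshold, seg2$threshold)
  expect_equal(seg1$n_pixels, seg2$n_pixels)
})

test_that("experiment runners are reproducible per seed", {
  a1 <- runAccuracyExperiment(3L, smallPhantomSpec(1), seed = 77L)
  a2 <- runAccuracyExperiment(3L, smallPhantomSpec(1), seed = 77L)
  expect_identical(a1$totals, a2$totals)
  expect_identical(a1$ranked, a2$ranked)
  r1 <- runReproducibilityExperiment(2L, smallPhantomSpec(1), seed = 5L)
  r2 <- runReproducibilityExperiment(2L, smallPhantomSpec(1), seed = 5L)
  expect_identical(r1$table, r2$table)
})

test_that("manual sweep against truth tracks the true mass", {
  acc <- runAccuracyExperiment(4L, smallPhantomSpec(3), methods = "STRM3",
                               seed = 11L)
  man <- acc$totals[acc$totals$method == "MANUAL", ]
  man <- man[order(man$study_id), ]
  tr <- acc$truth[order(acc$truth$study_id), ]
  # the reference standard should stay close to the known truth
  expect_lt(mean(abs(man$total_lge_g - tr$truth_mass_g)),
            0.2 * max(mean(tr$truth_mass_g), 1))
})
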