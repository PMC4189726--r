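# Unit tests for the eight threshold operators.

# Fixture: annulus whose remote ROI covers exactly the prescribed values
# (one-row strip of length(remoteVals) pixels) and whose lesion patch holds
# a prescribed intensity.
makeSlice <- function(remoteVals, lesionSi = 200, n = 45) {
  fx <- annulusFixture(n = n)
  px <- fx$pixels
  K <- length(remoteVals)
  stopifnot(K <= 9)              # annulus width at the mid row
  c0 <- fx$center[2] + 11
  roiPoly <- rectPolygon(fx$center[1] - 0.45, fx$center[1] + 0.45,
                         c0 - 0.45, c0 + K - 1 + 0.45)
  roiMask <- rasterizePolygon(roiPoly, c(n, n)) & fx$myo
  stopifnot(sum(roiMask) == K)
  px[which(roiMask)] <- remoteVals
  lesionMask <- rasterizePolygon(
    rectPolygon(fx$center[1] + 11, fx$center[1] + 18,
                fx$center[2] - 3, fx$center[2] + 3), c(n, n)) & fx$myo
  px[lesionMask] <- lesionSi
  list(image = sliceImage(px), myo = fx$myo, lesion = lesionMask,
       roi = referenceROI(roiPoly, "remote_myocardium"),
       corePoly = rectPolygon(fx$center[1] + 11, fx$center[1] + 18,
                              fx$center[2] - 3, fx$center[2] + 3))
}

test_that("STRM threshold is mean + k * sd of the remote ROI", {
  sl <- makeSlice(rep(100, 4))
  r <- strmThreshold(sl$image, sl$myo, sl$roi, k = 3)
  expect_equal(threshold(r), 100)          # zero-variance reference
  expect_identical(bareMask(lgeMask(r)), bareMask(sl$myo & pixels(sl$image) > 100))

  sl2 <- makeSlice(c(90, 100, 110))
  r2 <- strmThreshold(sl2$image, sl2$myo, sl2$roi, k = 3)
  expect_equal(threshold(r2), 100 + 3 * sqrt(200 / 3))   # population SD
  r2s <- strmThreshold(sl2$image, sl2$myo, sl2$roi, k = 3, sdEstimator = "sample")
  expect_equal(threshold(r2s), 100 + 3 * 10)

  expect_error(strmThreshold(sl$image, sl$myo, NULL, 3), "remote_myocardium")
  one <- makeSlice(123)
  expect_error(strmThreshold(one$image, one$myo,
                             referenceROI(rectPolygon(1.6, 2.4, 1.6, 2.4),
                                          "remote_myocardium"), 3),
               "disjoint")
})

test_that("separable lesion is recovered identically for k = 2 and k = 6", {
  # remote values with mean 100, population sd 10; lesion SI 200
  sl <- makeSlice(rep(c(90, 110), 4), lesionSi = 200)
  r2 <- strmThreshold(sl$image, sl$myo, sl$roi, 2)
  r6 <- strmThreshold(sl$image, sl$myo, sl$roi, 6)
  expect_equal(threshold(r2), 120)
  expect_equal(threshold(r6), 160)
  # remote ROI pixels (90/110) are below both thresholds; the lesion is not
  expect_identical(lgeMask(r2), lgeMask(r6))
  expect_identical(unname(lgeMask(r2) | sl$lesion), unname(lgeMask(r2) | sl$lesion))
  expect_true(all(lgeMask(r2)[sl$lesion]))
})

test_that("STRM masks are nested and non-increasing in k", {
  withr::with_seed(7, {
    fx <- annulusFixture()
    px <- fx$pixels
    px[fx$myo] <- rlnorm(sum(fx$myo), log(100), 0.4)
    img <- sliceImage(px)
    roi <- referenceROI(rectPolygon(fx$center[1] - 2.5, fx$center[1] + 2.5,
                                    fx$center[2] + 11, fx$center[2] + 19),
                        "remote_myocardium")
    masks <- lapply(2:6, function(k) lgeMask(strmThreshold(img, fx$myo, roi, k)))
    for (i in 1:4) {
      expect_true(all(masks[[i]] | !masks[[i + 1]]))   # mask(k+1) subset mask(k)
      expect_lte(sum(masks[[i + 1]]), sum(masks[[i]]))
    }
  })
})

test_that("FWHM threshold is half the core maximum (or mid-range)", {
  sl <- makeSlice(rep(100, 8), lesionSi = 200)
  core <- referenceROI(sl$corePoly, "enhancement_core")
  r <- fwhmThreshold(sl$image, sl$myo, core)
  expect_equal(threshold(r), 100)
  expect_equal(referenceStats(r)$maxSi, 200)

  # uniform myocardium: threshold 50, whole myocardium segmented
  fx <- annulusFixture(fill = 100)
  coreAll <- referenceROI(rectPolygon(fx$center[1] + 11, fx$center[1] + 18,
                                      fx$center[2] - 3, fx$center[2] + 3),
                          "enhancement_core")
  ru <- fwhmThreshold(sliceImage(fx$pixels), fx$myo, coreAll)
  expect_equal(threshold(ru), 50)
  expect_identical(bareMask(lgeMask(ru)), bareMask(fx$myo))

  # half-range mode sits midway between core max and min
  rr <- fwhmThreshold(sl$image, sl$myo, core, fwhmMode = "half_range")
  expect_equal(threshold(rr), min(referenceStats(rr)$minSi) +
                 0.5 * (200 - referenceStats(rr)$minSi))
})

test_that("FWHM excludes a faint patch that STRM3 includes", {
  # remote mean 100 sd 5, dense core 300, faint patch 130
  fx <- annulusFixture()
  px <- fx$pixels
  roiPoly <- rectPolygon(fx$center[1] - 2.4, fx$center[1] + 2.4,
                         fx$center[2] + 11, fx$center[2] + 19)
  roiMask <- rasterizePolygon(roiPoly, c(45, 45)) & fx$myo
  px[roiMask] <- rep(c(95, 105), length.out = sum(roiMask))   # mean 100 sd 5
  corePoly <- rectPolygon(fx$center[1] + 12, fx$center[1] + 16,
                          fx$center[2] - 2, fx$center[2] + 2)
  coreMask <- rasterizePolygon(corePoly, c(45, 45)) & fx$myo
  px[coreMask] <- 300
  faintMask <- rasterizePolygon(
    rectPolygon(fx$center[1] - 16, fx$center[1] - 12,
                fx$center[2] - 2, fx$center[2] + 2), c(45, 45)) & fx$myo
  px[faintMask] <- 130
  img <- sliceImage(px)
  rf <- fwhmThreshold(img, fx$myo, referenceROI(corePoly, "enhancement_core"))
  rs <- strmThreshold(img, fx$myo, referenceROI(roiPoly, "remote_myocardium"), 3)
  expect_equal(threshold(rf), 150)
  expect_equal(threshold(rs), 115)
  expect_false(any(lgeMask(rf)[faintMask]))
  expect_true(all(lgeMask(rs)[faintMask]))
  expect_lt(sum(lgeMask(rf)), sum(lgeMask(rs)))
})

test_that("Otsu separates a two-level image and matches the value oracle", {
  fx <- annulusFixture()
  px <- fx$pixels
  vals <- rep(c(50, 200), times = c(60, 40))
  px[which(fx$myo)[seq_along(vals)]] <- vals
  px[fx$myo & px == 100] <- 50          # remaining myocardium at the low level
  r <- otsuThreshold(sliceImage(px), fx$myo)
  expect_gte(threshold(r), 50)
  expect_lt(threshold(r), 200)
  expect_identical(bareMask(lgeMask(r)), bareMask(fx$myo & px == 200))

  expect_error(otsuThreshold(sliceImage(annulusFixture()$pixels),
                             annulusFixture()$myo), "Otsu undefined")
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  withr::with_seed(11, {
    fx <- annulusFixture()
    for (rep in 1:6) {
      px <- fx$pixels
      v <- round(c(rnorm(sum(fx$myo) * 0.7, 100, 12),
                   rnorm(sum(fx$myo) * 0.3, 230, 25)))
      v <- pmax(v[seq_len(sum(fx$myo))], 0)
      px[fx$myo] <- v
      r <- otsuThreshold(sliceImage(px), fx$myo)
      cand <- min(v):(max(v) - 1)
      prof <- oracleOtsuProfile(v, cand)
      expect_equal(referenceStats(r)$betweenClassVariance, max(prof),
                   tolerance = 1e-12)
      expect_equal(threshold(r), cand[which.max(prof)])
    }
  })
})

test_that("bimodal myocardium yields an Otsu threshold between the modes", {
  withr::with_seed(3, {
    fx <- annulusFixture()
    px <- fx$pixels
    nmyo <- sum(fx$myo)
    v <- c(rnorm(ceiling(nmyo / 2), 100, 10), rnorm(floor(nmyo / 2), 250, 10))
    px[fx$myo] <- pmax(v, 0)
    r <- otsuThreshold(sliceImage(px), fx$myo)
    expect_gt(threshold(r), 130)
    expect_lt(threshold(r), 220)
    # continuous path agrees with the histogram oracle at the same binning
    vals <- px[fx$myo]
    breaks <- seq(min(vals), max(vals), length.out = 1025)
    counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE), 1024)
    mids <- (breaks[-1] + breaks[-1025]) / 2
    prof <- oracleOtsuHistProfile(counts, mids)
    expect_equal(referenceStats(r)$betweenClassVariance, max(prof),
                 tolerance = 1e-9)
    expect_equal(threshold(r), breaks[-c(1, 1025)][which.max(prof)])
  })
})

test_that("manual sweep recovers the threshold that generated the target", {
  withr::with_seed(21, {
    fx <- annulusFixture()
    px <- fx$pixels
    px[fx$myo] <- sample(10:80, sum(fx$myo), replace = TRUE)
    img <- sliceImage(px)
    target <- fx$myo & px > 36
    r <- manualThresholdSweep(img, fx$myo, target)
    expect_equal(threshold(r), 36)
    expect_equal(referenceStats(r)$dice, 1)
    expect_identical(bareMask(lgeMask(r)), bareMask(target))
  })
})

test_that("manual sweep handles the degenerate targets", {
  fx <- annulusFixture()
  px <- fx$pixels
  px[fx$myo] <- seq_len(sum(fx$myo))
  img <- sliceImage(px)
  # target = entire myocardium -> threshold 0 (sweep start, 100% enhancement)
  r <- manualThresholdSweep(img, fx$myo, fx$myo)
  expect_equal(threshold(r), 0)
  # empty target -> threshold above the myocardial maximum, zero LGE, flagged
  r0 <- manualThresholdSweep(img, fx$myo, fx$myo & FALSE)
  expect_true(r0@flags$emptyTarget)
  expect_equal(sum(lgeMask(r0)), 0)
  expect_gte(threshold(r0), max(px[fx$myo]))
  expect_error(manualThresholdSweep(img, fx$myo, !fx$myo), "subset")
})

test_that("manual sweep attains the exhaustive-sweep Dice maximum", {
  withr::with_seed(33, {
    for (rep in 1:4) {
      fx <- annulusFixture()
      px <- fx$pixels
      px[fx$myo] <- rlnorm(sum(fx$myo), log(80), 0.5)
      img <- sliceImage(px)
      truthMask <- fx$myo & px > quantile(px[fx$myo], 0.8)
      noisy <- px + matrix(rnorm(45 * 45, 0, 8), 45, 45)
      noisy[noisy < 0] <- 0
      imgN <- sliceImage(noisy)
      r <- manualThresholdSweep(imgN, fx$myo, truthMask)
      cands <- c(0, sort(unique(noisy[fx$myo])))
      oracleDice <- vapply(cands, function(t)
        diceCoefficient(fx$myo & noisy > t, truthMask), numeric(1))
      expect_equal(referenceStats(r)$dice, max(oracleDice), tolerance = 1e-12)
      expect_equal(threshold(r), cands[which.max(oracleDice)])
    }
  })
})

test_that("raising any returned threshold never adds pixels", {
  withr::with_seed(5, {
    fx <- annulusFixture()
    px <- fx$pixels
    px[fx$myo] <- rlnorm(sum(fx$myo), log(100), 0.5)
    img <- sliceImage(px)
    roi <- referenceROI(rectPolygon(fx$center[1] - 2.5, fx$center[1] + 2.5,
                                    fx$center[2] + 11, fx$center[2] + 19),
                        "remote_myocardium")
    r <- strmThreshold(img, fx$myo, roi, 2)
    for (eps in c(1e-9, 0.5, 5, 50)) {
      up <- fx$myo & px > (threshold(r) + eps)
      expect_true(all(lgeMask(r) | !up))
    }
  })
})

test_that("post-processing removes only sub-threshold components", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2] <- TRUE; m[2, 3] <- TRUE       # 3-pixel component
  expect_identical(applyPostprocessing(m), m)                  # default: identity
  expect_equal(sum(applyPostprocessing(m, minComponentPx = 4)), 0)

  withr::with_seed(9, {
    rnd <- matrix(runif(40 * 40) < 0.35, 40, 40)
    out <- applyPostprocessing(rnd, connectivity = 8, minComponentPx = 5)
    lab <- oracleLabel(out, 8)
    if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 5))
    # removed pixels all belonged to small components of the input
    labIn <- oracleLabel(rnd, 8)
    removed <- rnd & !out
    if (any(removed))
      expect_true(all(tabulate(labIn[labIn > 0])[labIn[removed]] < 5))
  })
})

test_that("component labeling matches independent implementations", {
  withr::with_seed(14, {
    m <- matrix(runif(30 * 30) < 0.3, 30, 30)
    for (conn in c(4, 8)) {
      lab <- labelComponents(m, conn)
      orc <- oracleLabel(m, conn)
      # same partition: label images agree up to renumbering
      expect_equal(max(lab), max(orc))
      expect_true(all((lab > 0) == m))
      key <- paste(lab[m], orc[m])
      expect_equal(length(unique(key)), max(lab))
    }
    # EBImage::bwlabel is 4-connectivity; cross-check that case
    eb <- EBImage::bwlabel(m * 1)
    expect_equal(max(labelComponents(m, 4)), max(eb))
  })
})

test_that("segmentSlice dispatches and respects LGE-negative flags", {
  sl <- makeSlice(rep(c(90, 110), 4), lesionSi = 200)
  lslice <- lgeSlice(sl$image,
                     annulusFixture()$contours,
                     roiRemote = sl$roi,
                     roiCore = referenceROI(sl$corePoly, "enhancement_core"),
                     lgePositive = TRUE)
  r <- segmentSlice(lslice, "strm4")
  expect_equal(methodName(r), "STRM4")
  expect_equal(threshold(r), 140)
  neg <- lgeSlice(sl$image, annulusFixture()$contours, roiRemote = sl$roi,
                  lgePositive = FALSE)
  for (m in c("STRM3", "FWHM", "OAT")) {
    rn <- segmentSlice(neg, m)
    expect_true(is.na(threshold(rn)))
    expect_equal(sum(lgeMask(rn)), 0)
    expect_true(rn@flags$lgeNegative)
  }
  expect_error(segmentSlice(lslice, "BOGUS"), "unknown method")
})
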