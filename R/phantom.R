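# Synthetic short-axis LGE phantom with known scar ground truth.
#
# The generator emulates the enhancement pattern of hypertrophic
# cardiomyopathy: an annular myocardium containing patchy, non-uniform
# lesions whose intensity distribution is dominated by faint-to-moderate
# "dispersed fibrosis" (a graded border zone with exponentially decaying
# intensity mass) around a small dense core that carries the maximum signal.
# Remote myocardium sits at a nominal mean with Rician (magnitude-MR) noise.
# Reference regions are auto-derived from the ground truth, mirroring the
# two clinical rules: the remote ROI is the largest lesion-free annular
# sector, the core ROI a small disk containing the maximum-intensity lesion
# pixel.

#' Phantom specification
#'
#' Parameters of the synthetic short-axis study generator; defaults encode
#' the study conditions the pipeline is designed for (8 mm slices with 2 mm
#' gap; 68\% of subjects LGE-positive; patchy lesions whose intensity mass
#' decays from a faint border zone toward a small dense core).
#'
#' @param imageSize square image size in pixels.
#' @param pixelSpacingMm in-plane spacing (mm), length 1 or 2.
#' @param nSlices slices per study (apex to base).
#' @param sliceThicknessMm slice thickness (mm).
#' @param sliceGapMm inter-slice gap (mm).
#' @param epiRadiusPx,endoRadiusPx epicardial/endocardial radii at
#'   mid-ventricle (px); slices taper toward apex and base.
#' @param remoteMeanSi nominal SI of non-enhanced (remote) myocardium.
#' @param remoteSdSi noise sigma; on magnitude images this is what produces
#'   the remote-myocardium SD.  0 gives a noise-free phantom.
#' @param lesionCoreSi peak lesion SI (the dense-core maximum).
#' @param borderZoneSi faintest lesion SI (the border-zone floor); must
#'   exceed \code{remoteMeanSi}.
#' @param borderZoneFraction fraction of each lesion's pixels in the graded
#'   border zone (the remainder forms the dense core).  0 gives two-level
#'   core-only lesions (fully separable from remote tissue).
#' @param borderDecaySi exponential decay scale (SI units) of the border-zone
#'   intensity distribution above its floor: most border pixels are faint,
#'   few approach the core.
#' @param nLesions mean lesion count per slice (Poisson) in LGE-positive
#'   studies; 0 forces an LGE-negative phantom.
#' @param lesionAreaMeanPx median lesion area (px; log-normal sizes).
#' @param lesionAreaSdLog log-scale SD of lesion area.
#' @param lesionAreaRangePx clip range for lesion areas (px).
#' @param probLgePositive probability that a study shows any LGE.
#' @param shadingAmp amplitude of the smooth multiplicative intensity-shading
#'   field (surface-coil inhomogeneity): the field spans roughly
#'   \code{1 +/- shadingAmp} across the image.  0 disables shading.
#' @param noiseModel \code{"rician"} (magnitude MR; default),
#'   \code{"gaussian"} (clipped at 0) or \code{"none"}.
#' @param rngSeed integer seed; generation is a pure function of
#'   (spec, seed).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(imageSize = 96L,
                        pixelSpacingMm = c(1.4, 1.4),
                        nSlices = 6L,
                        sliceThicknessMm = 8,
                        sliceGapMm = 2,
                        epiRadiusPx = 28,
                        endoRadiusPx = 16,
                        remoteMeanSi = 100,
                        remoteSdSi = 10,
                        lesionCoreSi = 280,
                        borderZoneSi = 122,
                        borderZoneFraction = 0.94,
                        borderDecaySi = 10,
                        nLesions = 1.3,
                        lesionAreaMeanPx = 80,
                        lesionAreaSdLog = 0.6,
                        lesionAreaRangePx = c(12, 220),
                        probLgePositive = 0.68,
                        shadingAmp = 0.10,
                        noiseModel = c("rician", "gaussian", "none"),
                        rngSeed = 1L) {
  if (length(pixelSpacingMm) == 1L) pixelSpacingMm <- rep(pixelSpacingMm, 2L)
  new("PhantomSpec",
      imageSize = as.integer(imageSize),
      pixelSpacingMm = as.numeric(pixelSpacingMm),
      nSlices = as.integer(nSlices),
      sliceThicknessMm = as.numeric(sliceThicknessMm),
      sliceGapMm = as.numeric(sliceGapMm),
      epiRadiusPx = as.numeric(epiRadiusPx),
      endoRadiusPx = as.numeric(endoRadiusPx),
      remoteMeanSi = as.numeric(remoteMeanSi),
      remoteSdSi = as.numeric(remoteSdSi),
      lesionCoreSi = as.numeric(lesionCoreSi),
      borderZoneSi = as.numeric(borderZoneSi),
      borderZoneFraction = as.numeric(borderZoneFraction),
      borderDecaySi = as.numeric(borderDecaySi),
      nLesions = as.numeric(nLesions),
      lesionAreaMeanPx = as.numeric(lesionAreaMeanPx),
      lesionAreaSdLog = as.numeric(lesionAreaSdLog),
      lesionAreaRangePx = as.numeric(lesionAreaRangePx),
      probLgePositive = as.numeric(probLgePositive),
      shadingAmp = as.numeric(shadingAmp),
      noiseModel = match.arg(noiseModel),
      rngSeed = as.integer(rngSeed))
}

# Deterministic child seed, kept below 2^31.
childSeed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 9973 + j * 101 + 7) %% 2147483629)
}

# Lesion SI profile: ranks ascending from outermost (faintest) to innermost
# (brightest).  Border-zone intensities follow an exponential quantile map
# from the floor up to the core's lower edge; core intensities ramp linearly
# to the peak so exactly one pixel per lesion carries lesionCoreSi.
lesionIntensities <- function(s, spec) {
  b <- spec@borderZoneFraction
  if (b == 0) return(rep(spec@lesionCoreSi, s))   # uniform, fully separable
  nCore <- max(1L, round((1 - b) * s))
  nBorder <- s - nCore
  coreLo <- (spec@borderZoneSi + spec@lesionCoreSi) / 2
  si <- numeric(s)
  if (nBorder > 0L) {
    v <- (seq_len(nBorder) - 0.5) / nBorder
    tau <- spec@borderDecaySi
    cmax <- 1 - exp(-(coreLo - spec@borderZoneSi) / tau)
    si[seq_len(nBorder)] <- spec@borderZoneSi - tau * log(1 - v * cmax)
  }
  w <- seq_len(nCore) / nCore
  si[nBorder + seq_len(nCore)] <- coreLo + w * (spec@lesionCoreSi - coreLo)
  si
}

# Largest lesion-free annular sector, returned as a ReferenceROI polygon.
autoRemoteRoi <- function(center, rInner, rOuter, truthMask, myoMask) {
  ang <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    atan2(idx[, 1] - center[1], idx[, 2] - center[2])
  }
  lesA <- sort(ang(truthMask & myoMask))
  # span capped so the ROI stays a modest, clinically sized region (~2 cm^2)
  if (length(lesA) == 0L) {
    a1 <- -pi / 2; a2 <- a1 + 0.6
  } else {
    gaps <- diff(c(lesA, lesA[1] + 2 * pi))
    g <- which.max(gaps)
    margin <- min(0.22, gaps[g] / 4)
    span <- min(gaps[g] - 2 * margin, 0.6)
    if (span <= 0.12) return(NULL)
    mid <- lesA[g] + gaps[g] / 2
    a1 <- mid - span / 2; a2 <- mid + span / 2
  }
  referenceROI(annularSectorPolygon(center, rInner + 1.5, rOuter - 1.5, a1, a2),
               kind = "remote_myocardium")
}

#' Generate a synthetic LGE study with known ground truth
#'
#' Deterministic for a fixed spec (including its seed).  Lesions are placed
#' as Gaussian-bump blobs inside the myocardial annulus and truncated to
#' their target size; each receives the graded border-zone/core intensity
#' profile described in \code{\link{phantomSpec}}.  Reference ROIs are
#' auto-derived per slice from the noise-free truth: the remote ROI is the
#' largest lesion-free annular sector, the core ROI a small disk around the
#' maximum-SI lesion pixel.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed optional integer overriding \code{spec@rngSeed}.
#' @param densityGPerMl density used for the stored ground-truth mass.
#' @param studyId identifier for the generated study.
#' @return A \linkS4class{PhantomStudy}.
#' @examples
#' ph <- generatePhantom(phantomSpec(rngSeed = 7L))
#' truthTotalMass(ph)
#' @export
generatePhantom <- function(spec, seed = NULL, densityGPerMl = 1.05,
                            studyId = "phantom") {
  validObject(spec)
  if (!is.null(seed)) spec@rngSeed <- as.integer(seed)
  withr::with_seed(spec@rngSeed, {
    n <- spec@imageSize
    center <- c((n + 1) / 2, (n + 1) / 2)
    taper <- 0.85 + 0.15 * sin(pi * (seq_len(spec@nSlices) - 0.5) / spec@nSlices)
    studyPositive <- spec@nLesions > 0 && stats::runif(1) < spec@probLgePositive
    slices <- vector("list", spec@nSlices)
    truth <- vector("list", spec@nSlices)
    for (i in seq_len(spec@nSlices)) {
      epiR <- spec@epiRadiusPx * taper[i]
      endoR <- spec@endoRadiusPx * taper[i]
      contours <- contourSet(endo = circlePolygon(center, endoR),
                             epi = circlePolygon(center, epiR))
      myo <- buildMyocardiumMask(contours, c(n, n))
      nMyo <- sum(myo)
      myoIdx <- which(myo)
      myoRC <- which(myo, arr.ind = TRUE)
      base <- matrix(20, n, n)                       # air/background
      endoMask <- rasterizePolygon(contours@endo, c(n, n))
      base[endoMask] <- 240                          # bright blood pool
      base[myo] <- spec@remoteMeanSi
      truthMask <- matrix(FALSE, n, n)
      nLes <- if (studyPositive) stats::rpois(1, spec@nLesions) else 0L
      if (nLes > 0L && spec@lesionAreaRangePx[1] > 0.6 * nMyo)
        stop("infeasible spec: minimum lesion area exceeds the annulus")
      for (l in seq_len(nLes)) {
        s <- round(stats::rlnorm(1, log(spec@lesionAreaMeanPx), spec@lesionAreaSdLog))
        s <- min(max(s, spec@lesionAreaRangePx[1]), spec@lesionAreaRangePx[2])
        free <- !truthMask[myoIdx]
        if (sum(free) < s + 5) next                  # annulus nearly full
        ctr <- myoRC[sample(which(free), 1L), ]
        sig <- sqrt(s / pi) / 1.2
        seeds <- cbind(ctr[1] + stats::rnorm(3, 0, sig), ctr[2] + stats::rnorm(3, 0, sig))
        f <- rowSums(exp(-(outer(myoRC[, 1], seeds[, 1], "-")^2 +
                           outer(myoRC[, 2], seeds[, 2], "-")^2) / (2 * sig^2)))
        f[!free] <- -Inf
        pick <- order(f, decreasing = TRUE)[seq_len(s)]
        pick <- pick[order(f[pick])]                 # ascending: rim first
        base[myoIdx[pick]] <- lesionIntensities(s, spec)
        truthMask[myoIdx[pick]] <- TRUE
      }
      # surface-coil shading: smooth multiplicative field across the slice
      if (spec@shadingAmp > 0) {
        xn <- (seq_len(n) - center[1]) / (n / 2)
        co <- stats::rnorm(4)
        g <- outer(xn, xn, function(x, y)
          co[1] * x + co[2] * y + co[3] * x * y + co[4] * (x^2 - y^2))
        g <- g / max(abs(g), 1e-9)
        base <- base * (1 + spec@shadingAmp * g)
      }
      img <- base
      if (spec@remoteSdSi > 0 && spec@noiseModel != "none") {
        if (spec@noiseModel == "rician") {
          img <- sqrt((base + stats::rnorm(n * n, 0, spec@remoteSdSi))^2 +
                      stats::rnorm(n * n, 0, spec@remoteSdSi)^2)
        } else {
          img <- pmax(0, base + stats::rnorm(n * n, 0, spec@remoteSdSi))
        }
        img <- matrix(img, n, n)
      }
      roiRemote <- autoRemoteRoi(center, endoR, epiR, truthMask, myo)
      roiCore <- NULL
      positive <- any(truthMask)
      if (positive) {
        peak <- which(base == max(base[truthMask]) & truthMask)[1L]
        pk <- c((peak - 1L) %% n + 1L, (peak - 1L) %/% n + 1L)
        roiCore <- referenceROI(circlePolygon(pk, 3.5, 24L),
                                kind = "enhancement_core")
      }
      slices[[i]] <- lgeSlice(
        sliceImage(img, spec@pixelSpacingMm, spec@sliceThicknessMm,
                   spec@sliceGapMm, i),
        contours, roiRemote = roiRemote, roiCore = roiCore,
        lgePositive = positive)
      truth[[i]] <- truthMask
    }
    study <- lgeStudy(studyId, slices)
    areas <- vapply(truth, function(m) sum(m) * prod(spec@pixelSpacingMm),
                    numeric(1))
    tt <- totalLGE(areas, spec@sliceThicknessMm, densityGPerMl = densityGPerMl)
    new("PhantomStudy", study = study, spec = spec, truthMasks = truth,
        truthTotalMassG = tt$totalMassG)
  })
}

#' Simulate an observer: perturb reference-region placement
#'
#' Endocardial/epicardial contours and images are left untouched (as in
#' reproducibility protocols that reuse fixed contours); only the remote and
#' core reference ROIs are re-placed.  The remote ROI is rotated along the
#' myocardial ring (observers choose different remote segments), translated
#' and rescaled; the core ROI is translated and rescaled around the bright
#' core.  A perturbed remote ROI must stay on lesion-free myocardium and a
#' perturbed core ROI must still contain lesion pixels; invalid draws are
#' resampled with geometrically shrinking perturbation up to
#' \code{maxRetries}, then an error is raised.
#'
#' @param phantom a \linkS4class{PhantomStudy}.
#' @param roiJitterPx maximal ROI translation per axis (px, uniform).
#' @param roiSizeScale range of the ROI scale factor (about the centroid).
#' @param roiRotationRad maximal rotation of the remote ROI about the
#'   ventricular center (radians, uniform).
#' @param seed integer seed (deterministic per seed).
#' @param maxRetries resampling attempts per ROI.
#' @return A new \linkS4class{PhantomStudy} with perturbed ROIs.
#' @export
simulateObserver <- function(phantom, roiJitterPx = 1.5,
                             roiSizeScale = c(0.85, 1.2),
                             roiRotationRad = 0.5, seed = 1L,
                             maxRetries = 40L) {
  study <- phantom@study
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(study@slices)) {
      sl <- study@slices[[i]]
      myo <- buildMyocardiumMask(sl@contours, dim(sl@image@pixels))
      truthMask <- phantom@truthMasks[[i]]
      vcenter <- colMeans(sl@contours@epi)
      jitterPoly <- function(poly, rotate, damp) {
        ctr <- colMeans(poly)
        sc <- 1 + damp * (stats::runif(1, roiSizeScale[1], roiSizeScale[2]) - 1)
        shift <- damp * stats::runif(2, -roiJitterPx, roiJitterPx)
        out <- sweep(sweep(poly, 2, ctr) * sc, 2, ctr + shift, "+")
        if (rotate && roiRotationRad > 0) {
          a <- damp * stats::runif(1, -roiRotationRad, roiRotationRad)
          rel <- sweep(out, 2, vcenter)
          out <- sweep(cbind(rel[, 1] * cos(a) + rel[, 2] * sin(a),
                             -rel[, 1] * sin(a) + rel[, 2] * cos(a)),
                       2, vcenter, "+")
        }
        out
      }
      perturb <- function(roi, rotate, valid) {
        if (is.null(roi)) return(NULL)
        for (try in seq_len(maxRetries)) {
          cand <- roi
          cand@polygon <- jitterPoly(roi@polygon, rotate, 0.85^(try - 1L))
          if (valid(cand)) return(cand)
        }
        stop("observer perturbation pushed an ROI off the myocardium")
      }
      sl@roiRemote <- perturb(sl@roiRemote, TRUE, function(cand) {
        m <- rasterizePolygon(cand@polygon, dim(myo)) & myo
        sum(m) >= 2 && !any(m & truthMask)
      })
      sl@roiCore <- perturb(sl@roiCore, FALSE, function(cand) {
        m <- rasterizePolygon(cand@polygon, dim(myo)) & myo
        any(m & truthMask)
      })
      study@slices[[i]] <- sl
    }
  })
  new("PhantomStudy", study = study, spec = phantom@spec,
      truthMasks = phantom@truthMasks,
      truthTotalMassG = phantom@truthTotalMassG)
}
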