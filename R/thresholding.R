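# The seven semi-automated threshold operators and the manual-sweep
# reference standard.  Each operator maps (slice, myocardium mask, reference
# information) to a scalar SI threshold plus a binary LGE mask.  Segmentation
# is uniformly "SI strictly greater than threshold" for every method.

thresholdResult <- function(method, threshold, lgeMask, referenceStats = list(),
                            flags = list()) {
  new("ThresholdResult", method = method, threshold = as.numeric(threshold),
      lgeMask = lgeMask, referenceStats = referenceStats, flags = flags)
}

# SI values of myocardial pixels inside an ROI polygon.
roiMyocardialValues <- function(image, myoMask, roi) {
  roiMask <- rasterizePolygon(roi@polygon, dim(image@pixels)) & myoMask
  image@pixels[roiMask]
}

populationSd <- function(x) sqrt(mean((x - mean(x))^2))

#' STRM threshold: k standard deviations above remote myocardium
#'
#' Signal Threshold versus Reference Mean.  The threshold is
#' \code{mean + k * sd} of the signal intensities of myocardial pixels inside
#' the remote-myocardium reference region; the LGE mask contains the
#' myocardial pixels with SI strictly greater than the threshold.
#'
#' The SD estimator defaults to the population form (denominator n); set
#' \code{sdEstimator = "sample"} for the n - 1 form.
#'
#' @param image a \linkS4class{SliceImage}.
#' @param myoMask logical myocardium mask (from
#'   \code{\link{buildMyocardiumMask}}).
#' @param remoteRoi a \linkS4class{ReferenceROI} of kind
#'   \code{"remote_myocardium"}.
#' @param k number of standard deviations; the standard operators use
#'   k in 2..6 (other positive values are accepted but flagged).
#' @param sdEstimator \code{"population"} or \code{"sample"}.
#' @return A \linkS4class{ThresholdResult} with method \code{STRM<k>}.
#' @examples
#' img <- sliceImage(matrix(c(90, 100, 110, 200), 2, 2), pixelSpacing = 1)
#' myo <- matrix(TRUE, 2, 2)
#' roi <- referenceROI(rbind(c(0.6, 0.6), c(0.6, 2.4), c(2.4, 2.4), c(2.4, 0.6)),
#'                     "remote_myocardium")
#' @export
strmThreshold <- function(image, myoMask, remoteRoi, k,
                          sdEstimator = c("population", "sample")) {
  sdEstimator <- match.arg(sdEstimator)
  if (is.null(remoteRoi) || remoteRoi@kind != "remote_myocardium")
    stop("STRM requires a reference ROI of kind 'remote_myocardium'")
  if (k <= 0) stop("k must be positive")
  vals <- roiMyocardialValues(image, myoMask, remoteRoi)
  if (length(vals) == 0L)
    stop("remote ROI is disjoint from the myocardium mask")
  if (length(vals) < 2L)
    stop("remote ROI must cover >= 2 myocardial pixels (SD undefined)")
  m <- mean(vals)
  s <- if (sdEstimator == "population") populationSd(vals) else stats::sd(vals)
  thr <- m + k * s
  flags <- list()
  if (!k %in% 2:6) flags$nonStandardK <- TRUE
  thresholdResult(sprintf("STRM%g", k), thr, myoMask & image@pixels > thr,
                  referenceStats = list(mean = m, sd = s, n = length(vals),
                                        k = k, sdEstimator = sdEstimator),
                  flags = flags)
}

#' FWHM threshold: half the maximum core signal intensity
#'
#' Full Width at Half Maximum.  The threshold is 50\% of the maximum SI of
#' myocardial pixels inside the enhancement-core reference region
#' (\code{fwhmMode = "half_max"}, the default).  The alternative
#' \code{"half_range"} places the threshold midway between the core maximum
#' and the core minimum.
#'
#' @inheritParams strmThreshold
#' @param coreRoi a \linkS4class{ReferenceROI} of kind
#'   \code{"enhancement_core"} containing the brightest visible enhancement.
#' @param fwhmMode \code{"half_max"} or \code{"half_range"}.
#' @return A \linkS4class{ThresholdResult} with method \code{FWHM}.
#' @export
fwhmThreshold <- function(image, myoMask, coreRoi,
                          fwhmMode = c("half_max", "half_range")) {
  fwhmMode <- match.arg(fwhmMode)
  if (is.null(coreRoi) || coreRoi@kind != "enhancement_core")
    stop("FWHM requires a reference ROI of kind 'enhancement_core'")
  vals <- roiMyocardialValues(image, myoMask, coreRoi)
  if (length(vals) == 0L)
    stop("core ROI is disjoint from the myocardium mask")
  mx <- max(vals)
  thr <- if (fwhmMode == "half_max") 0.5 * mx else min(vals) + 0.5 * (mx - min(vals))
  thresholdResult("FWHM", thr, myoMask & image@pixels > thr,
                  referenceStats = list(maxSi = mx, minSi = min(vals),
                                        n = length(vals), mode = fwhmMode))
}

# Between-class variance profile over a histogram: counts and mids define the
# histogram; entry i is the variance for the split {bins <= i} vs {bins > i}.
betweenClassVariance <- function(counts, mids) {
  m <- length(counts)
  N <- sum(counts)
  S <- sum(counts * mids)
  cumN <- cumsum(counts)[-m]
  cumS <- cumsum(counts * mids)[-m]
  w0 <- cumN / N
  sigB <- rep(-Inf, m - 1L)
  ok <- cumN > 0 & cumN < N
  mu0 <- cumS[ok] / cumN[ok]
  mu1 <- (S - cumS[ok]) / (N - cumN[ok])
  sigB[ok] <- w0[ok] * (1 - w0[ok]) * (mu0 - mu1)^2
  sigB
}

#' Otsu auto-threshold over the myocardial histogram
#'
#' Chooses the threshold maximizing the between-class variance of the
#' myocardial signal-intensity histogram.  Integer-valued images use exact
#' integer bins (one bin per gray level, provided the range does not exceed
#' 4096 levels); continuous images are discretized to \code{nBins}
#' equal-width bins over the observed myocardial range.  Ties are broken
#' toward the lowest maximizing threshold.
#'
#' @inheritParams strmThreshold
#' @param nBins number of histogram bins for continuous-valued images.
#' @return A \linkS4class{ThresholdResult} with method \code{OAT}.
#' @export
otsuThreshold <- function(image, myoMask, nBins = 1024L) {
  vals <- image@pixels[myoMask]
  if (length(vals) < 2L || diff(range(vals)) == 0)
    stop("Otsu undefined: myocardium must contain >= 2 distinct SI values")
  lo <- min(vals); hi <- max(vals)
  if (all(vals == round(vals)) && hi - lo <= 4096) {
    mids <- lo:hi
    counts <- tabulate(vals - lo + 1L, nbins = length(mids))
    candidates <- mids[-length(mids)]
    binType <- "integer"
  } else {
    breaks <- seq(lo, hi, length.out = nBins + 1L)
    bin <- findInterval(vals, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = nBins)
    mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
    candidates <- breaks[2:nBins]
    binType <- "continuous"
  }
  sigB <- betweenClassVariance(counts, mids)
  i <- which.max(sigB)  # first maximum = lowest threshold
  thr <- candidates[i]
  thresholdResult("OAT", thr, myoMask & image@pixels > thr,
                  referenceStats = list(nBins = length(counts), binType = binType,
                                        betweenClassVariance = sigB[i]))
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return 2|A intersect B| / (|A| + |B|); defined as 1 when both are empty.
#' @export
diceCoefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Manual threshold sweep: reproducible surrogate of expert adjustment
#'
#' Simulates the expert's slide-bar procedure: the SI threshold starts at
#' zero (100\% enhancement) and is swept upward over the myocardial SI range;
#' the returned threshold is the one whose induced mask has maximal Dice
#' overlap with the target mask (the visually identified LGE - here supplied
#' as ground truth or an expert mask).  Ties are broken toward the lower
#' threshold.  An empty target returns a threshold above the myocardial
#' maximum (zero LGE) with flag \code{emptyTarget}.
#'
#' @inheritParams strmThreshold
#' @param targetMask logical matrix, the target segmentation; must be a
#'   subset of \code{myoMask}.
#' @return A \linkS4class{ThresholdResult} with method \code{MANUAL};
#'   \code{referenceStats$dice} records the Dice achieved.
#' @export
manualThresholdSweep <- function(image, myoMask, targetMask) {
  if (any(targetMask & !myoMask))
    stop("targetMask must be a subset of the myocardium mask")
  vals <- image@pixels[myoMask]
  tgt <- targetMask[myoMask]
  nB <- sum(tgt)
  if (nB == 0L) {
    thr <- max(vals)
    return(thresholdResult("MANUAL", thr, myoMask & image@pixels > thr,
                           referenceStats = list(dice = NA_real_),
                           flags = list(emptyTarget = TRUE)))
  }
  o <- order(vals, decreasing = TRUE)
  cumInter <- cumsum(tgt[o])          # |mask(top j) intersect target|
  s <- sort(vals)
  r <- rle(s)
  uniqAsc <- r$values
  nGreater <- length(vals) - cumsum(r$lengths)   # |{v > u}| per unique value
  thresholds <- c(0, uniqAsc)
  js <- c(sum(vals > 0), nGreater)
  dice <- vapply(js, function(j)
    if (j == 0L) 0 else 2 * cumInter[j] / (j + nB), numeric(1))
  best <- which.max(dice)             # first = lowest threshold on ties
  thr <- thresholds[best]
  thresholdResult("MANUAL", thr, myoMask & image@pixels > thr,
                  referenceStats = list(dice = dice[best],
                                        nCandidates = length(thresholds)))
}

#' Label connected components of a binary mask
#'
#' Breadth-first labeling under 4- or 8-connectivity (in-plane only; the
#' pipeline never bridges across slices).
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  stack <- integer(sum(mask))
  nextLab <- 0L
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    nextLab <- nextLab + 1L
    lab[p] <- nextLab
    top <- 1L
    stack[1L] <- p
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      r0 <- (q - 1L) %% nr + 1L
      c0 <- (q - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        rr <- r0 + dr[k]; cc <- c0 + dc[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        qq <- (cc - 1L) * nr + rr
        if (mask[qq] && lab[qq] == 0L) {
          lab[qq] <- nextLab
          top <- top + 1L
          stack[top] <- qq
        }
      }
    }
  }
  lab
}

#' Optional post-processing of a raw LGE mask
#'
#' With the default \code{minComponentPx = 0} the mask is returned unchanged
#' (no post-filter is applied by default); otherwise connected components
#' smaller than \code{minComponentPx} pixels are removed.
#'
#' @param rawMask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @param minComponentPx minimum surviving component size in pixels.
#' @return Logical matrix.
#' @export
applyPostprocessing <- function(rawMask, connectivity = 8, minComponentPx = 0) {
  if (minComponentPx <= 0) return(rawMask)
  lab <- labelComponents(rawMask, connectivity)
  if (max(lab) == 0L) return(rawMask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- c(FALSE, sizes >= minComponentPx)[lab + 1L]
  out <- rawMask & matrix(keep, nrow(rawMask), ncol(rawMask))
  out
}

#' Segment one slice with a named method
#'
#' Dispatcher over the eight operators.  Method labels: \code{"STRM2"} ..
#' \code{"STRM6"}, \code{"FWHM"}, \code{"OAT"}, \code{"MANUAL"}
#' (case-insensitive).  Slices flagged LGE-negative return an empty mask with
#' threshold NA for every method, mirroring per-slice visual adjudication.
#'
#' @param slice an \linkS4class{LGESlice}.
#' @param method method label.
#' @param config option list from \code{\link{lgeConfig}}.
#' @param myoMask optional precomputed myocardium mask (recomputed from the
#'   contours when NULL).
#' @param targetMask target segmentation for \code{MANUAL} (e.g. phantom
#'   ground truth).
#' @return A \linkS4class{ThresholdResult}.
#' @export
segmentSlice <- function(slice, method, config = lgeConfig(), myoMask = NULL,
                         targetMask = NULL) {
  method <- toupper(method)
  if (is.null(myoMask))
    myoMask <- buildMyocardiumMask(slice@contours, dim(slice@image@pixels))
  if (!slice@lgePositive) {
    return(thresholdResult(method, NA_real_,
                           matrix(FALSE, nrow(slice@image@pixels), ncol(slice@image@pixels)),
                           flags = list(lgeNegative = TRUE)))
  }
  res <- if (grepl("^STRM[0-9.]+$", method)) {
    strmThreshold(slice@image, myoMask, slice@roiRemote,
                  k = as.numeric(sub("STRM", "", method)),
                  sdEstimator = config$sdEstimator)
  } else if (method == "FWHM") {
    fwhmThreshold(slice@image, myoMask, slice@roiCore, fwhmMode = config$fwhmMode)
  } else if (method == "OAT") {
    otsuThreshold(slice@image, myoMask, nBins = config$otsuBins)
  } else if (method == "MANUAL") {
    if (is.null(targetMask))
      stop("MANUAL segmentation requires a targetMask")
    manualThresholdSweep(slice@image, myoMask, targetMask)
  } else stop(sprintf("unknown method '%s'", method))
  if (config$minComponentPx > 0)
    res@lgeMask <- applyPostprocessing(res@lgeMask, config$connectivity,
                                       config$minComponentPx)
  res
}

#' Segment every slice of a study with one or more methods
#'
#' @param study an \linkS4class{LGEStudy}.
#' @param methods character vector of method labels (see
#'   \code{\link{segmentSlice}}).
#' @param targetMasks list of per-slice target masks, required when
#'   \code{"MANUAL"} is among the methods.
#' @param config option list from \code{\link{lgeConfig}}.
#' @param returnMasks keep the full \linkS4class{ThresholdResult} objects as
#'   attribute \code{"results"}?
#' @return data.frame with columns study_id, slice_index, method, threshold,
#'   n_pixels, lge_area_mm2.
#' @export
segmentStudy <- function(study, methods = lgeMethods(), targetMasks = NULL,
                         config = lgeConfig(), returnMasks = FALSE) {
  methods <- toupper(methods)
  if ("MANUAL" %in% methods && is.null(targetMasks))
    stop("MANUAL among methods: supply per-slice targetMasks")
  rows <- list()
  all_results <- if (returnMasks) list() else NULL
  for (i in seq_along(study@slices)) {
    sl <- study@slices[[i]]
    myo <- buildMyocardiumMask(sl@contours, dim(sl@image@pixels))
    px <- pixelArea(sl@image)
    for (m in methods) {
      res <- segmentSlice(sl, m, config, myoMask = myo,
                          targetMask = if (!is.null(targetMasks)) targetMasks[[i]])
      n <- sum(res@lgeMask)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = study@studyId,
        slice_index = sl@image@sliceIndex,
        method = res@method,
        threshold = res@threshold,
        n_pixels = n,
        lge_area_mm2 = n * px,
        stringsAsFactors = FALSE)
      if (returnMasks)
        all_results[[sprintf("s%d_%s", sl@image@sliceIndex, res@method)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (returnMasks) attr(out, "results") <- all_results
  out
}

#' Standard method labels
#'
#' The seven semi-automated operators in conventional order, optionally with
#' the manual reference standard appended.
#'
#' @param includeManual append \code{"MANUAL"}?
#' @return Character vector of method labels.
#' @export
lgeMethods <- function(includeManual = FALSE) {
  m <- c("STRM2", "STRM3", "STRM4", "STRM5", "STRM6", "FWHM", "OAT")
  if (includeManual) c(m, "MANUAL") else m
}
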