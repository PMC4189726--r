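#' @import methods
NULL

setClassUnion("ReferenceROIOrNULL", "NULL")

#' SliceImage: one short-axis gray-level slice with geometry
#'
#' Container for a single magnitude-reconstructed short-axis slice.  Pixel
#' values are arbitrary signal-intensity (SI) units and must be finite and
#' non-negative.  Geometry carries the in-plane pixel spacing (mm), the slice
#' thickness (mm) and the inter-slice gap (mm).
#'
#' The coordinate convention used throughout the package: contours live in
#' continuous image coordinates in which pixel \code{(r, c)} (1-based matrix
#' indices) has its center at \code{(r, c)} and covers the half-open cell
#' \code{[r - 0.5, r + 0.5) x [c - 0.5, c + 0.5)}.
#'
#' @slot pixels numeric matrix of signal intensities.
#' @slot pixelSpacing numeric length-2, (row mm, col mm), both > 0.
#' @slot sliceThicknessMm slice thickness in mm, > 0.
#' @slot sliceGapMm inter-slice gap in mm, >= 0.
#' @slot sliceIndex integer position in the apex-to-base stack.
#' @exportClass SliceImage
setClass("SliceImage",
  representation(
    pixels = "matrix",
    pixelSpacing = "numeric",
    sliceThicknessMm = "numeric",
    sliceGapMm = "numeric",
    sliceIndex = "integer"
  )
)

setValidity("SliceImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (!is.numeric(p)) msg <- c(msg, "pixels must be a numeric matrix")
  else {
    if (any(!is.finite(p))) msg <- c(msg, "pixels must be finite")
    if (any(p < 0)) msg <- c(msg, "pixels must be >= 0 (magnitude images)")
  }
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two strictly positive values")
  if (length(object@sliceThicknessMm) != 1L || object@sliceThicknessMm <= 0)
    msg <- c(msg, "sliceThicknessMm must be a single positive value")
  if (length(object@sliceGapMm) != 1L || object@sliceGapMm < 0)
    msg <- c(msg, "sliceGapMm must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceImage
#'
#' @param pixels numeric matrix of signal intensities (finite, >= 0).
#' @param pixelSpacing in-plane pixel spacing in mm, length-2 (row, col) or a
#'   single value used for both.
#' @param sliceThicknessMm slice thickness in mm.
#' @param sliceGapMm inter-slice gap in mm.
#' @param sliceIndex integer slice position (apex-to-base).
#' @return A \linkS4class{SliceImage}.
#' @examples
#' img <- sliceImage(matrix(100, 8, 8), pixelSpacing = 1.4)
#' pixelArea(img)
#' @export
sliceImage <- function(pixels, pixelSpacing = c(1, 1), sliceThicknessMm = 8,
                       sliceGapMm = 2, sliceIndex = 1L) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("SliceImage", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing),
      sliceThicknessMm = as.numeric(sliceThicknessMm),
      sliceGapMm = as.numeric(sliceGapMm), sliceIndex = as.integer(sliceIndex))
}

#' ContourSet: endo/epi boundary polygons plus exclusions
#'
#' Closed polygons in image coordinates (n x 2 matrices, columns row/col; the
#' closing edge from last to first vertex is implicit).  The endocardial
#' polygon must lie strictly inside the epicardial polygon.  Exclusion
#' polygons flag artifact or blood-pool regions that are removed from the
#' myocardial mask.
#'
#' @slot endo endocardial polygon, n x 2 matrix.
#' @slot epi epicardial polygon, n x 2 matrix.
#' @slot exclusions list of polygons to exclude.
#' @exportClass ContourSet
setClass("ContourSet",
  representation(endo = "matrix", epi = "matrix", exclusions = "list")
)

setValidity("ContourSet", function(object) {
  msg <- character()
  chk <- function(poly, what) {
    if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
      return(sprintf("%s polygon must be an n x 2 matrix with n >= 3", what))
    if (abs(polygonArea(poly)) <= .Machine$double.eps)
      return(sprintf("%s polygon has zero area", what))
    if (!polygonIsSimple(poly))
      return(sprintf("%s polygon is self-intersecting", what))
    NULL
  }
  msg <- c(msg, chk(object@endo, "endocardial"), chk(object@epi, "epicardial"))
  for (i in seq_along(object@exclusions))
    msg <- c(msg, chk(object@exclusions[[i]], sprintf("exclusion %d", i)))
  if (!length(msg)) {
    inside <- pointInPolygon(object@endo[, 1], object@endo[, 2], object@epi)
    if (!all(inside))
      msg <- c(msg, "endocardial polygon must lie inside the epicardial polygon")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContourSet
#'
#' @param endo endocardial polygon (n x 2 matrix, row/col image coordinates).
#' @param epi epicardial polygon.
#' @param exclusions optional list of artifact/blood-pool polygons.
#' @return A \linkS4class{ContourSet}.
#' @export
contourSet <- function(endo, epi, exclusions = list()) {
  new("ContourSet", endo = endo, epi = epi, exclusions = exclusions)
}

#' ReferenceROI: reference region for STRM or FWHM thresholds
#'
#' A polygonal region of interest.  \code{kind = "remote_myocardium"} marks
#' the remote (non-enhanced) reference used by STRM thresholds;
#' \code{kind = "enhancement_core"} marks the region containing the maximum
#' signal intensity of visible enhancement, used by FWHM.
#'
#' @slot polygon n x 2 matrix, row/col image coordinates.
#' @slot kind one of \code{"remote_myocardium"}, \code{"enhancement_core"}.
#' @exportClass ReferenceROI
setClass("ReferenceROI",
  representation(polygon = "matrix", kind = "character")
)

setValidity("ReferenceROI", function(object) {
  msg <- character()
  if (!is.matrix(object@polygon) || ncol(object@polygon) != 2L ||
      nrow(object@polygon) < 3L)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  if (!object@kind %in% c("remote_myocardium", "enhancement_core"))
    msg <- c(msg, "kind must be 'remote_myocardium' or 'enhancement_core'")
  if (length(msg)) msg else TRUE
})

setIs("ReferenceROI", "ReferenceROIOrNULL")

#' Construct a ReferenceROI
#'
#' @param polygon n x 2 matrix (row/col image coordinates).
#' @param kind \code{"remote_myocardium"} or \code{"enhancement_core"}.
#' @return A \linkS4class{ReferenceROI}.
#' @export
referenceROI <- function(polygon, kind = c("remote_myocardium", "enhancement_core")) {
  new("ReferenceROI", polygon = polygon, kind = match.arg(kind))
}

#' LGESlice: one analyzed slice with contours and reference regions
#'
#' Bundles a \linkS4class{SliceImage} with its \linkS4class{ContourSet},
#' optional reference ROIs, and the per-slice LGE-positivity flag.  Slices
#' flagged \code{lgePositive = FALSE} (no visually apparent enhancement)
#' contribute zero LGE under every segmentation method.
#'
#' @slot image a SliceImage.
#' @slot contours a ContourSet.
#' @slot roiRemote remote-myocardium ReferenceROI or NULL.
#' @slot roiCore enhancement-core ReferenceROI or NULL.
#' @slot lgePositive logical flag.
#' @exportClass LGESlice
setClass("LGESlice",
  representation(
    image = "SliceImage",
    contours = "ContourSet",
    roiRemote = "ReferenceROIOrNULL",
    roiCore = "ReferenceROIOrNULL",
    lgePositive = "logical"
  )
)

setValidity("LGESlice", function(object) {
  msg <- character()
  if (!is.null(object@roiRemote) && object@roiRemote@kind != "remote_myocardium")
    msg <- c(msg, "roiRemote must have kind 'remote_myocardium'")
  if (!is.null(object@roiCore) && object@roiCore@kind != "enhancement_core")
    msg <- c(msg, "roiCore must have kind 'enhancement_core'")
  if (length(object@lgePositive) != 1L || is.na(object@lgePositive))
    msg <- c(msg, "lgePositive must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct an LGESlice
#'
#' @param image a \linkS4class{SliceImage}.
#' @param contours a \linkS4class{ContourSet}.
#' @param roiRemote optional remote-myocardium \linkS4class{ReferenceROI}.
#' @param roiCore optional enhancement-core \linkS4class{ReferenceROI}.
#' @param lgePositive logical; does the slice show visually apparent LGE?
#' @return An \linkS4class{LGESlice}.
#' @export
lgeSlice <- function(image, contours, roiRemote = NULL, roiCore = NULL,
                     lgePositive = TRUE) {
  new("LGESlice", image = image, contours = contours, roiRemote = roiRemote,
      roiCore = roiCore, lgePositive = lgePositive)
}

#' LGEStudy: an ordered short-axis stack for one subject
#'
#' Slice geometry (pixel spacing, thickness, gap) must be uniform across the
#' study.
#'
#' @slot studyId character identifier.
#' @slot slices list of \linkS4class{LGESlice}, apex to base.
#' @exportClass LGEStudy
setClass("LGEStudy",
  representation(studyId = "character", slices = "list")
)

setValidity("LGEStudy", function(object) {
  msg <- character()
  if (length(object@studyId) != 1L) msg <- c(msg, "studyId must be a single string")
  if (!length(object@slices)) msg <- c(msg, "study must contain at least one slice")
  if (!all(vapply(object@slices, is, logical(1), "LGESlice")))
    msg <- c(msg, "slices must all be LGESlice objects")
  if (!length(msg)) {
    geo <- vapply(object@slices, function(s)
      c(s@image@pixelSpacing, s@image@sliceThicknessMm, s@image@sliceGapMm),
      numeric(4))
    if (any(apply(geo, 1, function(x) diff(range(x)) > 1e-9)))
      msg <- c(msg, "slice geometry (spacing, thickness, gap) must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LGEStudy
#'
#' @param studyId character identifier.
#' @param slices list of \linkS4class{LGESlice} objects, ordered apex to base.
#' @return An \linkS4class{LGEStudy}.
#' @export
lgeStudy <- function(studyId, slices) {
  new("LGEStudy", studyId = as.character(studyId), slices = slices)
}

#' ThresholdResult: output of one segmentation operator on one slice
#'
#' @slot method one of STRM2..STRM6, FWHM, OAT, MANUAL.
#' @slot threshold scalar SI threshold (NA for LGE-negative slices).
#' @slot lgeMask logical matrix, subset of the myocardium mask; pixels with
#'   SI strictly greater than \code{threshold}.
#' @slot referenceStats list: mean/sd/n of the remote ROI (STRM), max SI of
#'   the core ROI (FWHM), histogram summary (OAT), Dice achieved (MANUAL).
#' @slot flags list of condition flags (e.g. \code{emptyTarget},
#'   \code{lgeNegative}, \code{nonStandardK}).
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(
    method = "character",
    threshold = "numeric",
    lgeMask = "matrix",
    referenceStats = "list",
    flags = "list"
  )
)

#' AgreementReport: Bland-Altman and ICC summary for paired measurements
#'
#' Limits of agreement are reported in the "mean difference +/- halfwidth"
#' convention with halfwidth = 1.96 x SD (n - 1) of the paired differences.
#'
#' @slot method optional label of the method being compared.
#' @slot meanDifference mean of a - b.
#' @slot loaHalfwidth 1.96 x sample SD of the differences.
#' @slot icc two-way random-effects absolute-agreement single-measure ICC
#'   (may be NA when not requested).
#' @slot nPairs number of pairs.
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(
    method = "character",
    meanDifference = "numeric",
    loaHalfwidth = "numeric",
    icc = "numeric",
    nPairs = "integer"
  )
)

setValidity("AgreementReport", function(object) {
  msg <- character()
  if (object@nPairs < 2L) msg <- c(msg, "nPairs must be >= 2")
  if (!is.na(object@icc) && (object@icc < -1 || object@icc > 1))
    msg <- c(msg, "icc must lie in [-1, 1]")
  if (object@loaHalfwidth < 0) msg <- c(msg, "loaHalfwidth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LGEResult: per-study quantification summary
#'
#' @slot studyId study identifier.
#' @slot method segmentation method label.
#' @slot perSlice data.frame with columns slice_index, method, threshold,
#'   n_pixels, lge_area_mm2.
#' @slot totalVolumeMl total LGE volume (ml).
#' @slot totalMassG total LGE mass (g).
#' @slot lvMassG left-ventricular myocardial mass (g) from the same contours.
#' @slot lgePercentOfLv LGE mass as percent of LV mass.
#' @slot densityGPerMl myocardial density used (g/ml).
#' @exportClass LGEResult
setClass("LGEResult",
  representation(
    studyId = "character",
    method = "character",
    perSlice = "data.frame",
    totalVolumeMl = "numeric",
    totalMassG = "numeric",
    lvMassG = "numeric",
    lgePercentOfLv = "numeric",
    densityGPerMl = "numeric"
  )
)

#' PhantomSpec: parameters of the synthetic short-axis phantom
#'
#' See \code{\link{phantomSpec}} for the meaning and defaults of each field.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    imageSize = "integer",
    pixelSpacingMm = "numeric",
    nSlices = "integer",
    sliceThicknessMm = "numeric",
    sliceGapMm = "numeric",
    epiRadiusPx = "numeric",
    endoRadiusPx = "numeric",
    remoteMeanSi = "numeric",
    remoteSdSi = "numeric",
    lesionCoreSi = "numeric",
    borderZoneSi = "numeric",
    borderZoneFraction = "numeric",
    borderDecaySi = "numeric",
    nLesions = "numeric",
    lesionAreaMeanPx = "numeric",
    lesionAreaSdLog = "numeric",
    lesionAreaRangePx = "numeric",
    probLgePositive = "numeric",
    shadingAmp = "numeric",
    noiseModel = "character",
    rngSeed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
  if (!(object@lesionCoreSi > object@borderZoneSi &&
        object@borderZoneSi > object@remoteMeanSi))
    msg <- c(msg, "require lesionCoreSi > borderZoneSi > remoteMeanSi")
  if (object@borderZoneFraction < 0 || object@borderZoneFraction >= 1)
    msg <- c(msg, "borderZoneFraction must lie in [0, 1)")
  if (any(object@endoRadiusPx >= object@epiRadiusPx))
    msg <- c(msg, "endoRadiusPx must be smaller than epiRadiusPx")
  if (max(object@epiRadiusPx) > object@imageSize / 2 - 2)
    msg <- c(msg, "epiRadiusPx too large for imageSize")
  if (!object@noiseModel %in% c("rician", "gaussian", "none"))
    msg <- c(msg, "noiseModel must be 'rician', 'gaussian' or 'none'")
  if (object@remoteSdSi < 0) msg <- c(msg, "remoteSdSi must be >= 0")
  if (object@probLgePositive < 0 || object@probLgePositive > 1)
    msg <- c(msg, "probLgePositive must lie in [0, 1]")
  if (object@shadingAmp < 0 || object@shadingAmp >= 0.5)
    msg <- c(msg, "shadingAmp must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' PhantomStudy: synthetic study with known ground truth
#'
#' @slot study the generated \linkS4class{LGEStudy} (images, contours,
#'   auto-derived reference ROIs).
#' @slot spec the \linkS4class{PhantomSpec} used.
#' @slot truthMasks list of logical matrices, the true lesion mask per slice.
#' @slot truthTotalMassG true total LGE mass (g) of the ground-truth masks.
#' @exportClass PhantomStudy
setClass("PhantomStudy",
  representation(
    study = "LGEStudy",
    spec = "PhantomSpec",
    truthMasks = "list",
    truthTotalMassG = "numeric"
  )
)
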