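# Per-slice areas, study-level LGE volume/mass, LV mass and %LV.

#' Area of a binary mask in mm^2
#'
#' @param mask logical matrix.
#' @param pixelSpacing length-2 (row mm, col mm) or a single value.
#' @return Pixel count times pixel area.
#' @export
sliceArea <- function(mask, pixelSpacing) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  if (any(pixelSpacing <= 0)) stop("pixelSpacing must be positive")
  sum(mask) * pixelSpacing[1] * pixelSpacing[2]
}

# Effective slice extent in mm used by the volume integral.
sliceExtentMm <- function(thicknessMm, gapMm, includeGap) {
  if (includeGap) thicknessMm + gapMm else thicknessMm
}

#' Total LGE volume and mass from per-slice areas
#'
#' Per-study total: sum over slices of LGE area times slice thickness, then
#' converted to mass with the myocardial density.  The inter-slice gap is
#' excluded from the integral unless \code{includeGap}.
#'
#' @param areasMm2 numeric vector of per-slice LGE areas (mm^2);
#'   LGE-negative slices contribute 0.
#' @param sliceThicknessMm common slice thickness (mm).
#' @param densityGPerMl myocardial density (g/ml).
#' @param sliceGapMm inter-slice gap (mm), used only when \code{includeGap}.
#' @param includeGap include the gap in the volume integral?
#' @return list(totalVolumeMl, totalMassG).
#' @export
totalLGE <- function(areasMm2, sliceThicknessMm, densityGPerMl = 1.05,
                     sliceGapMm = 0, includeGap = FALSE) {
  ext <- sliceExtentMm(sliceThicknessMm, sliceGapMm, includeGap)
  vol <- sum(areasMm2) * ext / 1000    # mm^3 -> ml
  list(totalVolumeMl = vol, totalMassG = vol * densityGPerMl)
}

#' Left-ventricular myocardial mass from the LGE-series contours
#'
#' Sum over slices of myocardial area times slice thickness, times density.
#' (The denominator of %LV here derives from the same contours used for LGE
#' analysis, not from a separate cine series.)
#'
#' @param study an \linkS4class{LGEStudy} with contours on every slice.
#' @param densityGPerMl myocardial density (g/ml).
#' @param includeGap include the inter-slice gap in the integral?
#' @return LV mass in grams.
#' @export
lvMass <- function(study, densityGPerMl = 1.05, includeGap = FALSE) {
  if (!length(study@slices)) stop("empty study")
  areas <- vapply(study@slices, function(sl) {
    myo <- buildMyocardiumMask(sl@contours, dim(sl@image@pixels))
    sliceArea(myo, sl@image@pixelSpacing)
  }, numeric(1))
  img1 <- study@slices[[1L]]@image
  ext <- sliceExtentMm(img1@sliceThicknessMm, img1@sliceGapMm, includeGap)
  sum(areas) * ext / 1000 * densityGPerMl
}

#' Quantify a segmented study
#'
#' Aggregates the per-slice segmentation table of one method into total LGE
#' volume (ml), mass (g), LV mass (g) and LGE as percent of LV mass.
#'
#' @param study the \linkS4class{LGEStudy} that was segmented.
#' @param sliceTable data.frame from \code{\link{segmentStudy}}, filtered to
#'   a single method (or containing one method only).
#' @param config option list from \code{\link{lgeConfig}}.
#' @return An \linkS4class{LGEResult}.
#' @export
quantifyStudy <- function(study, sliceTable, config = lgeConfig()) {
  meth <- unique(sliceTable$method)
  if (length(meth) != 1L)
    stop("sliceTable must contain exactly one method; got: ",
         paste(meth, collapse = ", "))
  img1 <- study@slices[[1L]]@image
  tot <- totalLGE(sliceTable$lge_area_mm2, img1@sliceThicknessMm,
                  densityGPerMl = config$densityGPerMl,
                  sliceGapMm = img1@sliceGapMm, includeGap = config$includeGap)
  lv <- lvMass(study, densityGPerMl = config$densityGPerMl,
               includeGap = config$includeGap)
  new("LGEResult",
      studyId = study@studyId,
      method = meth,
      perSlice = sliceTable,
      totalVolumeMl = tot$totalVolumeMl,
      totalMassG = tot$totalMassG,
      lvMassG = lv,
      lgePercentOfLv = 100 * tot$totalMassG / lv,
      densityGPerMl = config$densityGPerMl)
}

#' Study-level totals for every method in a segmentation table
#'
#' @param study an \linkS4class{LGEStudy}.
#' @param sliceTable data.frame from \code{\link{segmentStudy}} (any number
#'   of methods).
#' @param config option list from \code{\link{lgeConfig}}.
#' @return data.frame with columns study_id, method, total_lge_ml,
#'   total_lge_g, lv_mass_g, lge_pct.
#' @export
studyTotals <- function(study, sliceTable, config = lgeConfig()) {
  do.call(rbind, lapply(split(sliceTable, sliceTable$method), function(tab) {
    res <- quantifyStudy(study, tab, config)
    data.frame(study_id = res@studyId, method = res@method,
               total_lge_ml = res@totalVolumeMl, total_lge_g = res@totalMassG,
               lv_mass_g = res@lvMassG, lge_pct = res@lgePercentOfLv,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
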