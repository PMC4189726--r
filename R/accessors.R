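# Accessor generics and show methods.

#' @describeIn sliceImage pixel matrix accessor
#' @param object,x an object of the documented class
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @export
setMethod("pixels", "SliceImage", function(object) object@pixels)

#' @describeIn sliceImage pixel spacing (row mm, col mm)
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @export
setMethod("pixelSpacing", "SliceImage", function(object) object@pixelSpacing)

#' In-plane area of one pixel in mm^2
#' @param object a \linkS4class{SliceImage}
#' @return single numeric, row spacing x col spacing.
#' @export
pixelArea <- function(object) prod(object@pixelSpacing)

#' @describeIn sliceImage slice thickness in mm
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))
#' @export
setMethod("sliceThickness", "SliceImage", function(object) object@sliceThicknessMm)

#' @describeIn sliceImage inter-slice gap in mm
#' @export
setGeneric("sliceGap", function(object) standardGeneric("sliceGap"))
#' @export
setMethod("sliceGap", "SliceImage", function(object) object@sliceGapMm)

#' @describeIn lgeStudy study identifier
#' @param object an \linkS4class{LGEStudy}
#' @export
setGeneric("studyId", function(object) standardGeneric("studyId"))
#' @export
setMethod("studyId", "LGEStudy", function(object) object@studyId)

#' @describeIn lgeStudy list of \linkS4class{LGESlice} objects
#' @export
setGeneric("studySlices", function(object) standardGeneric("studySlices"))
#' @export
setMethod("studySlices", "LGEStudy", function(object) object@slices)

#' @describeIn lgeStudy number of slices
#' @export
setMethod("length", "LGEStudy", function(x) length(x@slices))

#' @describeIn segmentSlice method label of a ThresholdResult
#' @param object a \linkS4class{ThresholdResult}
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))
#' @export
setMethod("methodName", "ThresholdResult", function(object) object@method)

#' @describeIn segmentSlice chosen SI threshold
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @export
setMethod("threshold", "ThresholdResult", function(object) object@threshold)

#' @describeIn segmentSlice binary LGE mask (logical matrix)
#' @export
setGeneric("lgeMask", function(object) standardGeneric("lgeMask"))
#' @export
setMethod("lgeMask", "ThresholdResult", function(object) object@lgeMask)

#' @describeIn segmentSlice reference-region statistics used by the operator
#' @export
setGeneric("referenceStats", function(object) standardGeneric("referenceStats"))
#' @export
setMethod("referenceStats", "ThresholdResult", function(object) object@referenceStats)

#' @describeIn blandAltman mean of the paired differences
#' @param object an \linkS4class{AgreementReport}
#' @export
setGeneric("meanDifference", function(object) standardGeneric("meanDifference"))
#' @export
setMethod("meanDifference", "AgreementReport", function(object) object@meanDifference)

#' @describeIn blandAltman 1.96 x SD of the paired differences
#' @export
setGeneric("loaHalfwidth", function(object) standardGeneric("loaHalfwidth"))
#' @export
setMethod("loaHalfwidth", "AgreementReport", function(object) object@loaHalfwidth)

#' @describeIn blandAltman the 95\% limits of agreement (lower, upper)
#' @export
setGeneric("loaInterval", function(object) standardGeneric("loaInterval"))
#' @export
setMethod("loaInterval", "AgreementReport", function(object)
  c(object@meanDifference - object@loaHalfwidth,
    object@meanDifference + object@loaHalfwidth))

#' @describeIn iccAbsoluteAgreement ICC value stored in a report
#' @param object an \linkS4class{AgreementReport}
#' @export
setGeneric("iccValue", function(object) standardGeneric("iccValue"))
#' @export
setMethod("iccValue", "AgreementReport", function(object) object@icc)

#' @describeIn generatePhantom the generated LGEStudy
#' @param object a \linkS4class{PhantomStudy}
#' @export
setGeneric("phantomStudy", function(object) standardGeneric("phantomStudy"))
#' @export
setMethod("phantomStudy", "PhantomStudy", function(object) object@study)

#' @describeIn generatePhantom per-slice ground-truth lesion masks
#' @export
setGeneric("truthMasks", function(object) standardGeneric("truthMasks"))
#' @export
setMethod("truthMasks", "PhantomStudy", function(object) object@truthMasks)

#' @describeIn generatePhantom true total LGE mass in grams
#' @export
setGeneric("truthTotalMass", function(object) standardGeneric("truthTotalMass"))
#' @export
setMethod("truthTotalMass", "PhantomStudy", function(object) object@truthTotalMassG)

setMethod("show", "SliceImage", function(object) {
  cat(sprintf("SliceImage %dx%d px, spacing %.3gx%.3g mm, thickness %g mm, gap %g mm, index %d\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThicknessMm, object@sliceGapMm, object@sliceIndex))
})

setMethod("show", "LGEStudy", function(object) {
  pos <- sum(vapply(object@slices, function(s) s@lgePositive, logical(1)))
  cat(sprintf("LGEStudy '%s': %d slices (%d LGE-positive)\n",
              object@studyId, length(object@slices), pos))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult [%s]: threshold = %s, %d LGE pixels\n",
              object@method,
              if (is.na(object@threshold)) "NA" else format(object@threshold, digits = 6),
              sum(object@lgeMask)))
})

setMethod("show", "AgreementReport", function(object) {
  lab <- if (length(object@method) && nzchar(object@method[1])) object@method[1] else "pair"
  cat(sprintf("AgreementReport [%s], n = %d: mean difference %.4g +/- %.4g (95%% LoA), ICC = %s\n",
              lab, object@nPairs, object@meanDifference, object@loaHalfwidth,
              if (is.na(object@icc)) "NA" else sprintf("%.3f", object@icc)))
})

setMethod("show", "LGEResult", function(object) {
  cat(sprintf("LGEResult '%s' [%s]: LGE %.2f ml / %.2f g; LV mass %.1f g; %.1f%% of LV\n",
              object@studyId, object@method, object@totalVolumeMl,
              object@totalMassG, object@lvMassG, object@lgePercentOfLv))
})

setMethod("show", "PhantomStudy", function(object) {
  cat(sprintf("PhantomStudy '%s': %d slices, true LGE mass %.3f g\n",
              object@study@studyId, length(object@study@slices),
              object@truthTotalMassG))
})
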