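# Run configuration: one flat option list whose defaults reproduce the
# documented behavior of every module.

#' Pipeline configuration
#'
#' Returns the option list consumed by the segmentation, quantification and
#' agreement functions.  Defaults reproduce the package's documented
#' conventions; every entry can be overridden by name.
#'
#' @param methods method labels to run (see \code{\link{lgeMethods}}).
#' @param densityGPerMl myocardial density converting volume to mass
#'   (g/ml); 1.05 is the standard value.
#' @param includeGap add the inter-slice gap to the slice thickness in the
#'   volume integral?  The default FALSE follows the per-slice
#'   area-times-thickness formula.
#' @param sdEstimator SD estimator for STRM: \code{"population"} (n) or
#'   \code{"sample"} (n - 1).
#' @param fwhmMode \code{"half_max"} (threshold = max/2) or
#'   \code{"half_range"} (midway between core max and min).
#' @param iccVariant ICC variant label; only \code{"ICC21"} (two-way random
#'   effects, absolute agreement, single measure) is implemented.
#' @param otsuBins histogram bins for Otsu on continuous images.
#' @param connectivity in-plane connectivity for post-processing (8 or 4).
#' @param minComponentPx minimum component size kept by post-processing;
#'   0 disables the filter (default: no post-filter).
#' @param includeNegatives include LGE-negative studies (totals of 0 for all
#'   methods) in patient-level agreement analyses?
#' @param seed integer seed recorded with the run.
#' @return Named list of options.
#' @export
lgeConfig <- function(methods = lgeMethods(),
                      densityGPerMl = 1.05,
                      includeGap = FALSE,
                      sdEstimator = "population",
                      fwhmMode = "half_max",
                      iccVariant = "ICC21",
                      otsuBins = 1024L,
                      connectivity = 8,
                      minComponentPx = 0,
                      includeNegatives = TRUE,
                      seed = 1L) {
  list(methods = toupper(methods),
       densityGPerMl = as.numeric(densityGPerMl),
       includeGap = isTRUE(includeGap),
       sdEstimator = match.arg(sdEstimator, c("population", "sample")),
       fwhmMode = match.arg(fwhmMode, c("half_max", "half_range")),
       iccVariant = as.character(iccVariant),
       otsuBins = as.integer(otsuBins),
       connectivity = as.numeric(connectivity),
       minComponentPx = as.numeric(minComponentPx),
       includeNegatives = isTRUE(includeNegatives),
       seed = as.integer(seed))
}

#' Write / read a configuration as JSON
#'
#' The file form round-trips losslessly through \code{readLgeConfig}.
#'
#' @param config list from \code{\link{lgeConfig}}.
#' @param path file path.
#' @return \code{readLgeConfig} returns the configuration list.
#' @export
writeLgeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLgeConfig
#' @export
readLgeConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(lgeConfig, raw)
}
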