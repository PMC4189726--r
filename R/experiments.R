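# End-to-end phantom experiments: accuracy of the semi-automated operators
# against the manual-sweep reference, and two-observer reproducibility.

#' Segment a phantom study (all methods, manual sweep against truth)
#'
#' @param phantom a \linkS4class{PhantomStudy}.
#' @param methods method labels; \code{"MANUAL"} uses the phantom's
#'   ground-truth masks as sweep target.
#' @param config option list from \code{\link{lgeConfig}}.
#' @return Per-slice segmentation data.frame (see \code{\link{segmentStudy}}).
#' @export
segmentPhantom <- function(phantom, methods = lgeMethods(includeManual = TRUE),
                           config = lgeConfig()) {
  segmentStudy(phantom@study, methods, targetMasks = phantom@truthMasks,
               config = config)
}

#' Accuracy experiment: semi-automated methods versus the manual standard
#'
#' Generates \code{nStudies} phantoms, runs every requested method plus the
#' manual threshold sweep (target = ground truth), quantifies per-study
#' total LGE mass, and compares each method to the manual reference with
#' Bland-Altman and ICC, both at the patient level (total mass, g) and at
#' the slice level (chosen SI thresholds on LGE-positive slices).
#'
#' @param nStudies number of phantom studies (>= 2).
#' @param spec a \linkS4class{PhantomSpec}; each study uses a child seed
#'   derived from \code{seed}.
#' @param methods semi-automated methods to compare.
#' @param seed master seed for the experiment.
#' @param config option list from \code{\link{lgeConfig}};
#'   \code{config$includeNegatives} controls whether LGE-negative studies
#'   enter the patient-level comparison.
#' @return list with elements \code{totals} (long data.frame: study_id,
#'   method, total_lge_g, ...), \code{reports} (per-method
#'   \linkS4class{AgreementReport} vs manual), \code{ranked} (table from
#'   \code{\link{rankMethods}}), \code{thresholds} (per-slice threshold
#'   table), \code{thresholdConcordance} (slice-level agreement table) and
#'   \code{truth} (per-study true mass).
#' @export
runAccuracyExperiment <- function(nStudies = 30L, spec = phantomSpec(),
                                  methods = lgeMethods(), seed = 1L,
                                  config = lgeConfig()) {
  if (nStudies < 2L) stop("need at least 2 studies")
  methods <- toupper(methods)
  allMethods <- unique(c(methods, "MANUAL"))
  totals <- list(); thrRows <- list(); truthMass <- numeric(nStudies)
  for (i in seq_len(nStudies)) {
    ph <- generatePhantom(spec, seed = childSeed(seed, i),
                          densityGPerMl = config$densityGPerMl,
                          studyId = sprintf("phantom%03d", i))
    seg <- segmentPhantom(ph, allMethods, config)
    totals[[i]] <- studyTotals(ph@study, seg, config)
    pos <- vapply(ph@study@slices, function(s) s@lgePositive, logical(1))
    thrRows[[i]] <- seg[seg$slice_index %in% which(pos),
                        c("study_id", "slice_index", "method", "threshold")]
    truthMass[i] <- ph@truthTotalMassG
  }
  totals <- do.call(rbind, totals)
  thresholds <- do.call(rbind, thrRows)
  wide <- stats::reshape(totals[, c("study_id", "method", "total_lge_g")],
                         idvar = "study_id", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^total_lge_g\\.", "", names(wide))
  if (!config$includeNegatives) {
    keep <- wide$MANUAL > 0
    wide <- wide[keep, , drop = FALSE]
  }
  reports <- lapply(methods, function(m)
    agreementReport(wide[[m]], wide$MANUAL, method = m))
  names(reports) <- methods
  thrConcordance <- NULL
  if (nrow(thresholds)) {
    thrWide <- stats::reshape(thresholds, idvar = c("study_id", "slice_index"),
                              timevar = "method", direction = "wide")
    names(thrWide) <- sub("^threshold\\.", "", names(thrWide))
    if (nrow(thrWide) >= 2) {
      thrReports <- lapply(methods, function(m)
        sliceThresholdConcordance(thrWide$MANUAL, thrWide[[m]], method = m))
      names(thrReports) <- methods
      thrConcordance <- rankMethods(thrReports)
    }
  }
  list(totals = totals,
       reports = reports,
       ranked = rankMethods(reports),
       thresholds = thresholds,
       thresholdConcordance = thrConcordance,
       truth = data.frame(study_id = sprintf("phantom%03d", seq_len(nStudies)),
                          truth_mass_g = truthMass),
       nStudies = nStudies, seed = seed)
}

#' Reproducibility experiment: two simulated observers
#'
#' Generates phantoms, derives two observers per study by perturbing the
#' reference-region placement (contours fixed, images fixed), segments each
#' observer's study, and reports per-method inter-observer Bland-Altman
#' limits of agreement and ICC on total LGE mass.
#'
#' @inheritParams runAccuracyExperiment
#' @param roiJitterPx,roiSizeScale,roiRotationRad observer perturbation, see
#'   \code{\link{simulateObserver}}.
#' @return list with \code{reports} (per-method inter-observer
#'   \linkS4class{AgreementReport}), \code{table} (tidy summary sorted by
#'   limits-of-agreement halfwidth) and \code{totals} (long data.frame with
#'   observer column).
#' @export
runReproducibilityExperiment <- function(nStudies = 30L, spec = phantomSpec(),
                                         methods = lgeMethods(), seed = 1L,
                                         roiJitterPx = 1.5,
                                         roiSizeScale = c(0.85, 1.2),
                                         roiRotationRad = 0.5,
                                         config = lgeConfig()) {
  if (nStudies < 2L) stop("need at least 2 studies")
  methods <- toupper(methods)
  rows <- list()
  for (i in seq_len(nStudies)) {
    ph <- generatePhantom(spec, seed = childSeed(seed, i),
                          densityGPerMl = config$densityGPerMl,
                          studyId = sprintf("phantom%03d", i))
    for (obs in 1:2) {
      phObs <- simulateObserver(ph, roiJitterPx = roiJitterPx,
                                roiSizeScale = roiSizeScale,
                                roiRotationRad = roiRotationRad,
                                seed = childSeed(seed, i, obs))
      seg <- segmentPhantom(phObs, methods, config)
      tt <- studyTotals(phObs@study, seg, config)
      tt$observer <- obs
      rows[[length(rows) + 1L]] <- tt
    }
  }
  totals <- do.call(rbind, rows)
  reports <- lapply(methods, function(m) {
    t1 <- totals[totals$method == m & totals$observer == 1L, ]
    t2 <- totals[totals$method == m & totals$observer == 2L, ]
    stopifnot(identical(t1$study_id, t2$study_id))
    agreementReport(t1$total_lge_g, t2$total_lge_g, method = m)
  })
  names(reports) <- methods
  tab <- rankMethods(reports)
  tab <- tab[order(tab$loa_halfwidth), , drop = FALSE]
  rownames(tab) <- NULL
  list(reports = reports, table = tab, totals = totals,
       nStudies = nStudies, seed = seed)
}
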