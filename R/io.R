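# Readers/writers: NIfTI slice stacks, contour/ROI JSON, study round trip.
#
# Contour JSON schema (coordinates in pixels, row/col):
# {"pixel_spacing_mm": [r, c], "slice_thickness_mm": t, "slice_gap_mm": g,
#  "slices": [{"index": i, "endo": [[r,c],...], "epi": [[r,c],...],
#              "exclusions": [...], "roi_remote": [[r,c],...] | null,
#              "roi_core": [[r,c],...] | null, "lge_positive": true}]}

polyToList <- function(poly) {
  if (is.null(poly)) return(NULL)
  lapply(seq_len(nrow(poly)), function(i) as.numeric(poly[i, ]))
}

polyFromList <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  if (is.matrix(x)) return(unname(x))
  do.call(rbind, lapply(x, as.numeric))
}

#' Write a study (or phantom) to disk
#'
#' Writes \code{images.nii.gz} (slice axis third), \code{contours.json}
#' (contours, ROIs, per-slice positivity, geometry sidecar fields) and, for
#' phantoms, \code{truth.nii.gz} plus \code{truth.csv} with per-slice truth
#' areas and the true total mass.
#'
#' @param x an \linkS4class{LGEStudy} or \linkS4class{PhantomStudy}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeStudy <- function(x, dir) {
  phantom <- is(x, "PhantomStudy")
  study <- if (phantom) x@study else x
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img1 <- study@slices[[1L]]@image
  vol <- simplify2array(lapply(study@slices, function(s) s@image@pixels))
  nii <- RNifti::asNifti(vol)
  RNifti::pixdim(nii) <- c(img1@pixelSpacing,
                           img1@sliceThicknessMm + img1@sliceGapMm)
  RNifti::writeNifti(nii, file.path(dir, "images.nii.gz"))
  slices <- lapply(study@slices, function(s) {
    list(index = s@image@sliceIndex,
         endo = polyToList(s@contours@endo),
         epi = polyToList(s@contours@epi),
         exclusions = lapply(s@contours@exclusions, polyToList),
         roi_remote = if (!is.null(s@roiRemote)) polyToList(s@roiRemote@polygon),
         roi_core = if (!is.null(s@roiCore)) polyToList(s@roiCore@polygon),
         lge_positive = s@lgePositive)
  })
  jsonlite::write_json(
    list(study_id = study@studyId,
         pixel_spacing_mm = img1@pixelSpacing,
         slice_thickness_mm = img1@sliceThicknessMm,
         slice_gap_mm = img1@sliceGapMm,
         slices = slices),
    file.path(dir, "contours.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (phantom) {
    tvol <- simplify2array(lapply(x@truthMasks, function(m) m * 1L))
    tn <- RNifti::asNifti(tvol)
    RNifti::pixdim(tn) <- RNifti::pixdim(nii)
    RNifti::writeNifti(tn, file.path(dir, "truth.nii.gz"))
    areas <- vapply(x@truthMasks, function(m) sum(m) * pixelArea(img1), numeric(1))
    utils::write.csv(
      data.frame(slice_index = seq_along(areas), truth_area_mm2 = areas,
                 truth_total_mass_g = x@truthTotalMassG),
      file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Load a study from a NIfTI volume plus contour JSON
#'
#' Pixel spacing and slice distance from the NIfTI header are reconciled
#' against the JSON sidecar fields; a mismatch beyond 0.001 mm is an error.
#' Every image slice must have a contour entry and every contour entry must
#' reference an existing slice.
#'
#' @param imagesPath path to the NIfTI volume.
#' @param contoursPath path to the contour JSON.
#' @return An \linkS4class{LGEStudy}.
#' @export
loadStudy <- function(imagesPath, contoursPath) {
  if (!file.exists(imagesPath)) stop("images file not found: ", imagesPath)
  if (!file.exists(contoursPath)) stop("contours file not found: ", contoursPath)
  nii <- RNifti::readNifti(imagesPath)
  vol <- as.array(nii)
  if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
  if (any(!is.finite(vol))) stop("non-finite pixel values in ", imagesPath)
  meta <- jsonlite::read_json(contoursPath, simplifyVector = FALSE)
  spacing <- as.numeric(unlist(meta$pixel_spacing_mm))
  thick <- as.numeric(meta$slice_thickness_mm)
  gap <- as.numeric(meta$slice_gap_mm)
  pd <- RNifti::pixdim(nii)
  if (any(abs(pd[1:2] - spacing) > 1e-3))
    stop(sprintf("pixel spacing mismatch: header %.4g x %.4g vs sidecar %.4g x %.4g",
                 pd[1], pd[2], spacing[1], spacing[2]))
  if (length(pd) >= 3L && abs(pd[3] - (thick + gap)) > 1e-3)
    stop(sprintf("slice distance mismatch: header %.4g vs thickness+gap %.4g",
                 pd[3], thick + gap))
  nSlices <- dim(vol)[3]
  entries <- meta$slices
  idx <- vapply(entries, function(e) as.integer(e$index), integer(1))
  bad <- setdiff(idx, seq_len(nSlices))
  if (length(bad))
    stop(sprintf("contour JSON references absent slice %d of a %d-slice volume",
                 bad[1], nSlices))
  missing <- setdiff(seq_len(nSlices), idx)
  if (length(missing))
    stop(sprintf("missing contour for slice %d", missing[1]))
  slices <- lapply(seq_len(nSlices), function(i) {
    e <- entries[[match(i, idx)]]
    contours <- contourSet(endo = polyFromList(e$endo),
                           epi = polyFromList(e$epi),
                           exclusions = lapply(e$exclusions, polyFromList))
    rem <- polyFromList(e$roi_remote)
    core <- polyFromList(e$roi_core)
    lgeSlice(sliceImage(vol[, , i], spacing, thick, gap, i), contours,
             roiRemote = if (!is.null(rem)) referenceROI(rem, "remote_myocardium"),
             roiCore = if (!is.null(core)) referenceROI(core, "enhancement_core"),
             lgePositive = isTRUE(e$lge_positive))
  })
  sid <- if (!is.null(meta$study_id)) as.character(meta$study_id) else "study"
  lgeStudy(sid, slices)
}

#' Load per-slice truth masks from a NIfTI volume
#'
#' @param truthPath path to a 0/1 volume (slice axis third).
#' @return List of logical matrices.
#' @export
loadTruthMasks <- function(truthPath) {
  vol <- as.array(RNifti::readNifti(truthPath))
  if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
  lapply(seq_len(dim(vol)[3]), function(i) vol[, , i] > 0.5)
}

#' Run the per-study segmentation/quantification pipeline
#'
#' Loads a study, segments it with the configured methods (plus the manual
#' sweep when ground-truth/expert masks are supplied), quantifies totals and
#' writes \code{perslice.csv}, \code{totals.csv}, \code{config.json} and a
#' short run log to \code{outDir}.  A rerun with identical inputs and
#' configuration produces identical outputs.
#'
#' @param imagesPath NIfTI volume path.
#' @param contoursPath contour JSON path.
#' @param outDir output directory.
#' @param config option list from \code{\link{lgeConfig}}.
#' @param truthPath optional NIfTI of target masks enabling \code{MANUAL}.
#' @return Invisibly, list(perSlice, totals).
#' @export
runPipeline <- function(imagesPath, contoursPath, outDir,
                        config = lgeConfig(), truthPath = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  study <- stage("load", loadStudy(imagesPath, contoursPath))
  targets <- if (!is.null(truthPath)) stage("load", loadTruthMasks(truthPath))
  methods <- config$methods
  if (!is.null(targets)) methods <- unique(c(methods, "MANUAL"))
  seg <- stage("segment",
               segmentStudy(study, methods, targetMasks = targets, config = config))
  totals <- stage("quantify", studyTotals(study, seg, config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(seg, file.path(outDir, "perslice.csv"), row.names = FALSE)
  utils::write.csv(totals, file.path(outDir, "totals.csv"), row.names = FALSE)
  writeLgeConfig(config, file.path(outDir, "config.json"))
  writeLines(c(sprintf("lgequant pipeline run: %s", study@studyId),
               sprintf("methods: %s", paste(methods, collapse = ", ")),
               sprintf("seed: %d", config$seed),
               sprintf("slices: %d", length(study@slices))),
             file.path(outDir, "run.log"))
  invisible(list(perSlice = seg, totals = totals))
}
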