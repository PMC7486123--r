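#' Section template for the basolateral amygdala
#'
#' Polygonal outline of the BLA for one coronal section, split into the
#' lateral (LA) and basal (BA) nuclei, together with the six canonical
#' landmarks used for rigid registration. All coordinates are in micrometres,
#' in a frame whose origin is the dorsal-most point of the outline with y
#' increasing ventrally.
#'
#' @slot section one of \code{"anterior"}, \code{"intermediate"},
#'   \code{"posterior"}.
#' @slot outline closed polygon (n x 2 matrix, um) bounding the whole BLA.
#' @slot la,ba polygons for the lateral and basal nuclei; their interiors are
#'   disjoint and both lie inside \code{outline}.
#' @slot border polyline (k x 2 matrix) shared between LA and BA.
#' @slot subregions optional named list of further polygons.
#' @slot landmarks 6 x 2 matrix of ordered registration landmarks (um).
#' @slot origin length-2 numeric, the dorsal-most point of the outline.
#'
#' @seealso [blaTemplate()] to load the shipped templates,
#'   [assignRegion()] for point-in-polygon region calls.
#' @export
setClass("RegionTemplate", representation(
  section = "character",
  outline = "matrix",
  la = "matrix",
  ba = "matrix",
  border = "matrix",
  subregions = "list",
  landmarks = "matrix",
  origin = "numeric"
))

setValidity("RegionTemplate", function(object) {
  msg <- character()
  if (!object@section %in% c("anterior", "intermediate", "posterior"))
    msg <- c(msg, "section must be anterior/intermediate/posterior")
  if (nrow(object@landmarks) != 6L || ncol(object@landmarks) != 2L)
    msg <- c(msg, "landmarks must be a 6 x 2 matrix")
  for (p in list(object@outline, object@la, object@ba))
    if (nrow(p) < 3L || polygonArea(p) <= 0)
      msg <- c(msg, "polygons must have >= 3 vertices and positive area")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be a length-2 point")
  if (length(msg)) msg else TRUE
})

#' Rigid (rotation + translation) planar transform
#'
#' The transform returned by [fitProcrustes()]: a proper rotation (no
#' reflection, no scaling) followed by a translation, mapping source-frame
#' coordinates into the template frame.
#'
#' @slot rotation 2 x 2 orthogonal matrix with determinant +1.
#' @slot translation length-2 numeric (um).
#' @slot rmsd root-mean-square landmark residual of the fit (um); \code{NA}
#'   for hand-built transforms.
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric",
  rmsd = "numeric"
))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(2L, 2L))) msg <- c(msg, "rotation must be 2 x 2")
  else {
    if (max(abs(crossprod(R) - diag(2))) > 1e-8)
      msg <- c(msg, "rotation must be orthogonal")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must have det +1 (reflections not allowed)")
  }
  if (length(object@translation) != 2L)
    msg <- c(msg, "translation must have length 2")
  if (length(msg)) msg else TRUE
})

#' Distance-binned correlation profile
#'
#' Mean cell-to-cell Pearson correlation of the mFISH expression panel as a
#' function of distance from a seed cell, split by whether the partner cell
#' shares the seed's discrete phenotype. Bins are half-open
#' \code{[0,w), [w,2w), ...} of width \code{binWidth} micrometres. Aggregated
#' profiles additionally carry the across-seed standard deviation.
#'
#' @slot seedId id of the seed cell, or \code{"<aggregate>"}.
#' @slot binWidth bin width in um.
#' @slot stats data.frame with columns \code{bin} (left edge, um),
#'   \code{class} (\code{"same"}/\code{"opposite"}), \code{mean_r},
#'   \code{sd_r}, \code{n}.
#' @slot aggregated logical scalar.
#' @export
setClass("CorrelationProfile", representation(
  seedId = "character",
  binWidth = "numeric",
  stats = "data.frame",
  aggregated = "logical"
))

setValidity("CorrelationProfile", function(object) {
  st <- object@stats
  need <- c("bin", "class", "mean_r", "sd_r", "n")
  if (!all(need %in% names(st)))
    return(paste("stats must have columns", paste(need, collapse = ", ")))
  r <- st$mean_r[is.finite(st$mean_r)]
  if (length(r) && (min(r) < -1 - 1e-12 || max(r) > 1 + 1e-12))
    return("mean_r must lie in [-1, 1]")
  if (object@binWidth <= 0) return("binWidth must be positive")
  TRUE
})

#' Monte-Carlo null distribution of a statistic
#'
#' Draws of a statistic under repeated random selection from a reference pool,
#' with percentile 95% confidence interval and the add-one empirical p-value
#' \eqn{p = (1 + \#\{draws\ at\ least\ as\ extreme\}) / (1 + n_{iter})}.
#'
#' @slot statistic name of the statistic.
#' @slot draws numeric vector of null draws (length \code{nIter}).
#' @slot observed the observed value of the statistic.
#' @slot ci length-2 numeric, the 2.5th and 97.5th percentiles of the draws.
#' @slot pValue empirical p (never exactly 0 by construction).
#' @slot alternative \code{"two.sided"} or \code{"less"}.
#' @slot enriched logical: observed outside the percentile interval
#'   (\code{NA} when not applicable).
#' @slot seed integer seed used for the draws.
#' @export
setClass("NullDistribution", representation(
  statistic = "character",
  draws = "numeric",
  observed = "numeric",
  ci = "numeric",
  pValue = "numeric",
  alternative = "character",
  enriched = "logical",
  seed = "integer"
))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
    msg <- c(msg, "ci must be an ordered length-2 interval")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "empirical p must lie in (0, 1]")
  m <- mean(object@draws)
  if (m < object@ci[1] - 1e-9 || m > object@ci[2] + 1e-9)
    msg <- c(msg, "mean of draws must lie inside the 95% interval")
  if (length(msg)) msg else TRUE
})

#' In-memory image stack
#'
#' A simple voxel container for the image stage: intensities on an
#' (x, y, z) grid with physical pixel size and z-step. 2-D images use
#' \code{nz = 1}.
#'
#' @slot data numeric array, dims (nx, ny, nz).
#' @slot pixelSize lateral pixel size, um/px (> 0).
#' @slot zStep z spacing, um.
#' @export
setClass("ImageStack", representation(
  data = "array", pixelSize = "numeric", zStep = "numeric"
))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (!all(is.finite(object@data))) msg <- c(msg, "intensities must be finite")
  if (!(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmented regions of interest
#'
#' Output of the segmentation operations: a label image (0 = background) plus
#' a per-ROI summary table. Areas are mask pixel counts times the squared
#' pixel size.
#'
#' @slot labels integer matrix of ROI labels, dims (nx, ny).
#' @slot table data.frame with \code{roi}, \code{x_um}, \code{y_um}
#'   (centroid), \code{area_um2}.
#' @slot pixelSize um/px.
#' @export
setClass("ROISet", representation(
  labels = "matrix", table = "data.frame", pixelSize = "numeric"
))

setValidity("ROISet", function(object) {
  lab <- sort(unique(as.integer(object@labels)))
  lab <- lab[lab > 0]
  if (!setequal(lab, object@table$roi))
    return("label image and ROI table disagree")
  if (nrow(object@table) &&
      any(abs(object@table$area_um2 -
              tabulate(object@labels[object@labels > 0])[object@table$roi] *
              object@pixelSize^2) > 1e-6))
    return("areas must equal mask pixel count x pixelSize^2")
  TRUE
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack ", d[1], " x ", d[2], " x ", d[3], " px, ",
      object@pixelSize, " um/px, z-step ", object@zStep, " um\n", sep = "")
})

setMethod("show", "ROISet", function(object) {
  cat("ROISet: ", nrow(object@table), " ROIs",
      if (nrow(object@table)) paste0(", areas ",
        round(min(object@table$area_um2), 1), "-",
        round(max(object@table$area_um2), 1), " um^2"), "\n", sep = "")
})

#' @describeIn ROISet-class per-ROI summary table accessor
#' @param rois a \code{ROISet}
#' @export
roiTable <- function(rois) rois@table

setMethod("show", "RegionTemplate", function(object) {
  cat("RegionTemplate (", object@section, " BLA section)\n", sep = "")
  cat("  outline: ", nrow(object@outline), " vertices, area ",
      round(polygonArea(object@outline) / 1e6, 3), " mm^2\n", sep = "")
  cat("  LA area fraction: ",
      round(polygonArea(object@la) / polygonArea(object@outline), 3), "\n", sep = "")
  cat("  landmarks: 6; origin: (", paste(round(object@origin, 1), collapse = ", "),
      ") um\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- atan2(object@rotation[2, 1], object@rotation[1, 1]) * 180 / pi
  cat("RigidTransform: rotation ", round(ang, 3), " deg, translation (",
      paste(round(object@translation, 2), collapse = ", "), ") um",
      if (is.finite(object@rmsd)) paste0(", rmsd ", signif(object@rmsd, 4), " um"),
      "\n", sep = "")
})

setMethod("show", "CorrelationProfile", function(object) {
  cat("CorrelationProfile (", if (object@aggregated) "aggregate" else object@seedId,
      "): ", length(unique(object@stats$bin)), " bins of ", object@binWidth,
      " um\n", sep = "")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution of ", object@statistic, " (", length(object@draws),
      " draws)\n", sep = "")
  cat("  observed ", signif(object@observed, 5), "; null mean ",
      signif(mean(object@draws), 5), ", 95% CI [",
      signif(object@ci[1], 5), ", ", signif(object@ci[2], 5), "]\n", sep = "")
  cat("  empirical p = ", signif(object@pValue, 4),
      if (isTRUE(object@enriched)) "  (outside null interval)", "\n", sep = "")
})

## ---- accessors -----------------------------------------------------------

#' @describeIn RigidTransform-class rotation matrix accessor
#' @param object a \code{RigidTransform}
#' @export
rotationMatrix <- function(object) object@rotation

#' @describeIn RigidTransform-class translation accessor
#' @export
translationVector <- function(object) object@translation

#' @describeIn RegionTemplate-class landmark accessor
#' @param template a \code{RegionTemplate}
#' @export
templateLandmarks <- function(template) template@landmarks

#' @describeIn RegionTemplate-class outline polygon accessor
#' @export
templateOutline <- function(template) template@outline

#' @describeIn NullDistribution-class null draw accessor
#' @param nd a \code{NullDistribution}
#' @export
nullDraws <- function(nd) nd@draws

#' @describeIn NullDistribution-class percentile confidence interval accessor
#' @export
nullCI <- function(nd) nd@ci

#' @describeIn NullDistribution-class empirical p-value accessor
#' @export
nullPValue <- function(nd) nd@pValue

#' @describeIn CorrelationProfile-class per-bin statistics accessor
#' @param profile a \code{CorrelationProfile}
#' @export
profileStats <- function(profile) profile@stats
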