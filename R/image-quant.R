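#' @importFrom EBImage gblur watershed distmap bwlabel makeBrush
NULL

# coerce 2-D input: ImageStack -> max z-projection; matrix used as-is
.as2d <- function(img, pixelSize = NULL) {
  if (is(img, "ImageStack")) {
    list(im = apply(img@data, c(1, 2), max), pixelSize = img@pixelSize)
  } else {
    if (is.null(pixelSize)) stop("pixelSize required for plain matrix input")
    list(im = as.matrix(img), pixelSize = pixelSize)
  }
}

.roiSetFromLabels <- function(lab, pixelSize) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    return(new("ROISet", labels = lab,
               table = data.frame(roi = integer(0), x_um = numeric(0),
                                  y_um = numeric(0), area_um2 = numeric(0)),
               pixelSize = pixelSize))
  }
  px <- tabulate(lab, nbins = max(ids))
  rowIdx <- row(lab); colIdx <- col(lab)
  xs <- vapply(ids, function(i) mean(rowIdx[lab == i]), numeric(1))
  ys <- vapply(ids, function(i) mean(colIdx[lab == i]), numeric(1))
  new("ROISet", labels = lab,
      table = data.frame(roi = ids,
                         x_um = (xs - 0.5) * pixelSize,
                         y_um = (ys - 0.5) * pixelSize,
                         area_um2 = px[ids] * pixelSize^2),
      pixelSize = pixelSize)
}

.filterRelabel <- function(lab, pixelSize, areaMin, areaMax) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    px <- tabulate(lab, nbins = max(ids))
    area <- px[ids] * pixelSize^2
    drop <- ids[area < areaMin | area > areaMax]   # bounds inclusive
    lab[lab %in% drop] <- 0L
    keep <- setdiff(ids, drop)
    lab[] <- match(lab, keep, nomatch = 0L)        # contiguous relabel
  }
  lab
}

.checkThreshold <- function(im, threshold) {
  if (threshold >= max(im) || threshold < min(im)) {
    warning("threshold ", threshold, " outside image intensity range [",
            signif(min(im), 4), ", ", signif(max(im), 4),
            "]; returning empty ROI set")
    return(FALSE)
  }
  TRUE
}

#' Segment chromogenic ISH cells (blur, threshold, watershed, area filter)
#'
#' Gaussian blur, binarize at a fixed intensity threshold, split touching
#' cells with a distance-transform watershed, then keep components whose area
#' lies within the pass band (inclusive at both bounds).
#'
#' @param img 2-D image: an [ImageStack-class] (max z-projection is used) or
#'   a numeric matrix plus \code{pixelSize}.
#' @param sigmaPx Gaussian blur SD in pixels.
#' @param threshold binarization intensity threshold.
#' @param areaMin,areaMax pass band in um^2 (default 100-400).
#' @param pixelSize um/px for plain-matrix input.
#' @return a [ROISet-class].
#' @export
segmentChromogenic <- function(img, sigmaPx = 2, threshold, areaMin = 100,
                               areaMax = 400, pixelSize = NULL) {
  x <- .as2d(img, pixelSize)
  im <- if (sigmaPx > 0) gblur(x$im, sigma = sigmaPx) else x$im
  if (!.checkThreshold(im, threshold))
    return(.roiSetFromLabels(matrix(0L, nrow(im), ncol(im)), x$pixelSize))
  bin <- im > threshold
  lab <- watershed(distmap(bin))
  lab <- .filterRelabel(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                        x$pixelSize, areaMin, areaMax)
  .roiSetFromLabels(lab, x$pixelSize)
}

#' Segment nuclei from a DAPI max projection (watershed + dilation)
#'
#' Threshold, watershed-split touching nuclei, discard components outside the
#' area pass band (default 40-200 um^2, bounds retained), then isotropically
#' dilate each survivor by \code{dilationUm} to encompass the soma. Where
#' dilated masks would overlap, pixels go to the nearest ROI (ties to the
#' lower label id). Areas are re-reported post-dilation.
#'
#' @inheritParams segmentChromogenic
#' @param dilationUm dilation radius in um (default 5).
#' @return a [ROISet-class] with post-dilation masks and areas.
#' @export
segmentNuclei <- function(img, threshold, areaMin = 40, areaMax = 200,
                          dilationUm = 5, pixelSize = NULL) {
  x <- .as2d(img, pixelSize)
  if (!.checkThreshold(x$im, threshold))
    return(.roiSetFromLabels(matrix(0L, nrow(x$im), ncol(x$im)), x$pixelSize))
  bin <- x$im > threshold
  lab <- watershed(distmap(bin))
  lab <- .filterRelabel(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                        x$pixelSize, areaMin, areaMax)
  if (dilationUm > 0 && any(lab > 0)) {
    # nearest-ROI dilation: each background pixel within the radius joins its
    # closest surviving ROI
    fg <- which(lab > 0, arr.ind = TRUE)
    bg <- which(lab == 0, arr.ind = TRUE)
    if (nrow(bg) && nrow(fg)) {
      rpx <- dilationUm / x$pixelSize
      d2 <- outer(bg[, 1], fg[, 1], `-`)^2 + outer(bg[, 2], fg[, 2], `-`)^2
      nearest <- max.col(-d2, ties.method = "first")
      within <- d2[cbind(seq_len(nrow(bg)), nearest)] <= rpx^2
      lab[bg[within, , drop = FALSE]] <- lab[fg[nearest[within], , drop = FALSE]]
    }
  }
  .roiSetFromLabels(lab, x$pixelSize)
}

#' Segment Slc17a7-filled somata (blur + threshold, no watershed)
#'
#' As [segmentChromogenic()] but without watershed splitting (punctate in situ
#' signal makes watershed over-segment filled somata); touching cells merge.
#' Default pass band 75-450 um^2.
#'
#' @inheritParams segmentChromogenic
#' @return a [ROISet-class].
#' @export
segmentSlc17a7 <- function(img, sigmaPx = 2, threshold, areaMin = 75,
                           areaMax = 450, pixelSize = NULL) {
  x <- .as2d(img, pixelSize)
  im <- if (sigmaPx > 0) gblur(x$im, sigma = sigmaPx) else x$im
  if (!.checkThreshold(im, threshold))
    return(.roiSetFromLabels(matrix(0L, nrow(im), ncol(im)), x$pixelSize))
  lab <- bwlabel(im > threshold)
  lab <- .filterRelabel(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                        x$pixelSize, areaMin, areaMax)
  .roiSetFromLabels(lab, x$pixelSize)
}

# integer-precision phase correlation peak between two equal-size matrices;
# returns d such that b = a translated by +d (periodic convention)
.phaseCorr2 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0)
    stop("flat (zero-variance) image; registration undefined")
  Fa <- fft(a); Fb <- fft(b)
  cp <- Fb * Conj(Fa)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(fft(cp / mag, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  d <- pk - 1L
  dm <- dim(a)
  ifelse(d > dm / 2, d - dm, d)
}

#' Round-to-round FFT offset registration
#'
#' Integer (dx, dy) from phase correlation of the two DAPI max z-projections,
#' then dz from phase correlation of the through-plane (x, z) sections
#' (collapsed over y, which preserves the x/z offsets exactly while averaging
#' out per-voxel noise). Offsets are reported as
#' the translation of the moving round relative to the reference; apply the
#' negated offsets (see [translateStack()]) to every probe channel of the
#' moving round to align it.
#'
#' @param refDapi,movDapi [ImageStack-class]s of identical dimensions.
#' @return integer vector \code{c(dx, dy, dz)} in pixels.
#' @export
registerRounds <- function(refDapi, movDapi) {
  stopifnot(is(refDapi, "ImageStack"), is(movDapi, "ImageStack"))
  if (!all(dim(refDapi@data) == dim(movDapi@data)))
    stop("stacks must have identical dimensions")
  dm <- dim(refDapi@data)
  dxy <- .phaseCorr2(apply(refDapi@data, c(1, 2), max),
                     apply(movDapi@data, c(1, 2), max))
  if (dm[3] == 1L) return(as.integer(c(dxy, 0L)))
  # z alignment from the through-plane (x, z) section, collapsed over y:
  # collapsing makes the slice pair differ exactly by (dx, dz) and averages
  # out per-voxel noise a single slice would be sensitive to
  dxz <- .phaseCorr2(apply(refDapi@data, c(1, 3), mean),
                     apply(movDapi@data, c(1, 3), mean))
  as.integer(c(dxy[1], dxy[2], dxz[2]))
}

#' Per-cell counts-per-area (CPA) quantification
#'
#' For each ROI, the fraction of its mask pixels whose probe intensity
#' exceeds the signal threshold: CPA in [0, 1]. Channels with diffuse
#' background (the 750-nm dyes) can be pre-smoothed with a Gaussian filter.
#'
#' @param rois a [ROISet-class] in the probe image's frame.
#' @param probeImg matrix (same dims as the ROI label image) or
#'   [ImageStack-class] (max projection used).
#' @param threshold signal/background intensity threshold.
#' @param smoothSigmaPx optional Gaussian pre-smoothing SD in pixels.
#' @return data.frame \code{roi}, \code{cpa}.
#' @export
quantifyCPA <- function(rois, probeImg, threshold, smoothSigmaPx = NULL) {
  stopifnot(is(rois, "ROISet"))
  im <- if (is(probeImg, "ImageStack")) apply(probeImg@data, c(1, 2), max)
        else as.matrix(probeImg)
  if (!all(dim(im) == dim(rois@labels)))
    stop("probe image and ROI label image have different dimensions; ",
         "register the round first")
  if (!is.null(smoothSigmaPx) && smoothSigmaPx > 0)
    im <- gblur(im, sigma = smoothSigmaPx)
  pos <- im > threshold
  lab <- rois@labels
  ids <- rois@table$roi
  cpa <- vapply(ids, function(i) mean(pos[lab == i]), numeric(1))
  data.frame(roi = ids, cpa = cpa)
}
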