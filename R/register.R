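#' Rigid landmark (Procrustes) registration without scaling
#'
#' Fits the rotation + translation mapping the source landmark set onto the
#' target with minimum summed squared distance, with correspondence by order
#' (point i to point i). The rotation is constrained to be proper
#' (determinant +1): a mirrored source is never "fixed" by reflection, it
#' simply fits poorly and is flagged through the residual.
#'
#' @param source,target 6 x 2 landmark matrices (um). Any equal number of
#'   non-coincident points >= 2 is accepted; the section tracings use six.
#' @param rmsdWarn warn when the residual RMS distance exceeds this value
#'   (um), e.g. for mirrored or mismatched landmark sets.
#' @return a [RigidTransform-class] with the fitted rotation, translation and
#'   residual RMS.
#' @examples
#' lm <- cbind(c(0, 1, 1, 0, 2, -1), c(0, 0, 1, 1, 2, 2)) * 100
#' th <- pi / 6
#' R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
#' fitProcrustes(lm, t(R %*% t(lm)) + rep(c(100, -50), each = 6))
#' @export
fitProcrustes <- function(source, target, rmsdWarn = 100) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)) || ncol(source) != 2L)
    stop("source and target must be equal-size n x 2 matrices")
  if (nrow(source) < 2L) stop("need at least two landmarks")
  if (max(dist(source)) < 1e-12 || max(dist(target)) < 1e-12)
    stop("degenerate landmark set: all points coincide")
  cs <- colMeans(source); ct <- colMeans(target)
  A <- crossprod(sweep(target, 2, ct), sweep(source, 2, cs)) # t(Yc) %*% Xc
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  tr <- ct - as.vector(R %*% cs)
  fitted <- t(R %*% t(source)) + rep(tr, each = nrow(source))
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  if (rmsd > rmsdWarn)
    warning("landmark residual RMS ", round(rmsd, 1),
            " um exceeds ", rmsdWarn,
            " um; check landmark order or chirality")
  new("RigidTransform", rotation = R, translation = as.numeric(tr), rmsd = rmsd)
}

#' Apply a rigid transform to cell coordinates
#'
#' Maps \code{x_um}/\code{y_um} columns through the transform and, when a
#' template is supplied, re-expresses the result relative to the template's
#' dorsal-most origin. An optional manual post-translation (the hand
#' correction occasionally applied after automatic registration) can be
#' passed explicitly and is recorded in the returned table's attributes.
#'
#' @param transform a [RigidTransform-class].
#' @param cells data.frame with numeric columns \code{x_um}, \code{y_um}.
#' @param template optional [RegionTemplate-class] providing the origin.
#' @param postTranslation optional length-2 numeric (um) applied after the
#'   rigid map; defaults to none.
#' @return \code{cells} with transformed coordinates; attribute
#'   \code{postTranslation} records any manual correction.
#' @export
applyTransform <- function(transform, cells, template = NULL,
                           postTranslation = c(0, 0)) {
  stopifnot(is(transform, "RigidTransform"),
            all(c("x_um", "y_um") %in% names(cells)))
  xy <- as.matrix(cells[, c("x_um", "y_um")])
  xy <- t(transform@rotation %*% t(xy)) +
    rep(transform@translation, each = nrow(xy))
  xy <- xy + rep(as.numeric(postTranslation), each = nrow(xy))
  if (!is.null(template)) {
    stopifnot(is(template, "RegionTemplate"))
    xy <- sweep(xy, 2, template@origin)
  }
  cells$x_um <- xy[, 1]; cells$y_um <- xy[, 2]
  attr(cells, "postTranslation") <- as.numeric(postTranslation)
  cells
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% transform@translation),
      rmsd = transform@rmsd)
}

#' Assign registered cells to LA/BA (and optional subregions)
#'
#' Point-in-polygon assignment over the template, total and deterministic over
#' the plane. Points exactly on a polygon edge follow the half-open rule: an
#' on-edge point belongs to the first polygon tested (LA, then BA); on-edge
#' assignments are counted in the attribute \code{onEdge}.
#'
#' @param cells data.frame with \code{x_um}, \code{y_um} in the template
#'   frame (origin at the template's dorsal-most point).
#' @param template a [RegionTemplate-class].
#' @return \code{cells} with added \code{region} factor
#'   (\code{LA}/\code{BA}/\code{outside}) and, when the template defines
#'   subregions, a \code{subregion} column.
#' @export
assignRegion <- function(cells, template) {
  stopifnot(is(template, "RegionTemplate"),
            all(c("x_um", "y_um") %in% names(cells)))
  if (nrow(template@la) < 3L || nrow(template@ba) < 3L)
    stop("template is missing LA/BA polygons")
  # cells are in origin-relative coordinates; polygons in absolute ones
  xy <- cbind(cells$x_um + template@origin[1],
              cells$y_um + template@origin[2])
  la <- onPolygonEdge(xy, template@la) | pointInPolygon(xy, template@la)
  ba <- !la & (onPolygonEdge(xy, template@ba) | pointInPolygon(xy, template@ba))
  region <- factor(ifelse(la, "LA", ifelse(ba, "BA", "outside")),
                   levels = c("LA", "BA", "outside"))
  cells$region <- region
  if (length(template@subregions)) {
    sub <- rep(NA_character_, nrow(xy))
    for (nm in names(template@subregions)) {
      p <- template@subregions[[nm]]
      hit <- is.na(sub) & (onPolygonEdge(xy, p) | pointInPolygon(xy, p))
      sub[hit] <- nm
    }
    cells$subregion <- sub
  }
  attr(cells, "onEdge") <- sum(onPolygonEdge(xy, template@la) |
                                 onPolygonEdge(xy, template@ba))
  cells
}
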