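#' Simulate a DAPI-like image stack pair for registration/segmentation tests
#'
#' Draws bright disks (cylinders with Gaussian z-profiles) into a stack and
#' returns both the base stack and a copy translated by an integer pixel
#' shift. The translation is periodic (voxels wrap around), which keeps the
#' pair an exact translation of each other so offset recovery is well defined
#' for any shift up to the stack size. Disk areas are known analytically
#' (pi r^2), giving segmentation ground truth.
#'
#' @param rois data.frame of disk specs: \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{intensity}, optional \code{z_um} (disk centre
#'   depth; default mid-stack) and \code{zsd_um} (Gaussian z extent, default
#'   2 um).
#' @param dimPx integer length-3, stack dims (nx, ny, nz) in pixels.
#' @param pixelSize um/px, > 0.
#' @param zStep um per z slice.
#' @param shift integer length-3 (dx, dy, dz) pixel translation of the second
#'   stack; each |component| must be smaller than the stack dimension.
#' @param noiseSd additive Gaussian intensity noise (independent per stack).
#' @param seed integer seed.
#' @return list with \code{base} and \code{moved} [ImageStack-class]s and
#'   \code{truth} (the ROI table with analytic areas plus the shift).
#' @examples
#' disks <- data.frame(x_um = c(20, 50), y_um = c(30, 60),
#'                     radius_um = 8, intensity = 100)
#' pair <- simImageStack(disks, dimPx = c(96, 96, 5), pixelSize = 1,
#'                       shift = c(3, -2, 1))
#' @export
simImageStack <- function(rois, dimPx = c(128L, 128L, 8L), pixelSize = 0.5,
                          zStep = 0.35, shift = c(0L, 0L, 0L), noiseSd = 0,
                          seed = 1L) {
  stopifnot(pixelSize > 0, length(dimPx) == 3L, length(shift) == 3L)
  shift <- as.integer(shift)
  if (any(abs(shift) >= dimPx))
    stop("shift exceeds stack dimensions")
  nx <- dimPx[1]; ny <- dimPx[2]; nz <- dimPx[3]
  if (is.null(rois$z_um)) rois$z_um <- (nz / 2) * zStep
  if (is.null(rois$zsd_um)) rois$zsd_um <- 2
  base <- array(0, dimPx)
  xc <- (seq_len(nx) - 0.5) * pixelSize
  yc <- (seq_len(ny) - 0.5) * pixelSize
  zc <- (seq_len(nz) - 0.5) * zStep
  for (i in seq_len(nrow(rois))) {
    disk <- outer((xc - rois$x_um[i])^2, (yc - rois$y_um[i])^2, `+`) <=
      rois$radius_um[i]^2
    zprof <- exp(-((zc - rois$z_um[i])^2) / (2 * rois$zsd_um[i]^2))
    for (k in seq_len(nz))
      base[, , k] <- pmax(base[, , k], disk * rois$intensity[i] * zprof[k])
  }
  moved <- .circShift3(base, shift)
  withSeed(seed, {
    if (noiseSd > 0) {
      base <- base + array(rnorm(length(base), 0, noiseSd), dimPx)
      moved <- moved + array(rnorm(length(moved), 0, noiseSd), dimPx)
    }
  })
  truth <- rois
  truth$area_um2 <- pi * rois$radius_um^2
  list(base = new("ImageStack", data = base, pixelSize = pixelSize,
                  zStep = zStep),
       moved = new("ImageStack", data = moved, pixelSize = pixelSize,
                   zStep = zStep),
       truth = list(rois = truth, shift = shift))
}

# periodic integer translation: out[i] = in[i - d] (content moves +d)
.circShift3 <- function(a, d) {
  dm <- dim(a)
  idx <- lapply(1:3, function(k) ((seq_len(dm[k]) - 1L - d[k]) %% dm[k]) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Translate an image stack by integer voxel offsets
#'
#' Periodic translation matching the generator's convention; translating by
#' the negated output of [registerRounds()] aligns a moving round onto the
#' reference.
#'
#' @param stack an [ImageStack-class].
#' @param offset integer length-3 (dx, dy, dz).
#' @return the translated [ImageStack-class].
#' @export
translateStack <- function(stack, offset) {
  stopifnot(is(stack, "ImageStack"), length(offset) == 3L)
  new("ImageStack", data = .circShift3(stack@data, as.integer(offset)),
      pixelSize = stack@pixelSize, zStep = stack@zStep)
}
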