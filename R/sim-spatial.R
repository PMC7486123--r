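#' The 12-gene mFISH marker panel used by the spatial generator
#'
#' Two discrete nucleus markers (\code{Negr1} high in LA, \code{Cplx1} high in
#' BA), the excitatory gate gene \code{Slc17a7}, and nine graded markers
#' varying smoothly along per-gene spatial axes.
#' @export
mfishPanel <- c("Nr4a2", "Otof", "Cdh13", "Rorb", "Adamts2", "Prss23",
                "Bdnf", "Slc5a5", "Slc17a7", "Nnat", "Negr1", "Cplx1")

.discreteMarkers <- c(la = "Negr1", ba = "Cplx1")
.gateGene <- "Slc17a7"

#' Configuration for the synthetic mFISH spatial generator
#'
#' Emulates per-cell counts-per-area (CPA) tables over the BLA section
#' templates: the two discrete markers transition sharply (logistic in the
#' signed distance to the LA/BA border), graded markers vary monotonically
#' along gene-specific axes, a small fraction of interneuron-like "spillover"
#' cells carry the opposite discrete marker at full level while failing the
#' excitatory Slc17a7 gate, and additive truncated-Gaussian noise corrupts
#' every positive signal.
#'
#' @param templates list of [RegionTemplate-class] sections to populate
#'   (default: the three shipped sections).
#' @param nCellsPerSection cells per section.
#' @param markerPanel gene names; must contain \code{Negr1}, \code{Cplx1} and
#'   \code{Slc17a7}.
#' @param borderSharpness logistic slope (1/um) of the discrete-marker
#'   transition across the border; \code{Inf} gives a hard step.
#' @param gradientAxes optional named list (per graded gene) of
#'   \code{list(axis = c(x, y), profile = "logistic"|"linear", mid, width)};
#'   \code{NULL} draws gene-specific axes/midpoints/widths per seed.
#' @param markerAmplitude peak CPA of the discrete markers.
#' @param gradientAmplitude CPA dynamic range of the graded markers.
#' @param noiseSd additive CPA noise SD, truncated at 0; applied only where
#'   the mean signal is positive (a probe with no expression produces no
#'   pixels to call).
#' @param spilloverRate fraction of interneuron-like cells.
#' @param seed integer seed.
#' @return validated list of class \code{SpatialSimConfig}.
#' @export
simSpatialConfig <- function(templates = NULL, nCellsPerSection = 600L,
                             markerPanel = mfishPanel,
                             borderSharpness = 0.05, gradientAxes = NULL,
                             markerAmplitude = 0.05,
                             gradientAmplitude = 0.035, noiseSd = 0.004,
                             spilloverRate = 0.05, seed = 1L) {
  if (is.null(templates))
    templates <- lapply(c("anterior", "intermediate", "posterior"), blaTemplate)
  if (is(templates, "RegionTemplate")) templates <- list(templates)
  stopifnot(all(vapply(templates, is, TRUE, "RegionTemplate")))
  if (!all(c(.discreteMarkers, .gateGene) %in% markerPanel))
    stop("markerPanel must contain Negr1, Cplx1 and Slc17a7")
  if (spilloverRate < 0 || spilloverRate >= 1)
    stop("spilloverRate must lie in [0, 1)")
  if (!(borderSharpness > 0)) stop("borderSharpness must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (nCellsPerSection < 1L) stop("nCellsPerSection must be >= 1")
  for (tp in templates)
    if (polygonArea(tp@outline) <= 0) stop("degenerate (zero-area) template")
  structure(list(templates = templates,
                 nCellsPerSection = as.integer(nCellsPerSection),
                 markerPanel = markerPanel,
                 borderSharpness = borderSharpness,
                 gradientAxes = gradientAxes,
                 markerAmplitude = markerAmplitude,
                 gradientAmplitude = gradientAmplitude,
                 noiseSd = noiseSd, spilloverRate = spilloverRate,
                 seed = as.integer(seed)),
            class = "SpatialSimConfig")
}

# additive truncated noise on positive mean signal; exact zeros stay zero
.noisyCPA <- function(mu, sd) {
  out <- numeric(length(mu))
  pos <- mu > 0
  out[pos] <- pmax(0, mu[pos] + rnorm(sum(pos), 0, sd))
  out
}

#' Simulate per-cell mFISH CPA tables over the section templates
#'
#' @param cfg a [simSpatialConfig()] object.
#' @return data.frame with one row per cell: \code{cell_id}, \code{section},
#'   \code{x_um}, \code{y_um} (template frame, origin at the dorsal-most
#'   point), \code{area_um2}, one CPA column per panel gene, and generator
#'   truth columns \code{true_region} (\code{LA}/\code{BA}) and
#'   \code{spillover} (interneuron-like flag). The resolved per-gene gradient
#'   geometry is attached as attribute \code{gradientAxes}.
#' @examples
#' cells <- simSpatialCells(simSpatialConfig(nCellsPerSection = 50, seed = 2))
#' head(cells[, 1:6])
#' @export
simSpatialCells <- function(cfg) {
  stopifnot(inherits(cfg, "SpatialSimConfig"))
  withSeed(cfg$seed, {
    gradGenes <- setdiff(cfg$markerPanel, c(.discreteMarkers, .gateGene))
    axes <- if (is.null(cfg$gradientAxes)) list() else cfg$gradientAxes
    for (g in setdiff(gradGenes, names(axes))) {
      # unspecified genes get per-seed axes and monotone logistic profiles
      ang <- runif(1, 0, 2 * pi)
      axes[[g]] <- list(axis = c(cos(ang), sin(ang)), profile = "logistic",
                        mid = runif(1, 0.3, 0.7), width = runif(1, 0.12, 0.25))
    }
    res <- lapply(cfg$templates, function(tp) {
      n <- cfg$nCellsPerSection
      xyAbs <- samplePointsInPolygon(n, tp@outline)
      inLA <- pointInPolygon(xyAbs, tp@la)
      d <- distanceToPolyline(xyAbs, tp@border) * ifelse(inLA, -1, 1)
      p <- if (is.infinite(cfg$borderSharpness)) as.numeric(d > 0)
           else logistic(d * cfg$borderSharpness)
      spill <- runif(n) < cfg$spilloverRate
      muN <- cfg$markerAmplitude * (1 - p)
      muC <- cfg$markerAmplitude * p
      # interneuron-like cells: opposite marker at full level, gate gene off
      muN[spill] <- cfg$markerAmplitude * (p[spill] > 0.5)
      muC[spill] <- cfg$markerAmplitude * (p[spill] <= 0.5)
      muGate <- rep(0.02, n)
      muGate[spill] <- 0.001
      cpa <- matrix(0, n, length(cfg$markerPanel),
                    dimnames = list(NULL, cfg$markerPanel))
      cpa[, .discreteMarkers["la"]] <- .noisyCPA(muN, cfg$noiseSd)
      cpa[, .discreteMarkers["ba"]] <- .noisyCPA(muC, cfg$noiseSd)
      cpa[, .gateGene] <- .noisyCPA(muGate, cfg$noiseSd / 2)
      bbox <- apply(tp@outline, 2, range)
      for (g in gradGenes) {
        ax <- axes[[g]]$axis / sqrt(sum(axes[[g]]$axis^2))
        proj <- xyAbs %*% ax
        lim <- range(rbind(tp@outline) %*% ax)
        t01 <- (proj - lim[1]) / diff(lim)
        f <- if (identical(axes[[g]]$profile, "linear")) t01
             else logistic((t01 - axes[[g]]$mid) / axes[[g]]$width)
        mu <- 0.005 + cfg$gradientAmplitude * f
        cpa[, g] <- .noisyCPA(mu, cfg$noiseSd)
      }
      xy <- sweep(xyAbs, 2, tp@origin)
      data.frame(section = tp@section, x_um = xy[, 1], y_um = xy[, 2],
                 area_um2 = pmin(400, pmax(100, rnorm(n, 250, 50))),
                 cpa, true_region = ifelse(inLA, "LA", "BA"),
                 spillover = spill, check.names = FALSE)
    })
    out <- do.call(rbind, res)
    out <- cbind(cell_id = sprintf("mf%05d", seq_len(nrow(out))), out)
    attr(out, "gradientAxes") <- axes
    attr(out, "markerPanel") <- cfg$markerPanel
    out
  })
}

#' Simulate projection-labeled cell coordinates
#'
#' Positions are drawn from an isotropic Gaussian of SD \code{spread} centred
#' on \code{center}, truncated (by rejection) to the named nucleus polygon;
#' \code{spread = Inf} gives the uniform distribution over the nucleus.
#' Cell-body areas are drawn log-normal with a smaller LA mean, mirroring the
#' discrete soma-size difference between the nuclei.
#'
#' @param template a [RegionTemplate-class].
#' @param region \code{"LA"} or \code{"BA"}.
#' @param center length-2 numeric, template-frame um (origin-relative); must
#'   lie inside the template outline.
#' @param spread Gaussian SD in um (\code{Inf} for uniform).
#' @param n number of cells (0 returns an empty table).
#' @param seed integer seed.
#' @return data.frame \code{cell_id}, \code{x_um}, \code{y_um} (template
#'   frame), \code{region}, \code{area_um2}.
#' @export
simProjectionCells <- function(template, region = c("LA", "BA"), center,
                               spread, n, seed = 1L) {
  region <- match.arg(region)
  stopifnot(is(template, "RegionTemplate"), length(center) == 2L, n >= 0)
  poly <- if (region == "LA") template@la else template@ba
  centerAbs <- as.numeric(center) + template@origin
  if (!pointInPolygon(rbind(centerAbs), template@outline) &&
      !onPolygonEdge(rbind(centerAbs), template@outline))
    stop("center must lie inside the template outline")
  if (n == 0)
    return(data.frame(cell_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), region = character(0),
                      area_um2 = numeric(0)))
  withSeed(seed, {
    if (is.infinite(spread)) {
      xy <- samplePointsInPolygon(n, poly)
    } else {
      xy <- matrix(NA_real_, n, 2)
      filled <- 0L; tries <- 0L
      while (filled < n) {
        m <- max(4L * (n - filled), 64L)
        cand <- cbind(rnorm(m, centerAbs[1], spread),
                      rnorm(m, centerAbs[2], spread))
        keep <- head(which(pointInPolygon(cand, poly)), n - filled)
        if (length(keep)) {
          xy[filled + seq_along(keep), ] <- cand[keep, , drop = FALSE]
          filled <- filled + length(keep)
        }
        tries <- tries + 1L
        if (tries > 10000L)
          stop("rejection sampling failed; is the center near the ",
               region, " polygon?")
      }
    }
    xy <- sweep(xy, 2, template@origin)
    area <- rlnorm(n, meanlog = if (region == "LA") log(150) else log(250),
                   sdlog = 0.25)
    data.frame(cell_id = sprintf("proj%04d", seq_len(n)),
               x_um = xy[, 1], y_um = xy[, 2], region = region,
               area_um2 = area)
  })
}
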