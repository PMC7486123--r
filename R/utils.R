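#' @importFrom methods new validObject is slot
#' @importFrom stats prcomp rnbinom rlnorm rnorm runif rbinom dist hclust
#'   cutree cor pnorm pwilcox quantile sd var median setNames ave
#'   p.adjust fft predict
#' @importFrom utils combn head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed for a named pipeline stage. Kept below 2^31 so the
# result is always a valid R integer seed.
childSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

logistic <- function(x) 1 / (1 + exp(-x))

## ---- planar polygon utilities -------------------------------------------
## No computational-geometry package ships in this stack, so the few
## primitives needed (area, containment, segment distance) are implemented
## here with explicit boundary semantics.

# Shoelace area (positive regardless of orientation).
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# TRUE where point lies exactly on the polygon boundary (within eps).
onPolygonEdge <- function(pts, poly, eps = 1e-9) {
  pts <- rbind(pts)
  n <- nrow(poly)
  res <- rep(FALSE, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- a[1] + t * ab[1] - pts[, 1]
    dy <- a[2] + t * ab[2] - pts[, 2]
    res <- res | (dx * dx + dy * dy) <= eps^2
  }
  res
}

# Even-odd ray casting with the half-open edge rule (y1 <= y < y2), vectorised
# over points. Boundary points are NOT guaranteed in/out here; callers that
# care (assignRegion) test onPolygonEdge first.
pointInPolygon <- function(pts, poly) {
  pts <- rbind(pts)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from each point to a polyline (matrix of vertices).
distanceToPolyline <- function(pts, line) {
  pts <- rbind(pts)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- a[1] + t * ab[1] - pts[, 1]
    dy <- a[2] + t * ab[2] - pts[, 2]
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

# Uniform rejection sampling of n points inside a polygon.
samplePointsInPolygon <- function(n, poly) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  bbox <- apply(poly, 2, range)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 32L)
    cand <- cbind(runif(m, bbox[1, 1], bbox[2, 1]),
                  runif(m, bbox[1, 2], bbox[2, 2]))
    keep <- which(pointInPolygon(cand, poly))
    take <- head(keep, n - filled)
    if (length(take)) {
      out[filled + seq_along(take), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  out
}

meanPairwiseDistance <- function(xy) {
  if (nrow(xy) < 2) stop("need at least 2 points for pairwise distances")
  mean(dist(xy))
}
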