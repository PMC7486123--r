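#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' The test engine behind [differentialExpression()] and [areaCompare()].
#' For small samples the exact null distribution of U is used: via the
#' closed-form untied distribution when there are no ties, or by exhaustive
#' enumeration of all group assignments of the (mid-)ranks when there are.
#' Larger samples use the normal approximation with the tie correction and a
#' 0.5 continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact path;
#'   default \code{NULL} chooses exact when both samples have at most
#'   \code{maxExact} observations and full enumeration is affordable.
#' @param maxExact largest per-group size for the automatic exact path.
#' @param alternative \code{"two.sided"} (default) or \code{"less"}/
#'   \code{"greater"} for one-sided alternatives on \code{x}.
#' @return list with \code{statistic} (U for sample \code{x}), \code{p.value}
#'   and \code{method} (\code{"exact"} or \code{"normal"}).
#' @examples
#' rankSumTest(c(1, 2, 3), c(10, 11, 12))$statistic  # U = 0
#' @export
rankSumTest <- function(x, y, exact = NULL, maxExact = 10L,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact))
    exact <- nx <= maxExact && ny <= maxExact && choose(nx + ny, nx) <= 5e4
  if (exact) {
    if (!ties) {
      pl <- pwilcox(u, nx, ny)            # P(U <= u)
      pg <- 1 - pwilcox(u - 1, nx, ny)    # P(U >= u)
    } else {
      # enumerate U over all assignments of the midranks to group x
      idx <- combn(nx + ny, nx)
      us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
      pl <- mean(us <= u + 1e-9)
      pg <- mean(us >= u - 1e-9)
    }
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pl, pg)),
                less = pl, greater = pg)
    return(list(statistic = u, p.value = p, method = "exact"))
  }
  n <- nx + ny
  tie.tab <- table(r)
  tiesum <- sum(tie.tab^3 - tie.tab)
  mu <- nx * ny / 2
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tiesum / (n * (n - 1))))
  if (sigma == 0) return(list(statistic = u, p.value = 1, method = "normal"))
  z <- switch(alternative,
              two.sided = (abs(u - mu) - 0.5) / sigma,
              less = (u - mu + 0.5) / sigma,
              greater = (u - mu - 0.5) / sigma)
  p <- switch(alternative,
              two.sided = min(1, 2 * pnorm(-max(z, 0))),
              less = pnorm(z),
              greater = pnorm(-z))
  list(statistic = u, p.value = p, method = "normal")
}

# Vectorised normal-approximation rank-sum over matrix rows (genes); used by
# differentialExpression where per-gene exact tests would be pointless at
# n > 1000 cells. Returns two-sided p and the U statistic for group A.
rankSumRows <- function(mat, idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB)
  n <- nA + nB
  sub <- mat[, c(idxA, idxB), drop = FALSE]
  mu <- nA * nB / 2
  out <- t(apply(sub, 1L, function(v) {
    r <- rank(v)
    u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    tt <- rle(sort.int(v, method = "radix"))$lengths
    tiesum <- sum(tt^3 - tt)
    sigma2 <- nA * nB / 12 * ((n + 1) - tiesum / (n * (n - 1)))
    c(u, sigma2)
  }))
  u <- out[, 1]; sigma <- sqrt(out[, 2])
  z <- ifelse(sigma > 0, (abs(u - mu) - 0.5) / sigma, 0)
  p <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  p[sigma == 0] <- 1
  list(U = u, p.value = p)
}
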