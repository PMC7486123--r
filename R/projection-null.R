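#' Monte-Carlo enrichment null for projection targets
#'
#' Under the null, the N projection-labeled cells are an unremarkable random
#' selection from the excitatory reference pool. Each of \code{nIter}
#' iterations draws N pool cells (without replacement by default) and counts
#' how many fall in the LA; the observed LA count is compared against the
#' percentile 95% interval of the draws and the add-one two-sided empirical
#' p-value (distance from the null mean). An observed count more extreme than
#' every draw reports p = 1/(nIter + 1), i.e. p < 0.001 at the default 1000
#' iterations.
#'
#' @param observed data.frame of projection-labeled cells with a
#'   \code{region} column (\code{LA}/\code{BA}), e.g. from [assignRegion()]
#'   or [simProjectionCells()].
#' @param pool data.frame of reference excitatory cells with a \code{region}
#'   column; must contain at least \code{nrow(observed)} cells.
#' @param nIter Monte-Carlo iterations (default 1000).
#' @param seed integer seed.
#' @param replace draw with replacement instead (off by default: the pool is
#'   finite).
#' @return a [NullDistribution-class]; slot \code{enriched} is TRUE when the
#'   observed count falls outside the 95% interval.
#' @export
mcEnrichment <- function(observed, pool, nIter = 1000L, seed = 1L,
                         replace = FALSE) {
  stopifnot("region" %in% names(observed), "region" %in% names(pool))
  N <- nrow(observed)
  if (N > nrow(pool) && !replace)
    stop("observed set is larger than the pool")
  isLA <- pool$region == "LA"
  obs <- sum(observed$region == "LA")
  draws <- withSeed(seed,
    vapply(seq_len(nIter),
           function(i) sum(sample(isLA, N, replace = replace)),
           numeric(1)))
  .nullDist("LA count", draws, obs, alternative = "two.sided",
            seed = as.integer(seed))
}

#' Monte-Carlo null for spatial restriction of a projection
#'
#' Tests whether projection-labeled cells are more spatially concentrated
#' than a random same-size selection of reference cells: the statistic is the
#' mean (optionally median) pairwise Euclidean distance, and the one-sided
#' empirical p-value is the add-one fraction of null draws at or below the
#' observed value.
#'
#' @param observed data.frame with \code{x_um}, \code{y_um} (>= 2 cells).
#' @param pool reference cells with \code{x_um}, \code{y_um} (e.g. all BA
#'   excitatory cells).
#' @param nIter iterations.
#' @param seed integer seed.
#' @param statistic \code{"mean"} (default) or \code{"median"} pairwise
#'   distance.
#' @return a [NullDistribution-class] (alternative \code{"less"}).
#' @export
mcDistanceRestriction <- function(observed, pool, nIter = 1000L, seed = 1L,
                                  statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (nrow(observed) < 2L) stop("need at least 2 observed cells")
  stat <- function(xy) {
    d <- dist(xy)
    if (statistic == "mean") mean(d) else median(d)
  }
  obs <- stat(as.matrix(observed[, c("x_um", "y_um")]))
  pxy <- as.matrix(pool[, c("x_um", "y_um")])
  n <- nrow(observed)
  if (n > nrow(pool)) stop("observed set is larger than the pool")
  draws <- withSeed(seed,
    vapply(seq_len(nIter),
           function(i) stat(pxy[sample.int(nrow(pxy), n), , drop = FALSE]),
           numeric(1)))
  .nullDist(paste(statistic, "pairwise distance"), draws, obs,
            alternative = "less", seed = as.integer(seed))
}

.nullDist <- function(name, draws, obs, alternative, seed) {
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  p <- if (alternative == "two.sided") {
    m <- mean(draws)
    (1 + sum(abs(draws - m) >= abs(obs - m))) / (1 + length(draws))
  } else {
    (1 + sum(draws <= obs)) / (1 + length(draws))
  }
  new("NullDistribution", statistic = name, draws = as.numeric(draws),
      observed = obs, ci = ci, pValue = p, alternative = alternative,
      enriched = if (alternative == "two.sided") obs < ci[1] || obs > ci[2]
                 else NA, seed = seed)
}

#' Pairwise Mann-Whitney U comparisons of cell-body areas
#'
#' Two-sided unpaired Mann-Whitney U test for every pair of groups (exact
#' for small groups, normal approximation with tie correction otherwise).
#' No multiplicity adjustment is applied; the number of comparisons is
#' reported so readers can adjust if they wish.
#'
#' @param groups named list of numeric cell-body area vectors (um^2); each
#'   group needs >= 3 observations.
#' @return data.frame \code{groupA}, \code{groupB}, \code{U}, \code{p};
#'   attribute \code{nComparisons}.
#' @export
areaCompare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  ns <- lengths(groups)
  if (any(ns == 0)) stop("empty group: ", names(groups)[which(ns == 0)[1]])
  if (any(ns < 3)) stop("every group needs at least 3 observations")
  pairs <- combn(names(groups), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    t <- rankSumTest(groups[[a]], groups[[b]])
    data.frame(groupA = a, groupB = b, U = t$statistic, p = t$p.value)
  }))
  attr(out, "nComparisons") <- ncol(pairs)
  out
}
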