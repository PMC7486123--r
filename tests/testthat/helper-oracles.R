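# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / first principles and never call the package code
# they are checking.

# exhaustive two-sided Mann-Whitney p: enumerate every assignment of the
# pooled observations to the first group and tabulate the U statistic
enumRankSumP <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  us <- apply(sets, 2L, function(id) sum(r[id]) - nx * (nx + 1) / 2)
  pl <- mean(us <= uObs + 1e-9)
  pg <- mean(us >= uObs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(pl, pg)),
         less = pl, greater = pg)
}

# greedy Ward agglomeration from first principles: at each step merge the
# pair of clusters with the smallest increase in within-cluster sum of
# squares. Returns the list of partitions after each merge.
naiveWardMerges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL; bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ma <- colMeans(X[a, , drop = FALSE])
      mb <- colMeans(X[b, , drop = FALSE])
      d <- (length(a) * length(b)) / (length(a) + length(b)) *
        sum((ma - mb)^2)
      if (d < bestD) { bestD <- d; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(sort(merged)))
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  partitions
}

# partition sequence implied by an hclust merge matrix
hclustPartitions <- function(hc) {
  n <- length(hc$order)
  members <- lapply(seq_len(n), identity)
  clusters <- members
  partitions <- list()
  nodes <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(v) if (v < 0) members[[-v]] else nodes[[v]]
    merged <- sort(c(pick(hc$merge[s, 1]), pick(hc$merge[s, 2])))
    nodes[[s]] <- merged
    clusters <- Filter(function(cl) !all(cl %in% merged), clusters)
    clusters <- c(clusters, list(merged))
    partitions[[s]] <- lapply(clusters, sort)
  }
  partitions
}

samePartition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(cl) paste(cl, collapse = ","),
                                 character(1)))
  identical(key(a), key(b))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# seeded Gaussian blobs in `d` dimensions
makeBlobs <- function(nPer, centers, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(nPer * ncol(centers), sd = sd), nPer) +
      rep(centers[i, ], each = nPer)))
  list(x = X, label = rep(seq_len(nrow(centers)), each = nPer))
}

# small simulated dataset for pipeline unit tests
smallSim <- function(seed = 7, nCells = 180L, nGenes = 1200L, nDE = 60L,
                     nGrad = 8L) {
  computeCPM(qcFilter(simCounts(simCountConfig(
    nCells = nCells, nGenes = nGenes, nDEGenes = nDE,
    nGradientGenesPerPop = nGrad, seed = seed))))
}
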