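#' Differential expression between two clusters (Wilcoxon + Bonferroni)
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on log CPM between the two
#' clusters (normal approximation with tie and continuity corrections at this
#' sample size), Bonferroni-adjusted over the genes actually tested. Genes
#' detected (count > 0) in fewer than \code{minDetected} of the involved
#' cells are not tested — the expression floor keeps the Bonferroni
#' denominator honest and is reported alongside the results.
#'
#' @param sce object with \code{cpm}, \code{logcpm} and \code{counts} assays.
#' @param labels cluster labels from [clusterGraph()] (or any vector aligned
#'   with the cells).
#' @param clusterA,clusterB the two labels to contrast; each must contain at
#'   least 3 cells.
#' @param alpha adjusted-p significance threshold used for the
#'   \code{significant} flag.
#' @param minDetected expression floor (default: detected in >= 3 cells).
#' @return data.frame, one row per tested gene: \code{gene}, \code{logFC}
#'   (\code{ln((meanCPM_A + 1) / (meanCPM_B + 1))}), \code{p}, \code{pAdj}
#'   (\code{min(1, p x nTested)}), \code{enrichedCluster},
#'   \code{significant}; attribute \code{nTested}.
#' @export
differentialExpression <- function(sce, labels, clusterA = 0L, clusterB = 1L,
                                   alpha = 0.05, minDetected = 3L) {
  idxA <- which(labels == clusterA)
  idxB <- which(labels == clusterB)
  if (!length(idxA) || !length(idxB))
    stop("both clusters must be non-empty")
  if (length(idxA) < 3L || length(idxB) < 3L)
    stop("clusters of fewer than 3 cells cannot be tested at useful power")
  counts <- assay(sce, "counts")[, c(idxA, idxB), drop = FALSE]
  tested <- rowSums(counts > 0) >= minDetected
  lg <- assay(sce, "logcpm")[tested, , drop = FALSE]
  res <- if (max(length(idxA), length(idxB)) <= 10L) {
    # small clusters: exact per-gene null distribution
    sub <- lg[, c(idxA, idxB), drop = FALSE]
    p <- apply(sub, 1L, function(v)
      rankSumTest(v[seq_along(idxA)], v[-seq_along(idxA)])$p.value)
    list(p.value = p)
  } else rankSumRows(lg, idxA, idxB)
  nTested <- sum(tested)
  cpm <- assay(sce, "cpm")[tested, , drop = FALSE]
  mA <- rowMeans(cpm[, idxA, drop = FALSE])
  mB <- rowMeans(cpm[, idxB, drop = FALSE])
  out <- data.frame(
    gene = rownames(lg),
    logFC = log((mA + 1) / (mB + 1)),
    p = res$p.value,
    pAdj = pmin(1, res$p.value * nTested),
    enrichedCluster = ifelse(mA >= mB, clusterA, clusterB),
    row.names = NULL
  )
  out$significant <- out$pAdj < alpha
  attr(out, "nTested") <- nTested
  attr(out, "minDetected") <- minDetected
  out
}
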