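#' Select highly variable genes (binned dispersion z-scores)
#'
#' Per gene, mean statistic \code{ln(mean(CPM) + 1)} and dispersion statistic
#' \code{ln(var(CPM) / mean(CPM))}; dispersions are z-scored within
#' \code{nBins} equal-width bins of the mean statistic, and genes passing
#' \code{xLow <= mean <= xHigh} with z-scored dispersion \code{>= yCutoff}
#' are selected. Genes with zero mean or zero variance (dispersion undefined)
#' are excluded and listed in the \code{excluded} attribute. The interneuron
#' parameterization of the same procedure is obtained with
#' \code{xLow = 0.0125, yCutoff = 3}.
#'
#' @param sce object with \code{cpm} assay (see [computeCPM()]).
#' @param xLow,xHigh mean-statistic window (defaults 0.125, 3).
#' @param yCutoff minimum within-bin dispersion z-score (default 1).
#' @param nBins number of equal-width mean bins (default 20).
#' @return character vector of selected gene names; attributes \code{stats}
#'   (per-gene data.frame) and \code{excluded}.
#' @export
selectVariableGenes <- function(sce, xLow = 0.125, xHigh = 3, yCutoff = 1,
                                nBins = 20L) {
  cpm <- assay(sce, "cpm")
  gm <- rowMeans(cpm)
  gv <- apply(cpm, 1L, var)
  ok <- gm > 0 & gv > 0
  meanStat <- log(gm + 1)
  dispStat <- rep(NA_real_, length(gm))
  dispStat[ok] <- log(gv[ok] / gm[ok])
  z <- rep(NA_real_, length(gm))
  ms <- meanStat[ok]
  edges <- seq(min(ms), max(ms), length.out = nBins + 1L)
  bins <- pmin(pmax(findInterval(ms, edges, rightmost.closed = TRUE), 1L),
               nBins)
  zok <- ave(dispStat[ok], bins, FUN = function(v)
    if (length(v) > 1 && sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
  z[ok] <- zok
  sel <- ok & meanStat >= xLow & meanStat <= xHigh & z >= yCutoff
  sel[is.na(sel)] <- FALSE
  out <- rownames(cpm)[sel]
  attr(out, "stats") <- data.frame(gene = rownames(cpm), mean = meanStat,
                                   dispersion = dispStat, z = z,
                                   selected = sel, row.names = NULL)
  attr(out, "excluded") <- rownames(cpm)[!ok]
  out
}

#' PCA embedding of cells on selected genes
#'
#' Genes are z-scored across cells (zero-variance genes dropped with a
#' message), then cells are projected onto the leading principal components.
#' The sign of each component is fixed by making the largest-magnitude
#' element of its loading vector positive, so scores are reproducible across
#' platforms.
#'
#' @param sce object with \code{logcpm} assay, or a genes x cells matrix.
#' @param genes genes to use (>= 2).
#' @param nPcs number of components (clipped with a warning if it exceeds
#'   the data rank bound).
#' @return cells x PCs score matrix; attributes \code{varExplained} and
#'   \code{loadings}.
#' @export
pcaEmbed <- function(sce, genes, nPcs = 10L) {
  x <- if (is(sce, "SummarizedExperiment")) assay(sce, "logcpm") else sce
  genes <- intersect(genes, rownames(x))
  if (length(genes) < 2L) stop("need at least two (present) variable genes")
  m <- t(x[genes, , drop = FALSE])
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " zero-variance gene(s) before PCA")
    m <- m[, sds > 0, drop = FALSE]
  }
  maxPcs <- min(dim(m)) - 1L
  if (nPcs > maxPcs) {
    warning("nPcs clipped from ", nPcs, " to ", maxPcs)
    nPcs <- maxPcs
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- seq_len(nPcs)
  flip <- vapply(k, function(i) {
    l <- pc$rotation[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, k, drop = FALSE], 2L, flip, `*`)
  attr(scores, "varExplained") <- (pc$sdev^2 / sum(pc$sdev^2))[k]
  attr(scores, "loadings") <- sweep(pc$rotation[, k, drop = FALSE], 2L, flip, `*`)
  scores
}
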