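#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

.countsOf <- function(sce) {
  stopifnot(is(sce, "SummarizedExperiment"))
  assay(sce, "counts")
}

#' Exclude low-depth cells
#'
#' Removes cells whose total count is strictly below \code{minCounts}
#' (default 10,000); a cell at exactly the threshold is retained. The
#' exclusion report (ids and count) is stored in
#' \code{metadata(.)$qcFilter}.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   \code{counts} assay.
#' @param minCounts minimum total count per cell.
#' @return the filtered object. If every cell fails, an empty (0-column)
#'   object is returned with a warning rather than an error.
#' @export
qcFilter <- function(sce, minCounts = 10000) {
  totals <- colSums(.countsOf(sce))
  drop <- totals < minCounts
  report <- list(minCounts = minCounts, nRemoved = sum(drop),
                 removed = colnames(sce)[drop])
  if (all(drop) && ncol(sce) > 0)
    warning("qcFilter removed every cell (minCounts = ", minCounts, ")")
  out <- sce[, !drop]
  metadata(out)$qcFilter <- report
  out
}

#' Counts-per-million normalization
#'
#' Adds assays \code{cpm} (\code{counts / total x 1e6}) and \code{logcpm}
#' (\code{ln(1 + CPM)}, the log layer used for variable-gene statistics,
#' PCA and differential tests).
#'
#' @param sce object with a \code{counts} assay; every cell must have a
#'   positive total (run [qcFilter()] first).
#' @return the object with \code{cpm} and \code{logcpm} assays.
#' @export
computeCPM <- function(sce) {
  counts <- .countsOf(sce)
  totals <- colSums(counts)
  if (ncol(sce) && any(totals == 0))
    stop("cells with zero total counts present; run qcFilter() first")
  cpm <- sweep(counts, 2L, totals, `/`) * 1e6
  assay(sce, "cpm") <- cpm
  assay(sce, "logcpm") <- log1p(cpm)
  sce
}

#' Gate cells into non-neuronal / interneuron / excitatory classes
#'
#' Cells with \code{Snap25} CPM strictly below \code{neuronalMin} are
#' non-neuronal; of the rest, cells with \code{Gad1} CPM strictly above
#' \code{inhMax} are interneurons; the remainder are excitatory. Boundary
#' cells (CPM exactly at a threshold) stay in the less-exclusive class.
#'
#' @param sce object with a \code{cpm} assay.
#' @param neuronalGene,neuronalMin pan-neuronal gate (default Snap25, 250).
#' @param inhGene,inhMax interneuron gate (default Gad1, 100).
#' @return factor (levels \code{non_neuronal}, \code{interneuron},
#'   \code{excitatory}) named by cell, also stored in
#'   \code{colData(.)$cellClass} of the attribute-carrying return value when
#'   assigned back.
#' @export
gateCellClasses <- function(sce, neuronalGene = "Snap25", neuronalMin = 250,
                            inhGene = "Gad1", inhMax = 100) {
  cpm <- assay(sce, "cpm")
  for (g in c(neuronalGene, inhGene))
    if (!g %in% rownames(cpm))
      stop("gate gene '", g, "' is not present in the matrix")
  cls <- ifelse(cpm[neuronalGene, ] < neuronalMin, "non_neuronal",
                ifelse(cpm[inhGene, ] > inhMax, "interneuron", "excitatory"))
  factor(setNames(cls, colnames(cpm)),
         levels = c("non_neuronal", "interneuron", "excitatory"))
}
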