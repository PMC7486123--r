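#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Write / read a count matrix as matrix-market with TSV sidecars
#'
#' \code{writeCountsMM} writes \code{matrix.mtx}, \code{genes.tsv} and
#' \code{cells.tsv} (plus \code{coldata.tsv} for any cell annotations) into
#' \code{dir}; \code{readCountsMM} reads them back into a
#' SingleCellExperiment.
#'
#' @param sce object with a \code{counts} assay.
#' @param dir output directory (created if needed).
#' @return \code{writeCountsMM}: the directory, invisibly;
#'   \code{readCountsMM}: a [SingleCellExperiment::SingleCellExperiment].
#' @export
writeCountsMM <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(assay(sce, "counts"), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "cells.tsv"))
  cd <- as.data.frame(colData(sce))
  if (ncol(cd))
    write.table(cbind(cell = colnames(sce), cd),
                file.path(dir, "coldata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCountsMM
#' @export
readCountsMM <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  cdFile <- file.path(dir, "coldata.tsv")
  cd <- if (file.exists(cdFile)) {
    d <- read.delim(cdFile)
    rownames(d) <- d$cell
    S4Vectors::DataFrame(d[colnames(m), setdiff(names(d), "cell"),
                           drop = FALSE])
  } else S4Vectors::DataFrame(row.names = colnames(m))
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m),
                                             colData = cd)
}

#' Read / write dense CSV counts (genes as rows)
#' @param file CSV path; first column gene ids, remaining columns cells.
#' @return a SingleCellExperiment.
#' @export
readCountsCSV <- function(file) {
  d <- read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' @rdname readCountsCSV
#' @param sce object with a \code{counts} assay.
#' @export
writeCountsCSV <- function(sce, file) {
  write.csv(as.data.frame(assay(sce, "counts")), file)
  invisible(file)
}

#' Read / write spatial cell tables (TSV)
#'
#' Columns: \code{cell_id}, \code{section}, \code{x_um}, \code{y_um},
#' \code{area_um2}, then one CPA column per gene (plus any extra columns
#' such as \code{region} or \code{phenotype}).
#'
#' @param cells spatial-cell data.frame.
#' @param file TSV path.
#' @export
writeSpatialCells <- function(cells, file) {
  write.table(cells, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSpatialCells
#' @export
readSpatialCells <- function(file) {
  read.delim(file, check.names = FALSE)
}

#' Write an aggregate correlation profile as TSV
#' @param profile a [CorrelationProfile-class].
#' @param file TSV path.
#' @export
writeProfile <- function(profile, file) {
  write.table(profileStats(profile), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Export an mFISH dendrogram in Newick format
#'
#' Uses \pkg{ape} when available (it is a suggested dependency).
#'
#' @param labels output of [clusterMFISH()] (carries the \code{hclust}
#'   attribute).
#' @param file output path.
#' @export
writeDendrogramNewick <- function(labels, file) {
  hc <- attr(labels, "hclust")
  if (is.null(hc)) stop("labels carry no hclust attribute")
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the ape package")
  ape::write.tree(ape::as.phylo(hc), file)
  invisible(file)
}
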