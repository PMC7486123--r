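#' Phenotype index of relative discrete-marker expression
#'
#' \eqn{(E_{Cplx1} - E_{Negr1}) / (E_{Cplx1} + E_{Negr1})}: -1 for cells
#' exclusively expressing Negr1, +1 for cells exclusively expressing Cplx1,
#' 0 at parity. Undefined (NA) when both expressions are zero; such cells are
#' excluded from phenotype analyses downstream. The index is antisymmetric
#' under gene swap and invariant to rescaling both expressions.
#'
#' @param cells data.frame of spatial cells with per-gene CPA columns (a
#'   single-row data.frame works for one cell).
#' @param geneA,geneB the two discrete markers (defaults Negr1, Cplx1); the
#'   index is positive when \code{geneB} dominates.
#' @return numeric vector in [-1, 1], NA where both CPAs are zero.
#' @examples
#' phenotypeIndex(data.frame(Negr1 = 5, Cplx1 = 0))  # -1
#' phenotypeIndex(data.frame(Negr1 = 0, Cplx1 = 7))  # +1
#' @export
phenotypeIndex <- function(cells, geneA = "Negr1", geneB = "Cplx1") {
  for (g in c(geneA, geneB))
    if (!g %in% names(cells)) stop("gene column '", g, "' is missing")
  a <- cells[[geneA]]; b <- cells[[geneB]]
  ifelse(a + b > 0, (b - a) / (b + a), NA_real_)
}

#' Winner-take-all phenotype binarization
#'
#' Restricts to excitatory cells (\code{Slc17a7} CPA at or above the gate,
#' default 0.004; strictly lower is removed), then labels each survivor by
#' its higher-expressed discrete marker. Cells expressing neither marker are
#' labeled \code{none} and excluded from phenotype-stratified analyses.
#' Exact nonzero ties are broken to \code{CPLX1} deterministically and
#' counted in the \code{ties} attribute.
#'
#' @param cells spatial-cell data.frame with CPA columns.
#' @param gateGene,gateCpa excitatory gate (default \code{Slc17a7}, 0.004).
#' @param geneA,geneB discrete markers (default Negr1 -> \code{NEGR1},
#'   Cplx1 -> \code{CPLX1}).
#' @return the gated cells with a \code{phenotype} factor column
#'   (\code{NEGR1}, \code{CPLX1}, \code{none}); attributes \code{nGatedOut}
#'   and \code{ties}.
#' @export
binarizePhenotype <- function(cells, gateGene = "Slc17a7", gateCpa = 0.004,
                              geneA = "Negr1", geneB = "Cplx1") {
  for (g in c(gateGene, geneA, geneB))
    if (!g %in% names(cells)) stop("gene column '", g, "' is missing")
  keep <- cells[[gateGene]] >= gateCpa
  out <- cells[keep, , drop = FALSE]
  a <- out[[geneA]]; b <- out[[geneB]]
  ph <- ifelse(a + b == 0, "none", ifelse(b >= a, "CPLX1", "NEGR1"))
  out$phenotype <- factor(ph, levels = c("NEGR1", "CPLX1", "none"))
  attr(out, "nGatedOut") <- sum(!keep)
  attr(out, "ties") <- sum(a == b & a > 0)
  out
}

.pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Distance-binned correlation profile around one seed cell
#'
#' Pearson correlation of the expression panel between the seed and every
#' other phenotyped cell of the same section, averaged within half-open
#' distance bins \code{[0, w), [w, 2w), ...} (default w = 100 um) and split
#' by whether the partner shares the seed's discrete phenotype. The seed is
#' excluded from its own profile; cells with phenotype \code{none} are
#' ignored.
#'
#' @param seedId cell id of the seed (must carry a non-\code{none}
#'   phenotype).
#' @param cells phenotyped cells from [binarizePhenotype()] with
#'   \code{x_um}, \code{y_um}, \code{section}.
#' @param genes expression panel used for the correlations (default: the
#'   full 12-gene panel including the discrete markers).
#' @param binWidth bin width in um.
#' @param maxDist largest bin edge (default: farthest pair, rounded up).
#' @return a [CorrelationProfile-class].
#' @export
correlationProfile <- function(seedId, cells, genes = mfishPanel,
                               binWidth = 100, maxDist = NULL) {
  genes <- intersect(genes, names(cells))
  if (length(genes) < 3L) stop("need at least 3 panel genes")
  i <- match(seedId, cells$cell_id)
  if (is.na(i)) stop("seed cell '", seedId, "' not found")
  if (cells$phenotype[i] == "none")
    stop("seed cell has no discrete phenotype")
  same <- cells$section == cells$section[i] & cells$cell_id != seedId &
    cells$phenotype != "none"
  other <- cells[same, , drop = FALSE]
  sv <- as.numeric(cells[i, genes])
  if (sd(sv) == 0) stop("seed expression vector has zero variance")
  M <- as.matrix(other[, genes])
  r <- apply(M, 1L, function(v) if (sd(v) == 0) NA_real_ else .pearson(sv, v))
  dd <- sqrt((other$x_um - cells$x_um[i])^2 + (other$y_um - cells$y_um[i])^2)
  if (is.null(maxDist)) maxDist <- ceiling(max(dd) / binWidth) * binWidth
  edges <- seq(0, maxDist, by = binWidth)
  bin <- findInterval(dd, edges, rightmost.closed = FALSE)  # half-open bins
  cls <- ifelse(other$phenotype == cells$phenotype[i], "same", "opposite")
  grid <- expand.grid(bin = head(edges, -1), class = c("same", "opposite"),
                      stringsAsFactors = FALSE)
  st <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
    sel <- bin == match(grid$bin[j], head(edges, -1)) & cls == grid$class[j] &
      !is.na(r)
    data.frame(bin = grid$bin[j], class = grid$class[j],
               mean_r = if (any(sel)) mean(r[sel]) else NA_real_,
               sd_r = NA_real_, n = sum(sel))
  }))
  new("CorrelationProfile", seedId = as.character(seedId),
      binWidth = binWidth, stats = st, aggregated = FALSE)
}

#' Aggregate per-seed correlation profiles
#'
#' Pools profiles computed on a common bin grid: per bin and phenotype class,
#' the mean of the per-seed bin means and their across-seed standard
#' deviation (the spread shown about the aggregate curves). Bins empty in a
#' given seed are skipped for that seed; a single-profile aggregate has SD 0
#' by convention.
#'
#' @param profiles list of [CorrelationProfile-class] objects on the same bin
#'   grid.
#' @return an aggregate [CorrelationProfile-class].
#' @export
aggregateProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, TRUE, "CorrelationProfile")))
  w <- unique(vapply(profiles, function(p) p@binWidth, numeric(1)))
  if (length(w) != 1L) stop("profiles have inconsistent bin widths")
  bins <- sort(unique(profiles[[1]]@stats$bin))
  for (p in profiles)
    if (!setequal(unique(p@stats$bin), bins))
      stop("profiles have inconsistent bin grids")
  st <- do.call(rbind, lapply(c("same", "opposite"), function(cl) {
    do.call(rbind, lapply(bins, function(b) {
      vals <- unlist(lapply(profiles, function(p) {
        s <- p@stats
        v <- s$mean_r[s$bin == b & s$class == cl]
        v[!is.na(v)]
      }))
      data.frame(bin = b, class = cl,
                 mean_r = if (length(vals)) mean(vals) else NA_real_,
                 sd_r = if (length(vals) > 1) sd(vals)
                        else if (length(vals) == 1) 0 else NA_real_,
                 n = length(vals))
    }))
  }))
  new("CorrelationProfile", seedId = "<aggregate>", binWidth = w,
      stats = st, aggregated = TRUE)
}

#' Hierarchical clustering of sum-normalized CPA profiles
#'
#' Each cell's CPA vector is normalized to sum to 1 (cells with zero total
#' CPA are excluded with a message), then clustered agglomeratively with
#' Ward's D2 linkage on Euclidean distances and cut at \code{k}.
#'
#' @param cells spatial-cell data.frame.
#' @param genes CPA columns to use (default full panel).
#' @param k number of clusters to cut.
#' @return integer cluster labels named by cell id; attributes
#'   \code{hclust} (the dendrogram), \code{excluded} (zero-total cell ids).
#' @export
clusterMFISH <- function(cells, genes = mfishPanel, k = 2L) {
  genes <- intersect(genes, names(cells))
  M <- as.matrix(cells[, genes])
  tot <- rowSums(M)
  if (any(tot == 0))
    message("excluding ", sum(tot == 0), " cell(s) with zero total CPA")
  keep <- tot > 0
  Mn <- sweep(M[keep, , drop = FALSE], 1L, tot[keep], `/`)
  rownames(Mn) <- cells$cell_id[keep]
  hc <- hclust(dist(Mn, method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = k)
  names(labels) <- cells$cell_id[keep]
  attr(labels, "hclust") <- hc
  attr(labels, "excluded") <- cells$cell_id[!keep]
  labels
}

#' Histogram summary of phenotype indices
#'
#' Fixed-width histogram of the defined indices over [-1, 1] plus the
#' fraction with \code{|index| >= threshold} (the "extremeness" of the
#' bimodal structure).
#'
#' @param indices phenotype indices (NAs, i.e. undefined cells, dropped).
#' @param nBins histogram bins over [-1, 1].
#' @param threshold extremeness cutoff (default 0.9).
#' @return list: \code{breaks}, \code{counts}, \code{extremeFraction},
#'   \code{n}. Empty input gives zero counts and an NA fraction.
#' @export
bimodalitySummary <- function(indices, nBins = 20L, threshold = 0.9) {
  x <- indices[!is.na(indices)]
  breaks <- seq(-1, 1, length.out = nBins + 1L)
  counts <- if (length(x))
    tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE), nBins),
             nbins = nBins)
  else integer(nBins)
  list(breaks = breaks, counts = counts,
       extremeFraction = if (length(x)) mean(abs(x) >= threshold) else NA_real_,
       n = length(x))
}
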