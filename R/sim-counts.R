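#' Configuration for the synthetic scRNA-seq generator
#'
#' Defaults emulate the study conditions of the BLA excitatory-neuron dataset:
#' 1231 cells split 27/73 between two discrete populations (LA-like and
#' BA-like), 415 planted differentially expressed genes (half binary on/off,
#' half partially penetrant), a 1-D latent gradient within each population
#' driving a set of graded marker genes, negative-binomial counts, and
#' log-normal library sizes deep enough that ~5.9 thousand genes are detected
#' per cell.
#'
#' @param nCells number of cells.
#' @param propPop1 fraction of cells in population 1 (the smaller, LA-like
#'   population); must lie strictly inside (0, 1).
#' @param nGenes total number of genes (three gate genes \code{Snap25},
#'   \code{Slc17a7}, \code{Gad1} are included in this total).
#' @param nDEGenes number of planted discrete marker genes (0 gives the
#'   planted-null configuration when \code{nGradientGenesPerPop} is also 0).
#' @param fracOnOff fraction of DE genes that are binary on/off (mean ratio
#'   40x over a near-zero baseline); the remainder are partially penetrant,
#'   expressed in a Bernoulli subset of the enriched population.
#' @param nGradientGenesPerPop graded marker genes per population, modulated
#'   by the cell's latent coordinate u through a monotone logistic profile
#'   with gene-specific midpoint, width and amplitude.
#' @param depthMeanLog,depthSdLog log-normal library-size parameters.
#' @param nbDispersion negative-binomial size (inverse-dispersion) parameter,
#'   > 0.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return a validated list of class \code{ScSimConfig}.
#' @export
simCountConfig <- function(nCells = 1231L, propPop1 = 0.27, nGenes = 12000L,
                           nDEGenes = 415L, fracOnOff = 0.5,
                           nGradientGenesPerPop = 20L,
                           depthMeanLog = log(60000), depthSdLog = 0.35,
                           nbDispersion = 2, seed = 1L) {
  cfg <- list(nCells = as.integer(nCells), propPop1 = propPop1,
              nGenes = as.integer(nGenes), nDEGenes = as.integer(nDEGenes),
              fracOnOff = fracOnOff,
              nGradientGenesPerPop = as.integer(nGradientGenesPerPop),
              depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
              nbDispersion = nbDispersion, seed = as.integer(seed))
  if (!(cfg$propPop1 > 0 && cfg$propPop1 < 1))
    stop("propPop1 must lie strictly in (0, 1)")
  if (cfg$nDEGenes > cfg$nGenes) stop("nDEGenes must not exceed nGenes")
  if (cfg$nCells < 1L || cfg$nGenes < 1L) stop("nCells and nGenes must be >= 1")
  if (cfg$nDEGenes < 0L || cfg$nGradientGenesPerPop < 0L)
    stop("gene counts must be non-negative")
  if (!(cfg$nbDispersion > 0)) stop("nbDispersion must be positive")
  if (cfg$fracOnOff < 0 || cfg$fracOnOff > 1) stop("fracOnOff must be in [0, 1]")
  structure(cfg, class = "ScSimConfig")
}

# Target CPM of the three cell-class gate genes: all simulated cells are
# excitatory neurons, so Snap25/Slc17a7 are high and Gad1 absent.
.gateGeneCPM <- c(Snap25 = 1500, Slc17a7 = 800, Gad1 = 0)

#' Simulate a two-population scRNA-seq count matrix with planted structure
#'
#' Draws gene-wise negative-binomial counts whose means encode (i) two
#' discrete populations separated by \code{nDEGenes} planted markers and (ii)
#' a latent within-population gradient u in [0, 1] modulating graded markers.
#' Library sizes are log-normal. The generative truth (population labels, u,
#' planted gene sets) is returned alongside the counts so recovery can be
#' scored downstream.
#'
#' @param cfg a [simCountConfig()] object.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   \code{counts} (genes x cells, integer), \code{colData} columns
#'   \code{population} (factor \code{"pop1"}/\code{"pop2"}) and \code{u}, and
#'   the planted-gene truth in \code{metadata(sce)$truth}:
#'   \code{deGenes} (data.frame: gene, enrichedPop, type, cpmHigh),
#'   \code{gradientGenes} (named list of gene ids per population).
#' @examples
#' sce <- simCounts(simCountConfig(nCells = 60, nGenes = 500, nDEGenes = 20,
#'                                 seed = 7))
#' table(SummarizedExperiment::colData(sce)$population)
#' @export
simCounts <- function(cfg) {
  stopifnot(inherits(cfg, "ScSimConfig"))
  withSeed(cfg$seed, {
    nG <- cfg$nGenes; nC <- cfg$nCells
    gate <- .gateGeneCPM
    nGate <- length(gate)
    if (nG < nGate + cfg$nDEGenes + 2L * cfg$nGradientGenesPerPop)
      stop("nGenes too small for the requested planted gene sets")
    genes <- c(names(gate),
               sprintf("Gene%05d", seq_len(nG - nGate)))
    cells <- sprintf("cell%04d", seq_len(nC))

    ## population labels and latent gradient
    pop <- ifelse(runif(nC) < cfg$propPop1, 1L, 2L)
    u <- runif(nC)

    ## baseline relative abundance (heavy-tailed) for non-planted genes
    relBase <- rlnorm(nG, meanlog = 0, sdlog = 2.0)
    relBase[seq_len(nGate)] <- 0          # gate genes set from CPM targets

    ## planted gene assignment (indices into `genes`, skipping gate genes)
    pool <- sample((nGate + 1L):nG)
    deIdx <- pool[seq_len(cfg$nDEGenes)]
    gradIdx1 <- gradIdx2 <- integer(0)
    if (cfg$nGradientGenesPerPop > 0) {
      off <- cfg$nDEGenes
      gradIdx1 <- pool[off + seq_len(cfg$nGradientGenesPerPop)]
      gradIdx2 <- pool[off + cfg$nGradientGenesPerPop +
                         seq_len(cfg$nGradientGenesPerPop)]
    }

    ## per-population target CPM for planted genes
    cpm1 <- cpm2 <- rep(NA_real_, nG)      # NA = baseline gene
    deType <- character(0); deHigh <- numeric(0); dePop <- integer(0)
    penetrance <- rep(NA_real_, nG)
    if (cfg$nDEGenes > 0) {
      nOn <- round(cfg$fracOnOff * cfg$nDEGenes)
      deType <- rep(c("onoff", "penetrant"),
                    c(nOn, cfg$nDEGenes - nOn))[sample(cfg$nDEGenes)]
      dePop <- rep_len(c(1L, 2L), cfg$nDEGenes)
      deHigh <- exp(runif(cfg$nDEGenes, log(6), log(18)))
      lo <- deHigh / 40
      cpm1[deIdx] <- ifelse(dePop == 1L, deHigh, lo)
      cpm2[deIdx] <- ifelse(dePop == 2L, deHigh, lo)
      penetrance[deIdx] <- ifelse(deType == "penetrant",
                                  runif(cfg$nDEGenes, 0.4, 0.7), 1)
    }
    gradBase <- gradAmp <- gradMid <- gradWidth <- rep(NA_real_, nG)
    gIdx <- c(gradIdx1, gradIdx2)
    if (length(gIdx)) {
      gradBase[gIdx] <- exp(runif(length(gIdx), log(30), log(80)))
      gradAmp[gIdx] <- sample(c(-1, 1), length(gIdx), TRUE) *
        runif(length(gIdx), 1.2, 2.0)
      gradMid[gIdx] <- runif(length(gIdx), 0.25, 0.75)
      gradWidth[gIdx] <- runif(length(gIdx), 0.10, 0.20)
      # both populations share the gene's mean level; only the home
      # population's cells are modulated by u around that level
      meanMult <- vapply(gIdx, function(g) {
        uu <- seq(0.005, 0.995, by = 0.01)
        mean(exp(gradAmp[g] * (logistic((uu - gradMid[g]) / gradWidth[g]) - 0.5)))
      }, numeric(1))
      cpm1[gIdx] <- cpm2[gIdx] <- gradBase[gIdx] * meanMult
    }

    ## assemble per-cell relative-expression matrix
    planted <- which(!is.na(cpm1))
    baseRel <- relBase / sum(relBase)
    budget <- 1 - sum(gate) / 1e6 - sum(cpm1[planted] + cpm2[planted]) / 2e6
    rel1 <- rel2 <- baseRel * budget
    rel1[seq_len(nGate)] <- rel2[seq_len(nGate)] <- gate / 1e6
    rel1[planted] <- cpm1[planted] / 1e6
    rel2[planted] <- cpm2[planted] / 1e6

    R <- matrix(0, nG, nC, dimnames = list(genes, cells))
    R[, pop == 1L] <- rel1
    R[, pop == 2L] <- rel2
    ## penetrant DE genes: only a Bernoulli subset of the enriched population
    ## expresses the high level, the rest sit at baseline
    if (cfg$nDEGenes > 0) {
      pen <- deIdx[deType == "penetrant"]
      for (g in pen) {
        hi <- max(cpm1[g], cpm2[g]); lo <- min(cpm1[g], cpm2[g])
        enr <- which(pop == (if (cpm1[g] > cpm2[g]) 1L else 2L))
        silent <- enr[runif(length(enr)) > penetrance[g]]
        R[g, silent] <- lo / 1e6
      }
    }
    ## gradient modulation within the home population
    for (g in gradIdx1) {
      h <- which(pop == 1L)
      R[g, h] <- gradBase[g] / 1e6 *
        exp(gradAmp[g] * (logistic((u[h] - gradMid[g]) / gradWidth[g]) - 0.5))
    }
    for (g in gradIdx2) {
      h <- which(pop == 2L)
      R[g, h] <- gradBase[g] / 1e6 *
        exp(gradAmp[g] * (logistic((u[h] - gradMid[g]) / gradWidth[g]) - 0.5))
    }

    depth <- rlnorm(nC, cfg$depthMeanLog, cfg$depthSdLog)
    M <- sweep(R, 2L, depth / colSums(R), `*`)
    counts <- matrix(rnbinom(length(M), size = cfg$nbDispersion, mu = M),
                     nG, nC, dimnames = dimnames(M))
    ## gate genes behave like stable housekeeping markers: same means, much
    ## lower biological dispersion, so class gating reflects class not noise
    gi <- seq_len(nGate)
    counts[gi, ] <- rnbinom(length(gi) * nC, size = 20, mu = M[gi, ])
    storage.mode(counts) <- "integer"

    truth <- list(
      deGenes = if (cfg$nDEGenes > 0)
        data.frame(gene = genes[deIdx], enrichedPop = paste0("pop", dePop),
                   type = deType, cpmHigh = deHigh,
                   penetrance = penetrance[deIdx], row.names = NULL)
      else data.frame(gene = character(0), enrichedPop = character(0),
                      type = character(0), cpmHigh = numeric(0),
                      penetrance = numeric(0)),
      gradientGenes = list(pop1 = genes[gradIdx1], pop2 = genes[gradIdx2]),
      config = cfg
    )
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        population = factor(paste0("pop", pop), levels = c("pop1", "pop2")),
        u = u, row.names = cells)
    )
    S4Vectors::metadata(sce)$truth <- truth
    sce
  })
}
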