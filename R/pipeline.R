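#' Full-pipeline run configuration
#'
#' Every stage threshold of the pipeline, defaulting to its printed study
#' value: QC at 10,000 counts, Snap25/Gad1 gates at 250/100 CPM,
#' variable-gene cutoffs 0.125/3/1, 10 PCs, SNN k = 20 with 1/15 pruning,
#' coarse resolution 0.2, Bonferroni alpha 0.05, the
#' 50/100/200/400/800-cell x 100-replicate forest experiment, the 0.004 CPA
#' Slc17a7 gate, 100-um correlation bins, and 1000 Monte-Carlo iterations.
#' Unknown keys are rejected. Synthetic-generator settings are taken from
#' [simCountConfig()] / [simSpatialConfig()] defaults unless overridden via
#' \code{sc} / \code{spatial}.
#'
#' @param ... overrides, e.g. \code{minCounts = 0},
#'   \code{sc = list(nCells = 200)}, \code{rfGrid = 100}.
#' @param seed top-level seed; per-stage child seeds are derived from it
#'   deterministically.
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    sc = list(), spatial = list(),
    minCounts = 10000, neuronalMin = 250, inhMax = 100,
    xLow = 0.125, xHigh = 3, yCutoff = 1,
    nPcs = 10L, k = 20L, prune = 1 / 15,
    resolution = 0.2, fineResolution = 0.8,
    alpha = 0.05,
    rfGrid = c(50L, 100L, 200L, 400L, 800L), rfReps = 100L, rfTrees = 500L,
    gateCpa = 0.004, binWidth = 100, nProfileSeeds = 50L,
    nIter = 1000L,
    projection = list(n = 60L, region = "BA", center = c(0, 800),
                      spread = 120)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Run the full synthetic-data pipeline end to end
#'
#' simulate counts -> QC -> CPM -> class gating -> variable genes -> PCA ->
#' coarse clustering -> differential expression -> random-forest stability;
#' simulate spatial tables -> phenotype index/binarization -> correlation
#' profiles -> Ward clustering; simulate a projection subset -> enrichment
#' and distance-restriction nulls -> area comparison. Returns (and
#' optionally writes) a structured report containing every headline metric,
#' the resolved configuration and all derived seeds; a second run with the
#' same config is byte-identical.
#'
#' @param config a [runConfig()] object.
#' @param outDir optional directory; when given, \code{report.json},
#'   \code{labels.tsv}, \code{de_results.tsv}, \code{rf_results.tsv} and
#'   \code{spatial_cells.tsv} are written there.
#' @param stages character subset of
#'   \code{c("scrnaseq", "spatial", "projections")} to run.
#' @return the report, a nested list.
#' @export
runAll <- function(config = runConfig(), outDir = NULL,
                   stages = c("scrnaseq", "spatial", "projections")) {
  stopifnot(inherits(config, "RunConfig"))
  report <- list(provenance = list(
    package = as.character(utils::packageVersion("blamap")),
    seed = config$seed,
    config = unclass(config),
    configHash = .hashConfig(config)
  ))
  artifacts <- list()

  if ("scrnaseq" %in% stages) {
    scCfg <- do.call(simCountConfig,
                     c(config$sc,
                       list(seed = childSeed(config$seed, "simulate"))))
    sce <- simCounts(scCfg)
    sce <- qcFilter(sce, minCounts = config$minCounts)
    sce <- computeCPM(sce)
    classes <- gateCellClasses(sce, neuronalMin = config$neuronalMin,
                               inhMax = config$inhMax)
    exc <- sce[, classes == "excitatory"]
    vg <- selectVariableGenes(exc, xLow = config$xLow, xHigh = config$xHigh,
                              yCutoff = config$yCutoff)
    scores <- pcaEmbed(exc, vg, nPcs = config$nPcs)
    labels <- clusterGraph(scores, resolution = config$resolution,
                           k = config$k, prune = config$prune,
                           seed = childSeed(config$seed, "cluster"))
    twoPlus <- attr(labels, "nClusters") >= 2L
    de <- if (twoPlus)
      differentialExpression(exc, labels, 0L, 1L, alpha = config$alpha)
    rf <- if (twoPlus)
      rfSubsampleExperiment(exc, labels, vg, nTrainGrid = config$rfGrid,
                            nReps = config$rfReps, nTrees = config$rfTrees,
                            seed = childSeed(config$seed, "rf"))
    sizes <- table(labels)
    rfSummary <- if (twoPlus)
      stats::aggregate(accuracy ~ nTrain, rf$results, mean)
    report$scrnaseq <- list(
      nCellsSimulated = scCfg$nCells,
      qc = metadata(sce)$qcFilter[c("minCounts", "nRemoved")],
      cellClasses = as.list(table(classes)),
      nVariableGenes = length(vg),
      nClusters = attr(labels, "nClusters"),
      clusterSizes = as.list(sizes),
      smallerClusterFraction = as.numeric(min(sizes) / sum(sizes)),
      nDESignificant = if (twoPlus) sum(de$significant) else NA_integer_,
      nDETested = if (twoPlus) attr(de, "nTested") else NA_integer_,
      rfMeanAccuracy = if (twoPlus)
        setNames(as.list(rfSummary$accuracy), rfSummary$nTrain),
      rfRedraws = if (twoPlus) rf$redraws else NA_integer_
    )
    artifacts$labels <- data.frame(cell = names(labels), cluster = labels)
    artifacts$de <- de
    artifacts$rf <- if (twoPlus) rf$results
  }

  if ("spatial" %in% stages) {
    spCfg <- do.call(simSpatialConfig,
                     c(config$spatial,
                       list(seed = childSeed(config$seed, "spatial"))))
    cells <- simSpatialCells(spCfg)
    cells <- binarizePhenotype(cells, gateCpa = config$gateCpa)
    idx <- phenotypeIndex(cells)
    bim <- bimodalitySummary(idx)
    phen <- cells[cells$phenotype != "none", ]
    seedIds <- withSeed(childSeed(config$seed, "profiles"),
      sample(phen$cell_id, min(config$nProfileSeeds, nrow(phen))))
    maxD <- ceiling(max(vapply(split(phen, phen$section), function(s)
      max(dist(s[, c("x_um", "y_um")])), numeric(1))) / config$binWidth) *
      config$binWidth
    profs <- lapply(seedIds, function(s)
      correlationProfile(s, phen, binWidth = config$binWidth, maxDist = maxD))
    agg <- aggregateProfiles(profs)
    st <- profileStats(agg)
    near <- st[st$bin == 0, ]
    ward <- clusterMFISH(phen, k = 2L)
    report$spatial <- list(
      nCells = nrow(cells), nPhenotyped = nrow(phen),
      phenotypeCounts = as.list(table(cells$phenotype)),
      extremeIndexFraction = bim$extremeFraction,
      nearestBinSameR = near$mean_r[near$class == "same"],
      nearestBinOppositeR = near$mean_r[near$class == "opposite"],
      wardClusterSizes = as.list(table(ward))
    )
    artifacts$spatial <- cells
    artifacts$profile <- agg
  }

  if ("projections" %in% stages) {
    tpl <- blaTemplate("intermediate")
    pj <- config$projection
    obs <- simProjectionCells(tpl, region = pj$region, center = pj$center,
                              spread = pj$spread, n = pj$n,
                              seed = childSeed(config$seed, "projection"))
    poolLA <- simProjectionCells(tpl, "LA", center = c(0, 300), spread = Inf,
                                 n = 400L,
                                 seed = childSeed(config$seed, "poolLA"))
    poolBA <- simProjectionCells(tpl, "BA", center = c(0, 800), spread = Inf,
                                 n = 600L,
                                 seed = childSeed(config$seed, "poolBA"))
    pool <- rbind(poolLA, poolBA)
    enr <- mcEnrichment(obs, pool, nIter = config$nIter,
                        seed = childSeed(config$seed, "mc"))
    restr <- mcDistanceRestriction(obs, pool[pool$region == "BA", ],
                                   nIter = config$nIter,
                                   seed = childSeed(config$seed, "restrict"))
    areas <- areaCompare(list(LA = poolLA$area_um2, BA = poolBA$area_um2))
    report$projections <- list(
      n = nrow(obs), observedLACount = sum(obs$region == "LA"),
      enrichmentCI = nullCI(enr), enrichmentP = nullPValue(enr),
      enriched = enr@enriched,
      restrictionObserved = restr@observed,
      restrictionP = nullPValue(restr),
      areaComparisonP = areas$p
    )
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(artifacts$labels))
      write.table(artifacts$labels, file.path(outDir, "labels.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(artifacts$de))
      write.table(artifacts$de, file.path(outDir, "de_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(artifacts$rf))
      write.table(artifacts$rf, file.path(outDir, "rf_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(artifacts$spatial))
      writeSpatialCells(artifacts$spatial,
                        file.path(outDir, "spatial_cells.tsv"))
  }
  report
}

.hashConfig <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(f))
}
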