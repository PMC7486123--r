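mkSCE <- function(counts, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

test_that("QC filtering uses a strict lower bound on total counts", {
  m <- matrix(0L, 2, 3)
  m[1, ] <- c(9999L, 10000L, 20000L)
  sce <- mkSCE(m)
  out <- qcFilter(sce)
  expect_identical(colnames(out), c("c02", "c03"))   # 9,999 excluded, 10,000 kept
  rep <- S4Vectors::metadata(out)$qcFilter
  expect_identical(rep$nRemoved, 1L)
  expect_identical(rep$removed, "c01")

  # empty matrix passes through with a zero-row report
  empty <- qcFilter(mkSCE(matrix(0L, 2, 0)))
  expect_identical(ncol(empty), 0L)
  expect_identical(S4Vectors::metadata(empty)$qcFilter$nRemoved, 0L)

  expect_warning(qcFilter(mkSCE(matrix(1L, 2, 2))), "every cell")
})

test_that("CPM normalization is exact and errors on zero-total cells", {
  m <- matrix(c(10L, 99990L, 0L, 50L, 150L, 0L), 3, 2)
  sce <- computeCPM(mkSCE(m))
  cpm <- SummarizedExperiment::assay(sce, "cpm")
  expect_equal(cpm[1, 1], 100)                      # 10 of 100,000
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_true(all(cpm[3, ] == 0))                   # all-zero gene
  expect_equal(SummarizedExperiment::assay(sce, "logcpm"), log1p(cpm))
  expect_error(computeCPM(mkSCE(cbind(m, c(0L, 0L, 0L)))), "zero total")
})

test_that("cell-class gates use the printed strict inequalities", {
  cpmTargets <- rbind(Snap25 = c(249, 300, 300, 251),
                      Gad1 = c(0, 150, 100, 101))
  counts <- round(sweep(rbind(cpmTargets, other = 1e6 - colSums(cpmTargets)),
                        2, 1, `*`))
  storage.mode(counts) <- "integer"
  sce <- computeCPM(mkSCE(counts, genes = c("Snap25", "Gad1", "other")))
  cls <- gateCellClasses(sce)
  expect_identical(as.character(cls),
                   c("non_neuronal",    # Snap25 249 < 250
                     "interneuron",     # Gad1 150 > 100
                     "excitatory",      # Gad1 exactly 100 stays excitatory
                     "interneuron"))
  expect_error(gateCellClasses(sce, neuronalGene = "Missing"), "Missing")
})

test_that("variable-gene statistics match a hand computation on a toy", {
  # 3 genes x 6 cells of CPM; gene v is overdispersed, gene f flat,
  # gene z constant (undefined dispersion -> excluded)
  cpm <- rbind(v = c(0, 0, 40, 0, 0, 44),
               f = c(12, 14, 13, 15, 14, 12),
               z = rep(5, 6))
  colnames(cpm) <- sprintf("c%02d", 1:6)
  counts <- matrix(1L, 3, 6)
  sce <- mkSCE(counts, genes = rownames(cpm))
  SummarizedExperiment::assay(sce, "cpm") <- cpm
  SummarizedExperiment::assay(sce, "logcpm") <- log1p(cpm)

  # oracle: direct formulas, one bin
  mu <- rowMeans(cpm)
  disp <- log(apply(cpm, 1, var) / mu)
  z <- (disp[1:2] - mean(disp[1:2])) / sd(disp[1:2])
  expect_gt(z[["v"]], 0.7)   # sanity of the hand computation itself

  got <- selectVariableGenes(sce, xLow = 0, xHigh = 10, yCutoff = 0.7,
                             nBins = 1)
  expect_identical(as.character(got), "v")
  expect_identical(attr(got, "excluded"), "z")
  st <- attr(got, "stats")
  expect_equal(st$mean, log(mu + 1), ignore_attr = TRUE)
  expect_equal(st$dispersion[1:2], unname(disp[1:2]))
})

test_that("PCA embedding separates planted blobs and fixes signs", {
  blobs <- makeBlobs(30, rbind(c(0, 0, 0, 0), c(8, 8, 0, 0)), sd = 1,
                     seed = 12)
  lg <- t(cbind(blobs$x, matrix(rnorm(60 * 6, sd = 0.5), 60)))
  rownames(lg) <- sprintf("g%02d", 1:10)
  colnames(lg) <- sprintf("c%02d", 1:60)
  sc <- pcaEmbed(lg, rownames(lg), nPcs = 4)
  # PC1 separates the blobs with AUC ~ 1
  r <- rank(sc[, 1])
  auc <- (sum(r[blobs$label == 2]) - 30 * 31 / 2) / (30 * 30)
  expect_gt(max(auc, 1 - auc), 0.99)
  expect_true(all(diff(attr(sc, "varExplained")) <= 1e-12))

  # duplicate cells give identical score rows
  lg2 <- cbind(lg, dup = lg[, 1])
  sc2 <- pcaEmbed(lg2, rownames(lg), nPcs = 3)
  expect_equal(unname(sc2["dup", ]), unname(sc2[1, ]))

  expect_warning(pcaEmbed(lg, rownames(lg), nPcs = 50), "clipped")
})

test_that("graph clustering recovers blob structure and is permutation-stable", {
  blobs <- makeBlobs(60, rbind(c(0, 0), c(12, 12)), sd = 1, seed = 5)
  sc <- cbind(blobs$x, matrix(rnorm(120 * 8, sd = 0.3), 120))
  rownames(sc) <- sprintf("c%03d", 1:120)
  lab <- clusterGraph(sc, resolution = 0.2, k = 15, seed = 2)
  expect_identical(attr(lab, "nClusters"), 2L)
  expect_equal(ari(lab, blobs$label), 1)

  # one homogeneous blob: a single cluster at coarse resolution
  one <- matrix(rnorm(80 * 5), 80)
  rownames(one) <- sprintf("c%03d", 1:80)
  lab1 <- clusterGraph(one, resolution = 0.2, k = 15, seed = 2)
  expect_identical(attr(lab1, "nClusters"), 1L)

  # permuting the input cells permutes the labels identically
  perm <- withr::with_seed(1, sample(120))
  labP <- clusterGraph(sc[perm, ], resolution = 0.2, k = 15, seed = 2)
  expect_equal(ari(labP, lab[perm]), 1)

  expect_warning(clusterGraph(sc[1:10, ], k = 20, seed = 1), "clipped")
})

test_that("differential expression matches the exact enumeration oracle", {
  # 6-vs-6 toy, one clearly shifted gene
  set.seed(31)
  counts <- matrix(rpois(20 * 12, 40), 20, 12)
  counts[7, 1:6] <- counts[7, 1:6] + 60L
  storage.mode(counts) <- "integer"
  sce <- computeCPM(mkSCE(counts))
  lab <- rep(c(0L, 1L), each = 6)
  de <- differentialExpression(sce, lab, 0L, 1L)
  lg <- SummarizedExperiment::assay(sce, "logcpm")
  for (g in c("g07", "g01", "g13")) {
    expected <- enumRankSumP(lg[g, 1:6], lg[g, 7:12])
    expect_equal(de$p[de$gene == g], expected, tolerance = 1e-12)
  }
  expect_identical(de$enrichedCluster[de$gene == "g07"], 0L)
  # Bonferroni arithmetic over the tested genes
  expect_equal(de$pAdj, pmin(1, de$p * attr(de, "nTested")))

  expect_error(differentialExpression(sce, lab, 0L, 2L), "non-empty")
  expect_error(differentialExpression(sce, c(rep(0L, 2), rep(1L, 10)),
                                      0L, 1L), "fewer than 3")
})

test_that("random-forest experiment is perfect on separable data, chance on shuffled", {
  set.seed(8)
  n <- 120
  lab <- rep(c(0L, 1L), each = n / 2)
  counts <- matrix(rpois(30 * n, 20), 30, n)
  counts[1:5, lab == 0] <- 0L     # disjoint marker support
  counts[6:10, lab == 1] <- 0L
  storage.mode(counts) <- "integer"
  sce <- computeCPM(mkSCE(counts, cells = sprintf("c%03d", 1:n)))
  rf <- rfSubsampleExperiment(sce, lab, rownames(sce)[1:10],
                              nTrainGrid = 30L, nReps = 5L, seed = 4)
  expect_equal(mean(rf$results$accuracy), 1)

  shuf <- withr::with_seed(5, sample(lab))
  rf2 <- rfSubsampleExperiment(sce, shuf, rownames(sce)[1:10],
                               nTrainGrid = 30L, nReps = 8L, seed = 4)
  expect_lt(abs(mean(rf2$results$accuracy) - 0.5), 0.12)

  expect_error(rfSubsampleExperiment(sce, lab, rownames(sce)[1:10],
                                     nTrainGrid = 200L, seed = 1),
               "smaller")
})

test_that("2-D embedding is seeded, separates blobs, and validates perplexity", {
  blobs <- makeBlobs(25, rbind(c(0, 0, 0), c(10, 10, 0)), sd = 1, seed = 3)
  sc <- blobs$x
  rownames(sc) <- sprintf("c%02d", 1:50)
  y1 <- embed2D(sc, "tsne", perplexity = 8, maxIter = 250, seed = 11)
  y2 <- embed2D(sc, "tsne", perplexity = 8, maxIter = 250, seed = 11)
  expect_identical(y1, y2)
  within <- mean(dist(y1[blobs$label == 1, ])) +
    mean(dist(y1[blobs$label == 2, ]))
  across <- mean(as.matrix(dist(y1))[blobs$label == 1, blobs$label == 2])
  expect_gt(across, within / 2)
  expect_error(embed2D(sc, "tsne", perplexity = 20), "perplexity")

  # pca method maps duplicate inputs identically
  scd <- rbind(sc, dup = sc[1, ])
  yp <- embed2D(scd, "pca")
  expect_identical(unname(yp["dup", ]), unname(yp[1, ]))
})
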