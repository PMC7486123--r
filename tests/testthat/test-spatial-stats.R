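test_that("phenotype index matches its definition and symmetries", {
  df <- data.frame(Negr1 = c(5, 0, 3, 0), Cplx1 = c(0, 7, 3, 0))
  idx <- phenotypeIndex(df)
  expect_identical(idx, c(-1, 1, 0, NA))

  # antisymmetry under gene swap and scale invariance, over random cells
  set.seed(2)
  rnd <- data.frame(Negr1 = runif(50), Cplx1 = runif(50))
  expect_equal(phenotypeIndex(rnd),
               -phenotypeIndex(rnd, geneA = "Cplx1", geneB = "Negr1"))
  scaled <- rnd * 3.7
  expect_equal(phenotypeIndex(rnd), phenotypeIndex(scaled))

  expect_error(phenotypeIndex(data.frame(Negr1 = 1)), "Cplx1")
})

test_that("winner-take-all binarization gates on Slc17a7 and breaks ties to CPLX1", {
  df <- data.frame(cell_id = paste0("c", 1:5),
                   Slc17a7 = c(0.003, 0.004, 0.02, 0.02, 0.02),
                   Negr1 = c(1, 0.2, 0.1, 0.3, 0),
                   Cplx1 = c(0, 0.1, 0.1, 0.3, 0))
  out <- binarizePhenotype(df)
  expect_identical(nrow(out), 4L)                 # 0.003 < 0.004 removed
  expect_identical(attr(out, "nGatedOut"), 1L)
  expect_identical(as.character(out$phenotype),
                   c("NEGR1",      # argmax Negr1
                     "CPLX1",      # nonzero tie -> CPLX1
                     "CPLX1",      # nonzero tie -> CPLX1
                     "none"))      # both zero
  expect_identical(attr(out, "ties"), 2L)
})

test_that("binarized phenotypes equal generator truth at a hard border", {
  cells <- simSpatialCells(simSpatialConfig(
    templates = list(blaTemplate("intermediate")),
    nCellsPerSection = 400, borderSharpness = Inf, spilloverRate = 0,
    seed = 13))
  ph <- binarizePhenotype(cells)
  called <- ph[ph$phenotype != "none", ]
  expect_equal(mean((called$phenotype == "NEGR1") ==
                      (called$true_region == "LA")), 1)
})

test_that("correlation profiles use exact Pearson r and half-open 100-um bins", {
  panel <- c("a", "b", "c", "d")
  seedV <- c(1, 3, 2, 5)
  cells <- data.frame(cell_id = c("s", "same", "anti", "far"),
                      section = "intermediate",
                      x_um = c(0, 30, 60, 250), y_um = 0,
                      rbind(seedV, seedV,
                            2 * mean(seedV) - seedV,   # negated deviations
                            c(2, 2, 9, 1)),
                      phenotype = factor(c("NEGR1", "NEGR1", "NEGR1", "CPLX1"),
                                         levels = c("NEGR1", "CPLX1", "none")))
  names(cells)[5:8] <- panel
  pr <- correlationProfile("s", cells, genes = panel, binWidth = 100)
  st <- profileStats(pr)
  b0same <- st[st$bin == 0 & st$class == "same", ]
  expect_equal(b0same$n, 2L)
  # mean of r=+1 (identical) and r=-1 (mirror) is 0
  expect_equal(b0same$mean_r, 0, tolerance = 1e-12)
  # far cell: closed-form Pearson oracle, bin [200, 300)
  rOracle <- sum((seedV - mean(seedV)) * (c(2, 2, 9, 1) - mean(c(2, 2, 9, 1)))) /
    sqrt(sum((seedV - mean(seedV))^2) * sum((c(2, 2, 9, 1) - mean(c(2, 2, 9, 1)))^2))
  b2opp <- st[st$bin == 200 & st$class == "opposite", ]
  expect_equal(b2opp$mean_r, rOracle, tolerance = 1e-12)

  flat <- cells; flat[1, panel] <- 2
  expect_error(correlationProfile("s", flat, genes = panel), "zero variance")
})

test_that("profile aggregation pools means with across-seed dispersion", {
  panel <- c("a", "b", "c")
  set.seed(4)
  cells <- data.frame(cell_id = sprintf("c%02d", 1:30),
                      section = "anterior",
                      x_um = runif(30, 0, 350), y_um = runif(30, 0, 50),
                      matrix(runif(90), 30, dimnames = list(NULL, panel)),
                      phenotype = factor(sample(c("NEGR1", "CPLX1"), 30, TRUE),
                                         levels = c("NEGR1", "CPLX1", "none")))
  p1 <- correlationProfile("c01", cells, genes = panel, maxDist = 500)
  p2 <- correlationProfile("c02", cells, genes = panel, maxDist = 500)

  one <- aggregateProfiles(list(p1))
  s1 <- profileStats(p1); sA <- profileStats(one)
  nonEmpty <- !is.na(s1$mean_r)
  expect_equal(sA$mean_r[nonEmpty], s1$mean_r[nonEmpty])
  expect_true(all(sA$sd_r[nonEmpty] == 0))

  twin <- aggregateProfiles(list(p1, p1))
  sT <- profileStats(twin)
  expect_true(all(sT$sd_r[!is.na(sT$sd_r) & sT$n > 0] == 0))

  both <- aggregateProfiles(list(p1, p2))
  sB <- profileStats(both)
  expect_true(all(sB$mean_r >= -1 & sB$mean_r <= 1, na.rm = TRUE))

  p3 <- correlationProfile("c03", cells, genes = panel, maxDist = 900)
  expect_error(aggregateProfiles(list(p1, p3)), "inconsistent")
})

test_that("Ward-D2 clustering of sum-normalized CPA matches the naive oracle", {
  df <- data.frame(cell_id = paste0("c", 1:6),
                   g1 = c(10, 9, 6, 1, 0.5, 5),
                   g2 = c(0.5, 1, 4, 9, 10, 5),
                   g3 = c(2, 2.2, 3, 2, 1.8, 8))
  lab <- clusterMFISH(df, genes = c("g1", "g2", "g3"), k = 2)
  M <- as.matrix(df[, 2:4]); Mn <- sweep(M, 1, rowSums(M), `/`)
  expect_equal(unname(rowSums(Mn)), rep(1, 6))

  oracle <- naiveWardMerges(Mn)
  got <- hclustPartitions(attr(lab, "hclust"))
  for (s in seq_along(oracle))
    expect_true(samePartition(oracle[[s]], got[[s]]))

  # duplicated point-masses split perfectly at k = 2
  pm <- data.frame(cell_id = paste0("p", 1:8),
                   g1 = rep(c(1, 0), each = 4), g2 = rep(c(0, 1), each = 4))
  labPM <- clusterMFISH(pm, genes = c("g1", "g2"), k = 2)
  expect_equal(ari(labPM, rep(1:2, each = 4)), 1)

  zero <- rbind(df, data.frame(cell_id = "z", g1 = 0, g2 = 0, g3 = 0))
  expect_message(labZ <- clusterMFISH(zero, genes = c("g1", "g2", "g3"), k = 2),
                 "zero total")
  expect_identical(attr(labZ, "excluded"), "z")
})

test_that("bimodality summary matches the analytic uniform integral", {
  all1 <- bimodalitySummary(c(-1, 1, 1, -1))
  expect_equal(all1$extremeFraction, 1)

  set.seed(6)
  unif <- bimodalitySummary(runif(20000, -1, 1), threshold = 0.9)
  expect_lt(abs(unif$extremeFraction - 0.1), 0.01)   # P(|U| >= 0.9) = 0.1

  empty <- bimodalitySummary(numeric(0))
  expect_identical(empty$n, 0L)
  expect_true(all(empty$counts == 0))
  expect_true(is.na(empty$extremeFraction) && !is.nan(empty$extremeFraction))
  expect_identical(sum(bimodalitySummary(c(NA, 0.5))$counts), 1L)
})
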