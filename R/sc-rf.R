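#' Random-forest subsample classification experiment
#'
#' How stable is the discrete cluster structure? For each training size n and
#' each replicate, a random forest (500 trees) is trained on the
#' log-expression of the variable genes for n randomly drawn cells and
#' predicts the cluster identities of all remaining cells. A draw missing one
#' of the classes is redrawn (and counted). Held-out accuracy per replicate
#' and per-cell misclassification rates across replicates are returned.
#'
#' @param sce object with a \code{logcpm} assay.
#' @param labels cluster labels aligned with the cells.
#' @param genes feature genes (typically [selectVariableGenes()] output).
#' @param nTrainGrid training-set sizes (each must be < nCells).
#' @param nReps replicates per size.
#' @param nTrees trees per forest.
#' @param seed integer seed.
#' @return list: \code{results} (data.frame nTrain, rep, accuracy),
#'   \code{perCell} (cells x sizes matrix of misclassification rates),
#'   \code{redraws} (count of class-deficient draws).
#' @export
rfSubsampleExperiment <- function(sce, labels, genes,
                                  nTrainGrid = c(50L, 100L, 200L, 400L, 800L),
                                  nReps = 100L, nTrees = 500L, seed = 1L) {
  x <- t(assay(sce, "logcpm")[genes, , drop = FALSE])
  y <- factor(labels)
  n <- nrow(x)
  if (any(nTrainGrid >= n))
    stop("every training size must be smaller than the number of cells")
  withSeed(seed, {
    redraws <- 0L
    results <- list()
    perCell <- matrix(0, n, length(nTrainGrid),
                      dimnames = list(rownames(x), as.character(nTrainGrid)))
    heldOutN <- matrix(0, n, length(nTrainGrid))
    for (gi in seq_along(nTrainGrid)) {
      nt <- nTrainGrid[gi]
      acc <- numeric(nReps)
      for (r in seq_len(nReps)) {
        repeat {
          tr <- sample.int(n, nt)
          if (nlevels(droplevels(y[tr])) == nlevels(y)) break
          redraws <- redraws + 1L
        }
        fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                          ntree = nTrees)
        te <- setdiff(seq_len(n), tr)
        pred <- predict(fit, x[te, , drop = FALSE])
        wrong <- pred != y[te]
        acc[r] <- 1 - mean(wrong)
        perCell[te, gi] <- perCell[te, gi] + wrong
        heldOutN[te, gi] <- heldOutN[te, gi] + 1
      }
      results[[gi]] <- data.frame(nTrain = nt, rep = seq_len(nReps),
                                  accuracy = acc)
    }
    perCell <- ifelse(heldOutN > 0, perCell / heldOutN, NA_real_)
    list(results = do.call(rbind, results), perCell = perCell,
         redraws = redraws)
  })
}
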