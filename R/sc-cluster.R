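#' Shared-nearest-neighbour Louvain clustering in PC space
#'
#' Builds the k-nearest-neighbour graph (Euclidean, neighbour sets include
#' the cell itself), weights each edge by the Jaccard overlap of the two
#' neighbour sets, prunes weights below \code{prune} (default 1/15), and
#' maximizes modularity with the Louvain algorithm at the given resolution.
#' Resolution 0.2 recovers the coarse discrete structure; 0.8 probes
#' finer-scale heterogeneity.
#'
#' @param scores cells x PCs matrix from [pcaEmbed()].
#' @param resolution Louvain resolution parameter.
#' @param k neighbours per cell (clipped with a warning when fewer cells).
#' @param dims which PC columns to use (default 1:10, clipped to available).
#' @param prune SNN Jaccard pruning threshold.
#' @param seed seed for the Louvain pass.
#' @return integer vector of 0-based labels (0 = largest cluster), named by
#'   cell; attributes \code{resolution}, \code{k}, \code{dims},
#'   \code{nClusters}.
#' @export
clusterGraph <- function(scores, resolution = 0.2, k = 20L, dims = 1:10,
                         prune = 1 / 15, seed = 1L) {
  dims <- dims[dims <= ncol(scores)]
  x <- scores[, dims, drop = FALSE]
  n <- nrow(x)
  if (k > n) {
    warning("k clipped from ", k, " to ", n)
    k <- n
  }
  d <- as.matrix(dist(x))
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))  # includes self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)                 # shared-neighbour counts
  J <- S
  J@x <- J@x / (2 * k - J@x)                 # Jaccard: s / (|A| + |B| - s)
  J@x[J@x < prune] <- 0
  J <- Matrix::drop0(J)
  Matrix::diag(J) <- 0
  g <- igraph::graph_from_adjacency_matrix(J, mode = "undirected",
                                           weighted = TRUE)
  memb <- withSeed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  sizes <- sort(table(memb), decreasing = TRUE)
  labels <- match(as.character(memb), names(sizes)) - 1L
  names(labels) <- rownames(scores)
  attr(labels, "resolution") <- resolution
  attr(labels, "k") <- k
  attr(labels, "dims") <- dims
  attr(labels, "nClusters") <- length(sizes)
  labels
}

#' 2-D embedding of PC scores (visualization plumbing)
#'
#' Either the first two principal-component columns (\code{method = "pca"})
#' or a minimal exact t-SNE (\code{method = "tsne"}): perplexity-calibrated
#' Gaussian affinities, early exaggeration, momentum gradient descent.
#' Intended for plots only; no quantitative claims are made about the
#' embedding geometry.
#'
#' @param scores cells x PCs matrix.
#' @param method \code{"tsne"} or \code{"pca"}.
#' @param perplexity t-SNE perplexity; must be < nCells / 3.
#' @param maxIter gradient-descent iterations.
#' @param seed seed for the random initialization.
#' @return cells x 2 coordinate matrix.
#' @export
embed2D <- function(scores, method = c("tsne", "pca"), perplexity = 30,
                    maxIter = 500L, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(scores)
  if (method == "pca") return(scores[, 1:2, drop = FALSE])
  if (perplexity >= n / 3)
    stop("perplexity must be smaller than nCells / 3")
  d2 <- as.matrix(dist(scores))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2)
    for (it in seq_len(maxIter)) {
      ex <- if (it <= 100) 4 else 1
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= 250) 0.5 else 0.8
      G <- mom * G - 200 * grad
      Y <- Y + G
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    rownames(Y) <- rownames(scores)
    Y
  })
}
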