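#' Random walk with restart from seed proteins
#'
#' Iterates \eqn{p \leftarrow c\,e + (1-c)\,W^T p} with \eqn{e} uniform over
#' the seed nodes and \eqn{W} the column-normalized adjacency, until the L1
#' change drops below \code{tol} or \code{maxIter} is reached (then a warning
#' is raised and the last iterate returned). The stationary vector sums to 1
#' and ranks nodes by network proximity to the seeds.
#'
#' @param net a connected \linkS4class{PPINetwork}.
#' @param seeds integer node indices of the seed set (e.g. labeled positives).
#' @param restartProb restart probability c, default 0.15.
#' @param tol L1 convergence tolerance, default 1e-8.
#' @param maxIter iteration cap, default 1000.
#' @return numeric per-node stationary probability vector.
#' @export
rwrScores <- function(net, seeds, restartProb = 0.15, tol = 1e-8,
                      maxIter = 1000L) {
  n <- numNodes(net)
  stopifnot(length(seeds) > 0, all(seeds >= 1), all(seeds <= n),
            restartProb > 0, restartProb <= 1)
  e <- edgeMatrix(net)
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                            j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(n, n))
  colDeg <- pmax(Matrix::colSums(A), 1)
  Wt <- Matrix::t(A %*% Matrix::Diagonal(x = 1 / colDeg))  # W^T, row-stoch cols
  ev <- numeric(n)
  ev[seeds] <- 1 / length(seeds)
  p <- ev
  c0 <- restartProb
  for (it in seq_len(maxIter)) {
    pNew <- c0 * ev + (1 - c0) * as.numeric(Wt %*% p)
    if (sum(abs(pNew - p)) < tol) return(pNew)
    p <- pNew
  }
  warning("RWR did not converge within ", maxIter, " iterations")
  p
}

#' Rank unlabeled nodes by RWR proximity to the labeled positives
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param labels a \linkS4class{LabelSet}; positives seed the walk.
#' @param ... passed to \code{\link{rwrScores}}.
#' @return ranking data.frame (rank, node, score) over unlabeled nodes,
#'   descending score, ties by ascending node ID.
#' @export
rwrRanking <- function(net, labels, ...) {
  p <- rwrScores(net, positives(labels), ...)
  ids <- nodeIds(net)
  unl <- unlabeled(labels)
  df <- data.frame(node = ids[unl], score = p[unl], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$node), ]
  data.frame(rank = seq_len(nrow(df)), node = df$node, score = df$score,
             row.names = NULL)
}

#' Feature-only baseline (MLP ablation)
#'
#' The identical spy-CV protocol with the graph operator replaced by the
#' identity — no neighbor aggregation, so the scorer is a plain multilayer
#' perceptron on the frozen embeddings, trained with the nnPU loss.
#'
#' @inheritParams runPUModel
#' @param ... passed to \code{\link{runPUModel}} / \code{\link{trainFold}}.
#' @return as \code{\link{runPUModel}}.
#' @export
featureOnlyScores <- function(net, X, labels, lossCfg = puLossConfig("nnpu"),
                              seed = 42L, ...) {
  runPUModel(net, X, labels, lossCfg, seed = seed,
             identityAdjacency = TRUE, ...)
}

#' @noRd
#' Per-node topology features: degree, local clustering, core number, mean
#' neighbor degree, each z-scored across nodes.
topologyFeatures <- function(net) {
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  core <- igraph::coreness(g)
  mnd <- igraph::knn(g)$knn
  mnd[!is.finite(mnd)] <- 0
  X <- cbind(degree = deg, clustering = cl, core = core, meanNeighborDeg = mnd)
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  X <- X[, , drop = FALSE]
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  rownames(X) <- nodeIds(net)
  X
}

#' Graph-only baseline (topology-feature GCN ablation)
#'
#' The identical spy-CV protocol with the embedding matrix replaced by four
#' z-scored per-node topology descriptors (degree, local clustering
#' coefficient, core number, mean neighbor degree) — no molecular features,
#' only network structure.
#'
#' @inheritParams runPUModel
#' @param ... passed to \code{\link{runPUModel}}.
#' @return as \code{\link{runPUModel}}; the result also carries the feature
#'   matrix used as attribute \code{"topologyFeatures"}.
#' @export
graphOnlyScores <- function(net, labels, lossCfg = puLossConfig("nnpu"),
                            seed = 42L, ...) {
  Xt <- topologyFeatures(net)
  res <- runPUModel(net, Xt, labels, lossCfg, seed = seed, ...)
  attr(res, "topologyFeatures") <- Xt
  res
}
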