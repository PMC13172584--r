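# Independent oracles used to cross-check package computations.

# Upper-tail hypergeometric probability by direct combinatorial summation.
hyperTailOracle <- function(fgHits, fgSize, bgHits, bgSize) {
  ks <- fgHits:min(fgSize, bgHits)
  sum(choose(bgHits, ks) * choose(bgSize - bgHits, fgSize - ks)) /
    choose(bgSize, fgSize)
}

# Betweenness oracle via matrix-power path counting: walks of length equal to
# the graph distance are exactly the shortest paths, so (A^d)[s, t] counts
# geodesics, and the count through an interior node v factorizes as
# sigma(s, v) * sigma(v, t) when d(s, v) + d(v, t) = d(s, t).
# Returns normalized betweenness (pair-count denominator).
bruteBetweenness <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  Ak <- diag(n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% A
    newly <- is.infinite(dist) & Ak > 0
    dist[newly] <- k
    sigma[newly] <- Ak[newly]
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      if (s == v) next
      for (t in (s + 1):n) {
        if (t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Adjacency matrix of a PPINetwork (dense, unweighted).
denseAdjacency <- function(net) {
  n <- numNodes(net)
  A <- matrix(0, n, n)
  e <- edgeMatrix(net)
  A[e] <- 1
  A[e[, 2:1, drop = FALSE]] <- 1
  A
}

# Build a PPINetwork directly from an id vector and an index edge matrix.
makeNet <- function(ids, edges, weights = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  o <- order(lo, hi)
  if (is.null(weights)) weights <- rep(800L, nrow(edges))
  methods::new("PPINetwork", nodeIds = ids,
               edges = unname(cbind(lo, hi)[o, , drop = FALSE]),
               weights = as.integer(weights[o]))
}

# All connected labeled graphs on n nodes, as a list of dense adjacencies.
allConnectedGraphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    if (sum(sel) < n - 1) next
    A <- matrix(0, n, n)
    A[pairs[sel, , drop = FALSE]] <- 1
    A[pairs[sel, 2:1, drop = FALSE]] <- 1
    # connectivity via reachability
    reach <- diag(n)
    for (k in seq_len(n - 1)) reach <- reach %*% (A + diag(n))
    if (all(reach[1, ] > 0)) out[[length(out) + 1L]] <- A
  }
  out
}

adjacencyToNet <- function(A) {
  n <- nrow(A)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  makeNet(sprintf("N%02d", seq_len(n)), idx)
}
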