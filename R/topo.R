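#' Per-node network context metrics
#'
#' For each query node: degree (raw neighbor count), betweenness centrality
#' (shortest-path betweenness with fractional splitting over tied paths,
#' normalized by the pair count \eqn{(n-1)(n-2)/2}), local clustering
#' coefficient (triangles over possible neighbor pairs; 0 when degree < 2),
#' and the known-positive neighbor ratio (fraction of neighbors carrying a
#' positive label). These place candidates on the hub-versus-periphery axis
#' and quantify how embedded they are in known disease neighborhoods.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param labels a \linkS4class{LabelSet}.
#' @param queryNodes character IDs (or integer indices) of nodes to profile;
#'   defaults to all nodes.
#' @return data.frame: node, degree, betweenness, clustering, knownNeighbors,
#'   neighborRatio.
#' @export
topologyReport <- function(net, labels, queryNodes = NULL) {
  ids <- nodeIds(net)
  idx <- if (is.null(queryNodes)) {
    seq_along(ids)
  } else if (is.character(queryNodes)) {
    m <- match(queryNodes, ids)
    if (anyNA(m)) stop("query nodes not in network: ",
                       paste(queryNodes[is.na(m)], collapse = ", "))
    m
  } else as.integer(queryNodes)
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  posFlag <- logical(length(ids))
  posFlag[positives(labels)] <- TRUE
  adj <- igraph::as_adj_list(g)
  known <- vapply(idx, function(i) sum(posFlag[as.integer(adj[[i]])]), 1L)
  data.frame(node = ids[idx], degree = as.integer(deg[idx]),
             betweenness = as.numeric(btw[idx]),
             clustering = as.numeric(cl[idx]),
             knownNeighbors = as.integer(known),
             neighborRatio = ifelse(deg[idx] > 0, known / deg[idx], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
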