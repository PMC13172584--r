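#' Build a PPINetwork from raw edge records
#'
#' Applies the standard STRING-style preprocessing: keep only interactions with
#' confidence strictly above \code{minConfidence} (the reference pipeline uses
#' 700 on the 0-1000 STRING scale), drop self-interactions, and collapse
#' duplicate pairs to their maximum score. Surviving endpoints become the node
#' set, in lexicographically sorted order — the canonical ordering all
#' downstream matrices are aligned to.
#'
#' @param edgeRecords data.frame-like with three columns: protein A ID,
#'   protein B ID, confidence score (numeric, typically integer 0-1000).
#' @param minConfidence numeric; edges with score \code{> minConfidence} are
#'   retained (strict). Default 700.
#' @return a \linkS4class{PPINetwork}.
#' @examples
#' edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                     s = c(800, 650, 701))
#' net <- loadNetwork(edges)
#' numEdges(net)  # 2: the 650 edge is filtered out
#' @export
loadNetwork <- function(edgeRecords, minConfidence = 700) {
  edgeRecords <- as.data.frame(edgeRecords)
  if (ncol(edgeRecords) < 3L) stop("edge records need 3 columns (idA, idB, score)")
  a <- as.character(edgeRecords[[1L]])
  b <- as.character(edgeRecords[[2L]])
  s <- suppressWarnings(as.numeric(edgeRecords[[3L]]))
  bad <- which(!is.finite(s) | is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad)) stop("malformed edge row at line ", bad[1L])
  keep <- s > minConfidence & a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) stop("no edges above threshold")
  ids <- sort(unique(c(a, b)))
  ia <- match(a, ids); ib <- match(b, ids)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- paste0(lo, "_", hi)
  # duplicate pairs (either orientation) collapse to the max score
  w <- tapply(s, key, max)
  first <- !duplicated(key)
  e <- cbind(lo[first], hi[first])
  wv <- as.numeric(w[key[first]])
  o <- order(e[, 1L], e[, 2L])
  methods::new("PPINetwork",
    nodeIds = ids,
    edges = matrix(as.integer(e[o, ]), ncol = 2L),
    weights = as.integer(round(wv[o])))
}

#' Extract the largest connected component
#'
#' Message passing and random-walk propagation require a connected substrate,
#' so smaller components and isolated nodes are discarded. On a size tie the
#' component containing the lexicographically smallest node ID wins. The result
#' keeps canonical (sorted) node ordering.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return the induced \linkS4class{PPINetwork} on the largest component.
#' @export
largestConnectedComponent <- function(net) {
  if (numNodes(net) == 0L) stop("empty network")
  g <- asIgraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie-break: the component whose smallest member ID sorts first
    firstId <- vapply(biggest, function(k) {
      min(nodeIds(net)[comp$membership == k])
    }, character(1))
    biggest <- biggest[order(firstId)[1L]]
  }
  keep <- which(comp$membership == biggest)
  inducedSubnetwork(net, keep)
}

#' @noRd
inducedSubnetwork <- function(net, keepIdx) {
  keepIdx <- sort(keepIdx)
  ids <- nodeIds(net)[keepIdx]
  remap <- rep(NA_integer_, numNodes(net))
  remap[keepIdx] <- seq_along(keepIdx)
  e <- edgeMatrix(net)
  w <- edgeWeights(net)
  inside <- !is.na(remap[e[, 1L]]) & !is.na(remap[e[, 2L]])
  e <- cbind(remap[e[inside, 1L]], remap[e[inside, 2L]])
  w <- w[inside]
  if (nrow(e)) {
    o <- order(e[, 1L], e[, 2L])
    e <- e[o, , drop = FALSE]; w <- w[o]
  }
  methods::new("PPINetwork", nodeIds = ids,
               edges = matrix(as.integer(e), ncol = 2L), weights = w)
}

#' @noRd
asIgraph <- function(net) {
  igraph::graph_from_edgelist(edgeMatrix(net), directed = FALSE) |>
    (\(g) {
      miss <- numNodes(net) - igraph::vcount(g)
      if (miss > 0) g <- igraph::add_vertices(g, miss)
      igraph::set_vertex_attr(g, "name", value = nodeIds(net))
    })()
}

#' Align a keyed feature table to a network's node order
#'
#' Reorders feature rows into the network's canonical node order; rows for
#' proteins absent from the network are dropped (a count is messaged). Every
#' network node must have a feature row. Features are frozen inputs: they are
#' never modified or trained downstream.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param table numeric matrix or data.frame with rownames (or a first ID
#'   column) keying protein IDs.
#' @return numeric matrix, rows aligned to \code{nodeIds(net)}.
#' @export
alignFeatures <- function(net, table) {
  if (is.data.frame(table)) {
    if (!is.numeric(table[[1L]]) && is.null(rownames(table))) {
      rn <- as.character(table[[1L]])
      table <- as.matrix(table[, -1L, drop = FALSE])
      rownames(table) <- rn
    } else {
      table <- as.matrix(table)
    }
  }
  storage.mode(table) <- "double"
  ids <- nodeIds(net)
  hit <- match(ids, rownames(table))
  if (anyNA(hit)) {
    missing <- ids[is.na(hit)]
    stop("feature rows missing for ", length(missing), " network node(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  extra <- nrow(table) - length(ids)
  if (extra > 0) message("alignFeatures: dropping ", extra,
                         " feature row(s) not in the network")
  out <- table[hit, , drop = FALSE]
  if (anyNA(out) || any(!is.finite(out))) stop("feature matrix contains missing/non-finite values")
  rownames(out) <- ids
  out
}

#' Construct a LabelSet from positive protein IDs
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param positiveIds character vector of protein IDs carrying positive labels;
#'   IDs absent from the network are ignored with a message.
#' @return a \linkS4class{LabelSet}.
#' @export
makeLabelSet <- function(net, positiveIds) {
  ids <- nodeIds(net)
  idx <- match(unique(positiveIds), ids)
  dropped <- sum(is.na(idx))
  if (dropped) message("makeLabelSet: ", dropped, " positive ID(s) not in network")
  idx <- sort(idx[!is.na(idx)])
  if (!length(idx)) stop("no positive labels map onto the network")
  methods::new("LabelSet",
    positives = as.integer(idx),
    unlabeled = setdiff(seq_along(ids), idx),
    nNodes = length(ids))
}

# ---- file readers / writers -------------------------------------------------

#' Read a STRING-style edge list (TSV: protein1, protein2, combined_score)
#'
#' Lines starting with '#' are ignored. An optional two-column ID mapping file
#' (from, to) is applied to both endpoint columns before anything else.
#'
#' @param path TSV file path.
#' @param mappingPath optional two-column TSV mapping raw IDs to harmonized IDs.
#' @return data.frame with columns protein1, protein2, combined_score.
#' @export
readEdgeList <- function(path, mappingPath = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("protein1", "protein2", "combined_score"),
                          colClasses = c("character", "character", "numeric"))
  if (!is.null(mappingPath)) {
    map <- utils::read.table(mappingPath, sep = "\t", header = FALSE,
                             colClasses = "character")
    lut <- stats::setNames(map[[2L]], map[[1L]])
    hit1 <- df$protein1 %in% names(lut)
    hit2 <- df$protein2 %in% names(lut)
    df$protein1[hit1] <- lut[df$protein1[hit1]]
    df$protein2[hit2] <- lut[df$protein2[hit2]]
  }
  df
}

#' Write a PPINetwork as a three-column TSV edge list
#' @param net a \linkS4class{PPINetwork}.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
  ids <- nodeIds(net)
  e <- edgeMatrix(net)
  df <- data.frame(protein1 = ids[e[, 1L]], protein2 = ids[e[, 2L]],
                   combined_score = edgeWeights(net))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a feature table (TSV with header; first column = protein ID)
#' @param path TSV file path.
#' @return numeric matrix with protein-ID rownames.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  rn <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Write a feature matrix as TSV (first column = protein ID)
#' @param features numeric matrix with rownames.
#' @param path output path.
#' @export
writeFeatureTable <- function(features, path) {
  df <- data.frame(protein = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a label list (one protein ID per line)
#' @param path file path.
#' @return character vector.
#' @export
readLabels <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read annotation gene sets in GMT format
#'
#' One GMT file per category: term-ID, description, then member IDs, all
#' tab-separated.
#'
#' @param paths named character vector of GMT file paths; names become the
#'   category names.
#' @return an \linkS4class{AnnotationSets}.
#' @export
readAnnotations <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("GMT paths must be named by category")
  }
  cats <- list()
  termNames <- character()
  for (cat in names(paths)) {
    sets <- fgsea::gmtPathways(paths[[cat]])
    # second GMT column (description) is not returned by gmtPathways; re-read it
    lines <- strsplit(readLines(paths[[cat]]), "\t", fixed = TRUE)
    desc <- vapply(lines, function(f) f[2L], character(1))
    names(desc) <- vapply(lines, function(f) f[1L], character(1))
    cats[[cat]] <- sets
    termNames <- c(termNames, desc)
  }
  methods::new("AnnotationSets", categories = cats, termNames = termNames)
}

#' Write one annotation category to a GMT file
#' @param sets named list of character vectors (term -> members).
#' @param path output path.
#' @param descriptions optional named character of term descriptions.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(term) {
    d <- if (!is.null(descriptions) && term %in% names(descriptions)) {
      descriptions[[term]]
    } else "na"
    paste(c(term, d, sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
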