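#' PPINetwork: an undirected weighted protein-protein interaction graph
#'
#' Stores a deduplicated, self-loop-free undirected graph over protein
#' identifiers. Node order is canonical (lexicographically sorted IDs) and is
#' the row order every downstream object (feature matrix, score vector,
#' adjacency operator) is aligned to. Edge confidence scores are kept as read
#' (STRING-style integers in [0, 1000]) but are metadata only: message passing
#' and all topology metrics use the unweighted adjacency.
#'
#' @slot nodeIds character vector of unique protein IDs, sorted.
#' @slot edges integer matrix with two columns; each row is an unordered node
#'   index pair with \code{edges[, 1] < edges[, 2]}, rows unique and ordered.
#' @slot weights integer vector of per-edge confidence scores.
#'
#' @export
setClass("PPINetwork",
  representation(
    nodeIds = "character",
    edges = "matrix",
    weights = "integer"
  )
)

setValidity("PPINetwork", function(object) {
  msg <- character()
  n <- length(object@nodeIds)
  e <- object@edges
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "duplicate node IDs")
  if (is.unsorted(object@nodeIds)) msg <- c(msg, "node IDs must be sorted")
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoint out of range")
    if (any(e[, 1L] >= e[, 2L])) {
      msg <- c(msg, "edges must satisfy i < j (no self-loops, canonical order)")
    }
    key <- (e[, 1L] - 1) * as.double(n) + e[, 2L]
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(object@weights) != nrow(e)) {
    msg <- c(msg, "weights length must equal edge count")
  }
  if (length(msg)) msg else TRUE
})

#' LabelSet: partition of network nodes into labeled positives and unlabeled
#'
#' In the PU setting there are no labeled negatives: every node is either a
#' labeled positive or unlabeled (a mixture of hidden positives and true
#' negatives). Spy evaluation temporarily moves a subset of positives into the
#' unlabeled pool; such derived splits live in \code{FoldSplit} lists, not here.
#'
#' @slot positives integer vector of node indices carrying positive labels.
#' @slot unlabeled integer vector of the remaining node indices.
#' @slot nNodes integer, number of nodes in the paired network.
#'
#' @export
setClass("LabelSet",
  representation(
    positives = "integer",
    unlabeled = "integer",
    nNodes = "integer"
  )
)

setValidity("LabelSet", function(object) {
  msg <- character()
  p <- object@positives
  u <- object@unlabeled
  n <- object@nNodes
  if (length(p) < 1L) msg <- c(msg, "at least one labeled positive required")
  if (length(intersect(p, u))) msg <- c(msg, "positives and unlabeled overlap")
  if (!setequal(c(p, u), seq_len(n))) {
    msg <- c(msg, "positives and unlabeled must partition all node indices")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSets: gene-set collections per annotation category
#'
#' One member-set collection per category (e.g. tissue, GO BP/MF/CC, pathway),
#' as read from GMT files. Term membership is stored on protein IDs, not node
#' indices, so a collection can be reused across networks.
#'
#' @slot categories named list; each element is a named list mapping term ID to
#'   a character vector of member protein IDs.
#' @slot termNames named character vector mapping term ID to a display string.
#'
#' @export
setClass("AnnotationSets",
  representation(
    categories = "list",
    termNames = "character"
  )
)

setValidity("AnnotationSets", function(object) {
  msg <- character()
  if (is.null(names(object@categories)) ||
      anyDuplicated(names(object@categories))) {
    msg <- c(msg, "categories must be uniquely named")
  }
  for (cat in names(object@categories)) {
    sets <- object@categories[[cat]]
    if (!is.list(sets) || is.null(names(sets))) {
      msg <- c(msg, sprintf("category '%s' must be a named list", cat))
      next
    }
    if (any(!vapply(sets, length, 1L))) {
      msg <- c(msg, sprintf("category '%s' has an empty term", cat))
    }
  }
  if (length(msg)) msg else TRUE
})
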