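#' @name pugnn-accessors
#' @title Accessors for pugnn data classes
#'
#' @description Slot access for \linkS4class{PPINetwork},
#' \linkS4class{LabelSet} and \linkS4class{AnnotationSets} goes through these
#' generics; slots are an implementation detail.
#'
#' @param x a pugnn data object.
#' @return \code{nodeIds}: character vector of protein IDs in canonical order.
#'   \code{numNodes}, \code{numEdges}: integer counts. \code{edgeMatrix}: the
#'   two-column integer index matrix. \code{edgeWeights}: integer confidence
#'   scores. \code{positives}, \code{unlabeled}: integer node-index vectors.
#'   \code{categories}: named list of term collections.
NULL

#' @rdname pugnn-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname pugnn-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname pugnn-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname pugnn-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname pugnn-accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname pugnn-accessors
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname pugnn-accessors
#' @export
setGeneric("unlabeled", function(x) standardGeneric("unlabeled"))

#' @rdname pugnn-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname pugnn-accessors
#' @export
setMethod("nodeIds", "PPINetwork", function(x) x@nodeIds)

#' @rdname pugnn-accessors
#' @export
setMethod("numNodes", "PPINetwork", function(x) length(x@nodeIds))

#' @rdname pugnn-accessors
#' @export
setMethod("numEdges", "PPINetwork", function(x) nrow(x@edges))

#' @rdname pugnn-accessors
#' @export
setMethod("edgeMatrix", "PPINetwork", function(x) x@edges)

#' @rdname pugnn-accessors
#' @export
setMethod("edgeWeights", "PPINetwork", function(x) x@weights)

#' @rdname pugnn-accessors
#' @export
setMethod("positives", "LabelSet", function(x) x@positives)

#' @rdname pugnn-accessors
#' @export
setMethod("unlabeled", "LabelSet", function(x) x@unlabeled)

#' @rdname pugnn-accessors
#' @export
setMethod("categories", "AnnotationSets", function(x) x@categories)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodeIds), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges)) {
    cat("  confidence scores:", min(object@weights), "-",
        max(object@weights), "\n")
  }
  ids <- object@nodeIds
  cat("  nodeIds:", paste(utils::head(ids, 4), collapse = ", "),
      if (length(ids) > 4) "..." else "", "\n")
})

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet:", length(object@positives), "labeled positives,",
      length(object@unlabeled), "unlabeled of", object@nNodes, "nodes\n")
})

setMethod("show", "AnnotationSets", function(object) {
  cat("AnnotationSets with", length(object@categories), "categories:\n")
  for (cat_ in names(object@categories)) {
    cat("  ", cat_, ": ", length(object@categories[[cat_]]), " terms\n",
        sep = "")
  }
})
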