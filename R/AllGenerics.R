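#' @include AllClasses.R
NULL

#' Accessors for nodescope result objects
#'
#' Small accessor family: slot access in user code is discouraged.
#'
#' @param x a nodescope S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))
#' @rdname accessors
#' @export
setGeneric("cellEmbeddings", function(x) standardGeneric("cellEmbeddings"))
#' @rdname accessors
#' @export
setGeneric("sigPCs", function(x) standardGeneric("sigPCs"))
#' @rdname accessors
#' @export
setGeneric("pcVariance", function(x) standardGeneric("pcVariance"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("snnGraph", function(x) standardGeneric("snnGraph"))
#' @rdname accessors
#' @export
setGeneric("layoutCoords", function(x) standardGeneric("layoutCoords"))
#' @rdname accessors
#' @export
setGeneric("nodeAssignment", function(x) standardGeneric("nodeAssignment"))
#' @rdname accessors
#' @export
setGeneric("icScores", function(x) standardGeneric("icScores"))
#' @rdname accessors
#' @export
setGeneric("icWeights", function(x) standardGeneric("icWeights"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("transferredLabels", function(x) standardGeneric("transferredLabels"))

#' @rdname accessors
setMethod("geneLoadings", "PCAModel", function(x) x@loadings)
#' @rdname accessors
setMethod("geneLoadings", "ReferenceModel", function(x) x@pca@loadings)
#' @rdname accessors
setMethod("cellEmbeddings", "PCAModel", function(x) x@embeddings)
#' @rdname accessors
setMethod("cellEmbeddings", "ProjectionResult", function(x) x@embeddings)
#' @rdname accessors
setMethod("sigPCs", "PCAModel", function(x) x@sigPCs)
#' @rdname accessors
setMethod("sigPCs", "ReferenceModel", function(x) x@pca@sigPCs)
#' @rdname accessors
setMethod("pcVariance", "PCAModel", function(x) x@sdev^2)
#' @rdname accessors
setMethod("clusterLabels", "ClusterResult",
          function(x) setNames(x@labels, x@cells))
#' @rdname accessors
setMethod("snnGraph", "ClusterResult", function(x) x@snn)
#' @rdname accessors
setMethod("layoutCoords", "TSNELayout", function(x) x@coords)
#' @rdname accessors
setMethod("layoutCoords", "ReferenceModel", function(x) x@layout)
#' @rdname accessors
setMethod("layoutCoords", "ProjectionResult", function(x) x@coords)
#' @rdname accessors
setMethod("nodeAssignment", "NodeTree", function(x) x@assignment)
#' @rdname accessors
setMethod("icScores", "ICAModel", function(x) x@scores)
#' @rdname accessors
setMethod("icWeights", "ICAModel", function(x) x@weights)
#' @rdname accessors
setMethod("transitionMatrix", "DiffusionOperator", function(x) x@P)
#' @rdname accessors
setMethod("transferredLabels", "ProjectionResult",
          function(x) setNames(x@labels, rownames(x@embeddings)))

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", length(object@varGenes), "variable genes,",
      nrow(object@embeddings), "cells,", length(object@sdev), "components\n")
  cat("  significant PCs (z >", object@zThreshold, "):",
      paste(object@sigPCs, collapse = " "), "\n")
  if (length(object@excludedPCs))
    cat("  excluded PCs:", paste(object@excludedPCs, collapse = " "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@cells), "cells,",
      length(unique(object@labels)), "clusters (resolution",
      object@resolution, ", k", object@k, ")\n")
  cat("  modularity:", round(object@modularity, 4), "\n")
})

setMethod("show", "NodeTree", function(object) {
  cat("NodeTree:", length(object@assignment), "clusters ->",
      length(unique(object@assignment)), "nodes (", object@linkage,
      "linkage )\n")
  for (nd in sort(unique(object@assignment)))
    cat("  node", nd, ":",
        paste(names(object@assignment)[object@assignment == nd],
              collapse = " "), "\n")
})

setMethod("show", "ReferenceModel", function(object) {
  cat("ReferenceModel:", nrow(object@layout), "reference cells,",
      length(object@pca@varGenes), "variable genes,",
      length(object@pca@sigPCs), "significant PCs\n")
  cat("  labels:", paste(head(sort(unique(object@labels)), 8),
                         collapse = " "), "\n")
})

setMethod("show", "ProjectionResult", function(object) {
  cat("ProjectionResult:", nrow(object@embeddings), "query cells placed by",
      object@K, "- nearest-neighbor averaging\n")
  if (length(object@notes)) cat("  note:", object@notes[1], "\n")
})

setMethod("show", "ICAModel", function(object) {
  cat("ICAModel:", ncol(object@scores), "components,",
      nrow(object@scores), "cells,", nrow(object@weights), "genes\n")
})

setMethod("show", "DiffusionOperator", function(object) {
  cat("DiffusionOperator over", nrow(object@P), "cells (k =", object@k,
      ");", object@bandwidthRule, "\n")
})
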