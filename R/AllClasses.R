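#' @import methods
#' @importFrom stats median sd var quantile rnorm runif rbeta rbinom rgamma
#'   rnbinom rmultinom p.adjust pchisq pt pf phyper dist hclust cutree aov
#'   anova lm t.test fisher.test cor setNames as.formula coef complete.cases
#'   prcomp
#' @importFrom utils head read.delim write.table
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PCAModel: an SVD principal component decomposition
#'
#' Holds the gene loadings, variance-weighted cell embeddings, per-component
#' standard deviations and z-scores, and the significant-component set of a
#' centered/unit-scaled SVD PCA fitted on a variable-gene subset.
#'
#' Embeddings are the SVD scores \eqn{UD} (equivalently, the centered and
#' scaled expression matrix multiplied by the loadings), so each embedding
#' column is already weighted by its component's singular value.  The
#' significant set is \{components with variance z-score > threshold\} minus
#' any manually excluded components (e.g. one tracking a batch effect).
#'
#' @slot loadings genes x components orthonormal loading matrix.
#' @slot embeddings cells x components score matrix (\eqn{UD}).
#' @slot sdev per-component standard deviation (singular value / sqrt(n-1)).
#' @slot zScores z-score of each component's share of total variance.
#' @slot sigPCs integer indices of significant components, in order.
#' @slot excludedPCs integer indices manually excluded from the significant set.
#' @slot varGenes character vector of the genes the model was fitted on.
#' @slot center,scale per-gene centering/scaling constants used before SVD.
#' @slot zThreshold the z cutoff used for significance.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    loadings = "matrix", embeddings = "matrix", sdev = "numeric",
    zScores = "numeric", sigPCs = "integer", excludedPCs = "integer",
    varGenes = "character", center = "numeric", scale = "numeric",
    zThreshold = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- NULL
  if (ncol(object@loadings) != ncol(object@embeddings))
    msg <- c(msg, "loadings and embeddings must have the same component count")
  if (length(object@sdev) != ncol(object@loadings))
    msg <- c(msg, "sdev length must equal the component count")
  if (nrow(object@loadings) != length(object@varGenes))
    msg <- c(msg, "one loading row per variable gene required")
  if (any(object@sigPCs > length(object@sdev)))
    msg <- c(msg, "sigPCs out of range")
  if (is.null(msg)) TRUE else msg
})

#' ClusterResult: SNN Louvain-Jaccard community assignment
#'
#' @slot labels integer cluster label per cell, contiguous from 0.
#' @slot cells cell identifiers, parallel to labels.
#' @slot snn sparse symmetric SNN graph (Jaccard edge weights).
#' @slot modularity modularity achieved by the partition.
#' @slot resolution,k,seed parameters of the run.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    labels = "integer", cells = "character", snn = "Matrix",
    modularity = "numeric", resolution = "numeric", k = "integer",
    seed = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@cells))
    msg <- c(msg, "one label per cell required")
  u <- sort(unique(object@labels))
  if (length(u) && !identical(u, seq(0L, max(u))))
    msg <- c(msg, "labels must be contiguous integers from 0")
  if (is.null(msg)) TRUE else msg
})

#' TSNELayout: a 2-D t-SNE embedding
#'
#' @slot coords cells x 2 coordinate matrix.
#' @slot perplexity,seed parameters of the run.
#' @exportClass TSNELayout
setClass("TSNELayout",
  representation(coords = "matrix", perplexity = "numeric", seed = "integer"))

setValidity("TSNELayout", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have 2 columns")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' NodeTree: hierarchical merging of cluster centroids into nodes
#'
#' The dendrogram is an \code{\link[stats]{hclust}} tree over cluster
#' centroids in significant-PC space; nodes are the groups obtained by
#' cutting it, named "A", "B", ... in dendrogram order.
#'
#' @slot dendrogram the hclust object over cluster centroids.
#' @slot assignment named character vector, cluster label -> node name.
#' @slot linkage agglomeration method used.
#' @exportClass NodeTree
setClass("NodeTree",
  representation(dendrogram = "ANY", assignment = "character",
                 linkage = "character"))

setValidity("NodeTree", function(object) {
  msg <- NULL
  if (!inherits(object@dendrogram, "hclust"))
    msg <- c(msg, "dendrogram must be an hclust object")
  else if (!all(object@dendrogram$labels %in% names(object@assignment)))
    msg <- c(msg, "every cluster (dendrogram leaf) needs a node assignment")
  if (is.null(msg)) TRUE else msg
})

#' ReferenceModel: a fitted dataset used as projection target
#'
#' Bundles the reference PCA (loadings + centering/scaling constants +
#' significant components), the reference cells' 2-D layout and their labels,
#' so external query cells can be embedded via the gene loadings and placed
#' among the reference cells by kNN.
#'
#' @slot pca the reference \linkS4class{PCAModel}.
#' @slot layout reference cells x 2 layout coordinates.
#' @slot labels per-reference-cell label.
#' @slot meta free-form metadata list.
#' @exportClass ReferenceModel
setClass("ReferenceModel",
  representation(pca = "PCAModel", layout = "matrix", labels = "character",
                 meta = "list"))

setValidity("ReferenceModel", function(object) {
  msg <- NULL
  n <- nrow(object@pca@embeddings)
  if (nrow(object@layout) != n)
    msg <- c(msg, "layout must have one row per reference cell")
  if (length(object@labels) != n)
    msg <- c(msg, "labels must have one entry per reference cell")
  if (is.null(msg)) TRUE else msg
})

#' ProjectionResult: query cells embedded, placed and labeled in a reference
#'
#' @slot embeddings query cells x significant components.
#' @slot nnIndex,nnDist query cells x K neighbor indices/distances.
#' @slot coords query cells x 2 placed coordinates (mean of neighbor layout).
#' @slot labels,confidence transferred label and vote fraction per query.
#' @slot K neighbor count used.
#' @slot notes character metadata (e.g. the K convention note).
#' @exportClass ProjectionResult
setClass("ProjectionResult",
  representation(
    embeddings = "matrix", nnIndex = "matrix", nnDist = "matrix",
    coords = "matrix", labels = "character", confidence = "numeric",
    K = "integer", notes = "character"))

setValidity("ProjectionResult", function(object) {
  msg <- NULL
  n <- nrow(object@embeddings)
  if (nrow(object@nnIndex) != n || ncol(object@nnIndex) != object@K)
    msg <- c(msg, "nnIndex must be n_query x K")
  if (length(object@confidence) &&
      (any(object@confidence <= 0) || any(object@confidence > 1)))
    msg <- c(msg, "confidence must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' ICAModel: independent component decomposition
#'
#' Cell scores are scaled to unit sample variance per component; gene weights
#' satisfy (approximately) \code{X = scores \%*\% t(weights)} for the z-scaled
#' input.  Components are sign-oriented so the heavier tail of each weight
#' vector is positive.
#'
#' @slot scores cells x components.
#' @slot weights genes x components.
#' @slot topPos,topNeg per-component character lists of the top-n genes in
#'   the positive/negative weight tails.
#' @slot nTail size of the stored tails (default 50).
#' @slot seed RNG seed used.
#' @exportClass ICAModel
setClass("ICAModel",
  representation(scores = "matrix", weights = "matrix", topPos = "list",
                 topNeg = "list", nTail = "integer", seed = "integer"))

setValidity("ICAModel", function(object) {
  msg <- NULL
  if (ncol(object@scores) != ncol(object@weights))
    msg <- c(msg, "scores and weights must agree on component count")
  if (ncol(object@scores) < 1L) msg <- c(msg, "at least one component required")
  if (is.null(msg)) TRUE else msg
})

#' DiffusionOperator: row-stochastic cell-cell transition matrix
#'
#' Built from a kNN graph with an adaptive Gaussian kernel (bandwidth =
#' distance to the ceiling(k/3)-th neighbor), symmetrized and row-normalized.
#' Powers of this operator diffuse (impute) expression across similar cells.
#'
#' @slot P sparse row-stochastic transition matrix.
#' @slot k neighbor count.
#' @slot bandwidthRule human-readable description of the kernel bandwidth.
#' @exportClass DiffusionOperator
setClass("DiffusionOperator",
  representation(P = "Matrix", k = "integer", bandwidthRule = "character"))

setValidity("DiffusionOperator", function(object) {
  rs <- Matrix::rowSums(object@P)
  if (any(abs(rs - 1) > 1e-9)) return("every row of P must sum to 1")
  if (any(object@P@x < 0)) return("P entries must be nonnegative")
  TRUE
})
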