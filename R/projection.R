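#' @include AllClasses.R utils.R
NULL

#' Bundle a fitted PCA, layout and labels into a reference model
#'
#' @param pca a \linkS4class{PCAModel} fitted on the reference dataset.
#' @param layout reference 2-D layout (\linkS4class{TSNELayout} or matrix).
#' @param labels per-reference-cell label.
#' @param meta optional metadata list.
#' @return a \linkS4class{ReferenceModel}.
#' @export
referenceModel <- function(pca, layout, labels, meta = list()) {
  coords <- if (is(layout, "TSNELayout")) layout@coords else as.matrix(layout)
  methods::new("ReferenceModel", pca = pca, layout = coords,
               labels = as.character(labels), meta = meta)
}

#' Project query cells into a reference PC space via gene loadings
#'
#' Query expression is restricted to the reference's variable genes,
#' transformed with the reference's per-gene centering and scaling
#' constants (a variable gene missing from the query contributes the
#' centered value of a zero count), and multiplied by the reference gene
#' loadings.  Because reference embeddings are the SVD scores, the product
#' carries the same per-component variance weighting and the two are
#' directly comparable.
#'
#' @param ref a \linkS4class{ReferenceModel}.
#' @param query a \linkS4class{SingleCellExperiment} with a \code{lognorm}
#'   assay, or a genes x cells normalized matrix.
#' @return query cells x components embedding matrix.
#' @export
projectIntoReference <- function(ref, query) {
  norm <- getLogNorm(query)
  vg <- ref@pca@varGenes
  shared <- intersect(vg, rownames(norm))
  if (length(shared) < 0.5 * length(vg))
    stop("only ", length(shared), "/", length(vg),
         " reference variable genes present in query (floor is 50%)")
  n <- ncol(norm)
  Q <- matrix(0, n, length(vg), dimnames = list(colnames(norm), vg))
  Q[, shared] <- t(as.matrix(norm[shared, , drop = FALSE]))
  Q <- sweep(sweep(Q, 2, ref@pca@center), 2, ref@pca@scale, "/")
  emb <- Q %*% ref@pca@loadings
  colnames(emb) <- colnames(ref@pca@loadings)
  emb
}

#' Place query cells among reference cells by kNN
#'
#' Neighbors are found by Euclidean distance in significant-component
#' space (ties broken by reference cell index, so placement is
#' deterministic); each query cell is placed at the arithmetic mean of its
#' K neighbors' layout coordinates and labeled by majority vote
#' (\code{\link{transferLabels}}).
#'
#' @param ref a \linkS4class{ReferenceModel}.
#' @param queryEmbeddings matrix from \code{\link{projectIntoReference}}.
#' @param K neighbor count (default 5; the alternative K = 3 convention is
#'   recorded in the result's notes).
#' @return a \linkS4class{ProjectionResult}.
#' @export
knnPlace <- function(ref, queryEmbeddings, K = 5) {
  sig <- ref@pca@sigPCs
  refE <- ref@pca@embeddings[, sig, drop = FALSE]
  K <- as.integer(K)
  if (K < 1L || K > nrow(refE)) stop("K must be in [1, n_reference]")
  qE <- queryEmbeddings[, sig, drop = FALSE]
  nn <- knnExact(refE, qE, k = K)
  coords <- matrix(0, nrow(qE), 2,
                   dimnames = list(rownames(qE), colnames(ref@layout)))
  for (i in seq_len(nrow(qE)))
    coords[i, ] <- colMeans(ref@layout[nn$index[i, ], , drop = FALSE])
  tl <- transferLabels(nn$index, ref@labels)
  methods::new("ProjectionResult", embeddings = queryEmbeddings,
               nnIndex = nn$index, nnDist = nn$dist, coords = coords,
               labels = tl$label, confidence = tl$confidence, K = K,
               notes = paste("K =", K, "(majority vote; the source method",
                             "is also described with K = 3)"))
}

#' Transfer reference labels to query cells by neighbor majority vote
#'
#' Confidence is the vote fraction; a tied vote is broken in favor of the
#' tied label carried by the best-ranked (nearest) neighbor.
#'
#' @param nnIndex n_query x K matrix of reference neighbor indices (or a
#'   \linkS4class{ProjectionResult}).
#' @param refLabels per-reference-cell labels.
#' @return list with \code{label} and \code{confidence} vectors.
#' @export
transferLabels <- function(nnIndex, refLabels) {
  if (is(nnIndex, "ProjectionResult")) nnIndex <- nnIndex@nnIndex
  refLabels <- as.character(refLabels)
  n <- nrow(nnIndex)
  lab <- character(n); conf <- numeric(n)
  for (i in seq_len(n)) {
    votes <- refLabels[nnIndex[i, ]]
    tab <- table(votes)
    mx <- max(tab)
    cand <- names(tab)[tab == mx]
    lab[i] <- if (length(cand) == 1L) cand else
      votes[match(TRUE, votes %in% cand)]
    conf[i] <- mx / length(votes)
  }
  list(label = lab, confidence = conf)
}

#' Serialize a ReferenceModel to a directory of plain-text tables
#' @param ref a \linkS4class{ReferenceModel}.
#' @param dir output directory (created).
#' @export
writeReferenceModel <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, col.names = NA)
  wt(ref@pca@loadings, "loadings.tsv")
  wt(data.frame(center = ref@pca@center, scale = ref@pca@scale,
                row.names = ref@pca@varGenes), "constants.tsv")
  wt(ref@layout, "layout.tsv")
  write.table(data.frame(cell = rownames(ref@layout), label = ref@labels),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(sigPCs = ref@pca@sigPCs, sdev = ref@pca@sdev,
         zThreshold = ref@pca@zThreshold, meta = ref@meta),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
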