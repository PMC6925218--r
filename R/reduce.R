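#' @include AllClasses.R utils.R
NULL

#' Binned-dispersion variable gene selection
#'
#' Computes per-gene mean normalized expression and dispersion
#' (variance/mean), sorts genes into equal-width mean-expression bins,
#' z-scores the dispersion within each bin, and selects genes with mean in
#' (\code{meanLow}, \code{meanHigh}) and binned dispersion z-score at least
#' \code{zMin}.
#'
#' @param x a \linkS4class{SingleCellExperiment} with a \code{lognorm} assay,
#'   or a genes x cells normalized matrix.
#' @param meanLow,meanHigh mean-expression window (defaults 0.125 and 3).
#' @param zMin minimum within-bin dispersion z-score (default 0.5).
#' @param nBins number of equal-width bins (default 20).
#' @return a \code{VariableGeneSelection} list: per-gene \code{table}
#'   (mean, dispersion, bin, z), selected \code{genes}, and the parameters.
#' @export
selectVariableGenes <- function(x, meanLow = 0.125, meanHigh = 3,
                                zMin = 0.5, nBins = 20) {
  norm <- getLogNorm(x)
  mu <- Matrix::rowMeans(norm)
  if (length(unique(mu)) < nBins)
    stop("need at least nBins distinct gene means")
  ex2 <- Matrix::rowMeans(norm^2)
  n <- ncol(norm)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- cut(mu, breaks = nBins, include.lowest = TRUE, labels = FALSE)
  z <- rep(0, length(mu))
  for (b in unique(bin)) {
    i <- bin == b
    s <- sd(disp[i])
    if (is.finite(s) && s > 0) z[i] <- (disp[i] - mean(disp[i])) / s
  }
  sel <- mu > meanLow & mu < meanHigh & z >= zMin
  if (!any(sel))
    stop("no variable genes selected; consider relaxing meanLow/meanHigh/zMin")
  structure(list(
    table = data.frame(gene = rownames(norm), mean = mu, dispersion = disp,
                       bin = bin, z = z, selected = sel,
                       row.names = NULL),
    genes = rownames(norm)[sel],
    params = list(meanLow = meanLow, meanHigh = meanHigh, zMin = zMin,
                  nBins = nBins)),
    class = "VariableGeneSelection")
}

#' SVD principal component analysis on a variable-gene subset
#'
#' Genes are centered and unit-scaled across cells before the singular value
#' decomposition.  Cell embeddings are the SVD scores (\eqn{UD}; each
#' component weighted by its singular value), gene loadings the right
#' singular vectors.  Component signs are fixed so the largest-magnitude
#' loading of each component is positive.  The significant-component set is
#' pre-computed at the default z threshold (see
#' \code{\link{selectSignificantPCs}}).
#'
#' @param x normalized input (as in \code{\link{selectVariableGenes}}).
#' @param genes variable gene identifiers (or a \code{VariableGeneSelection}).
#' @param nComponents number of components to retain; the default is the
#'   complete decomposition, on which the significance z-scoring is defined.
#' @param zThreshold significance z cutoff stored with the model.
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, genes, nComponents = NULL, zThreshold = 2) {
  norm <- getLogNorm(x)
  if (inherits(genes, "VariableGeneSelection")) genes <- genes$genes
  stopifnot(all(genes %in% rownames(norm)))
  X <- as.matrix(Matrix::t(norm[genes, , drop = FALSE]))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance gene(s) dropped before PCA")
    X <- X[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
    genes <- genes[keep]
  }
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ## complete decomposition by default: the variance z-scoring that selects
  ## significant components is defined on the full spectrum
  maxK <- min(dim(X))
  k <- if (is.null(nComponents)) maxK else as.integer(nComponents)
  if (k > maxK) stop("nComponents exceeds min(n_cells, n_genes)")
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  emb <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                 diag(sv$d[seq_len(k)], k), 2, flip, "*")
  rownames(loadings) <- genes
  rownames(emb) <- rownames(X)
  colnames(loadings) <- colnames(emb) <- paste0("PC", seq_len(k))
  sdev <- sv$d[seq_len(k)] / sqrt(max(nrow(X) - 1, 1))
  zs <- .pcZScores(sdev^2)
  sig <- which(zs > zThreshold)
  methods::new("PCAModel", loadings = loadings, embeddings = emb,
               sdev = sdev, zScores = zs, sigPCs = as.integer(sig),
               excludedPCs = integer(), varGenes = genes, center = ctr,
               scale = scl, zThreshold = zThreshold)
}

.pcZScores <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Select significant principal components by variance z-score
#'
#' z-scores each component's variance against the per-component variance
#' vector and returns the components with z above the threshold, minus any
#' manual exclusions (e.g. a component tracking a batch effect), preserving
#' component order.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param zThreshold z cutoff (default 2).
#' @param exclusions integer component indices to reject.
#' @return integer vector of component indices.
#' @export
selectSignificantPCs <- function(model, zThreshold = 2,
                                 exclusions = integer()) {
  z <- .pcZScores(pcVariance(model))
  out <- setdiff(which(z > zThreshold), as.integer(exclusions))
  if (length(out) == 0L)
    stop("no significant components at z > ", zThreshold)
  as.integer(out)
}

#' Apply a significant-component set (with exclusions) to a model
#' @param model a \linkS4class{PCAModel}.
#' @inheritParams selectSignificantPCs
#' @return the model with updated \code{sigPCs}/\code{excludedPCs}.
#' @export
setSignificantPCs <- function(model, zThreshold = model@zThreshold,
                              exclusions = integer()) {
  model@sigPCs <- selectSignificantPCs(model, zThreshold, exclusions)
  model@excludedPCs <- as.integer(exclusions)
  model@zThreshold <- zThreshold
  methods::validObject(model)
  model
}

## significant-component embedding matrix, variance weighted
sigEmbeddings <- function(model) {
  if (length(model@sigPCs) == 0L)
    stop("model has no significant components")
  model@embeddings[, model@sigPCs, drop = FALSE]
}

#' Shared-nearest-neighbor Louvain-Jaccard clustering
#'
#' Builds the k-nearest-neighbor graph (Euclidean distance in
#' significant-component space, each cell's neighbor list including itself),
#' weights edges by the Jaccard index of the two cells' neighbor lists
#' (edges below \code{prune} dropped), and maximizes modularity by Louvain
#' community detection at the given resolution.
#'
#' @param x a \linkS4class{PCAModel} (its significant components are used)
#'   or a cells x dims embedding matrix.
#' @param k neighbor count including self (default 30).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed controlling the community detection.
#' @param prune Jaccard floor below which SNN edges are dropped
#'   (default 1/15).
#' @return a \linkS4class{ClusterResult}; labels are 0-based and ordered by
#'   decreasing cluster size.
#' @export
buildSNNCluster <- function(x, k = 30, resolution = 0.8, seed = 42,
                            prune = 1 / 15) {
  emb <- if (is(x, "PCAModel")) sigEmbeddings(x) else as.matrix(x)
  n <- nrow(emb)
  if (n < k + 1) stop("need at least k + 1 cells")
  cells <- rownames(emb) %||% sprintf("cell%d", seq_len(n))
  if (all(apply(emb, 2, function(cc) length(unique(cc)) == 1L))) {
    warning("degenerate embeddings (all cells identical): single cluster")
    return(methods::new("ClusterResult", labels = rep(0L, n), cells = cells,
                        snn = Matrix::Matrix(0, n, n, sparse = TRUE),
                        modularity = NA_real_, resolution = resolution,
                        k = as.integer(k), seed = as.integer(seed)))
  }
  nn <- knnExact(emb, emb, k = k - 1L, selfIndex = seq_len(n))
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = c(seq_len(n), as.vector(nn$index)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * k - shared@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  comm <- withSeed(seed, igraph::cluster_louvain(
    g, weights = igraph::E(g)$weight, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  methods::new("ClusterResult", labels = as.integer(labels), cells = cells,
               snn = jac, modularity = igraph::modularity(comm),
               resolution = resolution, k = as.integer(k),
               seed = as.integer(seed))
}

#' t-SNE layout of an embedding
#'
#' @param x a \linkS4class{PCAModel} (significant components) or a cells x
#'   dims matrix (e.g. IC scores).
#' @param perplexity t-SNE perplexity; must be below n_cells / 3.
#' @param seed RNG seed (layout is deterministic given the seed).
#' @param ... passed to \code{\link[Rtsne]{Rtsne}}.
#' @return a \linkS4class{TSNELayout}.
#' @export
embedTSNE <- function(x, perplexity = 30, seed = 42, ...) {
  emb <- if (is(x, "PCAModel")) sigEmbeddings(x) else as.matrix(x)
  if (ncol(emb) < 2L)
    stop("t-SNE needs at least 2 input dimensions; ",
         "supply a model with >= 2 components")
  if (perplexity >= nrow(emb) / 3)
    stop("perplexity must be below n_cells / 3")
  fit <- withSeed(seed, Rtsne::Rtsne(emb, perplexity = perplexity,
                                     pca = FALSE, check_duplicates = FALSE,
                                     num_threads = 1, ...))
  coords <- fit$Y
  rownames(coords) <- rownames(emb)
  colnames(coords) <- c("tSNE1", "tSNE2")
  methods::new("TSNELayout", coords = coords, perplexity = perplexity,
               seed = as.integer(seed))
}

#' Merge clusters into nodes by hierarchical clustering of centroids
#'
#' Cluster centroids are the per-cluster mean embeddings over significant
#' components; the centroid dendrogram (Euclidean distance, average linkage
#' by default) is cut into the requested number of groups, which become
#' nodes named "A", "B", ... in dendrogram leaf order.  The cut can be
#' restricted to a designated subset of clusters (the multi-cluster
#' complex); clusters outside the subset each keep a singleton node named
#' after themselves.
#'
#' @param model a \linkS4class{PCAModel} for the same cells.
#' @param clusters a \linkS4class{ClusterResult}.
#' @param nNodes number of node groups after the cut.
#' @param linkage agglomeration method (default "average").
#' @param restrictTo optional integer cluster labels forming the subtree to
#'   cut.
#' @return a \linkS4class{NodeTree}.
#' @export
mergeClustersToNodes <- function(model, clusters, nNodes,
                                 linkage = "average", restrictTo = NULL) {
  emb <- sigEmbeddings(model)
  labs <- clusters@labels
  stopifnot(nrow(emb) == length(labs))
  uniq <- sort(unique(labs))
  if (length(uniq) < 2L) stop("need at least 2 clusters")
  cent <- t(vapply(uniq, function(cl)
    colMeans(emb[labs == cl, , drop = FALSE]), numeric(ncol(emb))))
  rownames(cent) <- as.character(uniq)
  sub <- if (is.null(restrictTo)) uniq else intersect(uniq, restrictTo)
  if (nNodes > length(sub)) stop("nNodes exceeds the cluster count")
  hc <- hclust(dist(cent[as.character(sub), , drop = FALSE]),
               method = linkage)
  grp <- cutree(hc, k = nNodes)
  ## name nodes by order of first appearance along the dendrogram
  leafOrder <- hc$labels[hc$order]
  nodeOf <- grp[leafOrder]
  first <- nodeOf[!duplicated(nodeOf)]
  nodeName <- stats::setNames(LETTERS[seq_along(first)], first)
  assignment <- stats::setNames(nodeName[as.character(grp)], names(grp))
  extra <- setdiff(as.character(uniq), names(assignment))
  if (length(extra))
    assignment <- c(assignment,
                    stats::setNames(paste0("cluster", extra), extra))
  methods::new("NodeTree", dendrogram = hc,
               assignment = assignment[as.character(uniq)],
               linkage = linkage)
}

#' Export a node dendrogram as Newick
#' @param tree a \linkS4class{NodeTree}.
#' @param path output file.
#' @export
exportNodeTreeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree@dendrogram), file = path)
  invisible(path)
}

#' Per-cell node labels from a NodeTree
#' @param tree a \linkS4class{NodeTree}.
#' @param clusters a \linkS4class{ClusterResult}.
#' @return character node label per cell.
#' @export
nodeLabels <- function(tree, clusters) {
  unname(tree@assignment[as.character(clusters@labels)])
}
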