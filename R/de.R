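#' @include utils.R
NULL

## Per-gene log-likelihood of the zero-inflated bimodal model on a
## genes x cells block: a point mass at zero plus a log-scale normal
## component for positive values.  Vectorized over genes.  Variances are
## maximum-likelihood with a small floor for numerical stability.
.bimodLik <- function(m, varFloor = 1e-3) {
  m <- as.matrix(m)
  n <- ncol(m)
  pos <- m > 0
  n1 <- rowSums(pos)
  n0 <- n - n1
  p <- n1 / n
  s1 <- rowSums(m)
  s2 <- rowSums(m^2)
  mu <- ifelse(n1 > 0, s1 / n1, 0)
  v <- ifelse(n1 > 0, pmax(s2 / n1 - mu^2, varFloor), varFloor)
  llBin <- ifelse(n0 > 0, n0 * log(pmax(1 - p, .Machine$double.xmin)), 0) +
    ifelse(n1 > 0, n1 * log(pmax(p, .Machine$double.xmin)), 0)
  llNorm <- ifelse(n1 > 0, -n1 / 2 * (log(2 * pi * v) + 1), 0)
  llBin + llNorm
}

#' Bimodal likelihood-ratio differential expression test
#'
#' Models each gene's normalized expression as a mixture of a point mass at
#' zero and a log-scale normal component; the likelihood-ratio statistic
#' compares a pooled fit against separate per-group fits (expression
#' probability, positive-component mean and variance), referred to a
#' chi-squared distribution with 3 degrees of freedom.  The log fold-change
#' is the difference of group mean normalized expression (zeros included);
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param x a \linkS4class{SingleCellExperiment} with a \code{lognorm} assay
#'   or a genes x cells normalized matrix.
#' @param cellsA,cellsB column indices or names of the two groups.
#' @return data.frame with one row per gene: \code{logFC}, \code{pctA},
#'   \code{pctB}, \code{stat}, \code{p}, \code{padj}.
#' @export
deBimodLRT <- function(x, cellsA, cellsB) {
  norm <- getLogNorm(x)
  a <- as.matrix(norm[, cellsA, drop = FALSE])
  b <- as.matrix(norm[, cellsB, drop = FALSE])
  if (ncol(a) == 0L || ncol(b) == 0L) stop("both groups must be nonempty")
  llA <- .bimodLik(a)
  llB <- .bimodLik(b)
  llP <- .bimodLik(cbind(a, b))
  stat <- pmax(2 * (llA + llB - llP), 0)
  ## finite-sample (Bartlett-type) correction: the chi-squared reference is
  ## inflated by the plug-in variance fits, in proportion to the inverse
  ## expressed-cell counts of each group
  n1A <- pmax(rowSums(a > 0), 1)
  n1B <- pmax(rowSums(b > 0), 1)
  stat <- stat / (1 + 0.6 * (1 / n1A + 1 / n1B))
  p <- pchisq(stat, df = 3, lower.tail = FALSE)
  allZero <- rowSums(a) + rowSums(b) == 0
  p[allZero] <- 1
  out <- data.frame(
    gene = rownames(norm) %||% as.character(seq_len(nrow(norm))),
    logFC = rowMeans(a) - rowMeans(b),
    pctA = rowMeans(a > 0), pctB = rowMeans(b > 0),
    stat = stat, p = p, row.names = NULL)
  out$logFC[allZero] <- 0
  out$padj <- p.adjust(out$p, method = "BH")
  out
}

#' Heuristic doublet-cluster detection
#'
#' A doublet cluster's signature is significant differential expression of
#' many genes with low fold-change and a high expressing fraction in both
#' groups, simultaneously against both putative parent clusters.  For every
#' cluster and every candidate parent pair, the test counts genes with
#' adjusted p below \code{alpha}, |logFC| below \code{fcMax} and
#' min(pct) above \code{pctMin} in the comparison against each parent; the
#' cluster is flagged when both counts reach \code{nMin}.
#'
#' @param x normalized input (as in \code{\link{deBimodLRT}}).
#' @param clusters a \linkS4class{ClusterResult}.
#' @param nMin minimum qualifying genes against each parent (default 50).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @param fcMax low-fold-change ceiling (default 0.5).
#' @param pctMin expressing-fraction floor (default 0.25).
#' @param missMax maximum number of genes a putative parent may express
#'   broadly (pct > 0.6) that the candidate cluster lacks (pct < 0.4); a
#'   co-capture artifact contains a superset of each parent's transcripts
#'   (default 5).
#' @param orphanMax maximum number of genes the candidate expresses broadly
#'   that neither putative parent does - the parent pair must jointly
#'   account for the candidate's transcriptome (default 5).
#' @return data.frame of flagged clusters with the implicated parent pair
#'   and the qualifying gene counts (zero rows when nothing is flagged).
#' @export
detectDoubletClusters <- function(x, clusters, nMin = 50, alpha = 0.05,
                                  fcMax = 0.5, pctMin = 0.25,
                                  missMax = 5, orphanMax = 5) {
  norm <- getLogNorm(x)
  labs <- clusters@labels
  uniq <- sort(unique(labs))
  if (length(uniq) < 3L) stop("need at least 3 clusters")
  ## qualifying-gene count for every unordered cluster pair
  qual <- matrix(0L, length(uniq), length(uniq),
                 dimnames = list(as.character(uniq), as.character(uniq)))
  for (i in seq_along(uniq)) for (j in seq_along(uniq)) {
    if (i >= j) next
    de <- deBimodLRT(norm, which(labs == uniq[i]), which(labs == uniq[j]))
    ok <- de$padj < alpha & abs(de$logFC) < fcMax &
      pmin(de$pctA, de$pctB) > pctMin
    qual[i, j] <- qual[j, i] <- sum(ok)
  }
  ## per-cluster expressing fractions for the containment checks
  pct <- vapply(uniq, function(cl)
    Matrix::rowMeans(norm[, labs == cl, drop = FALSE] > 0),
    numeric(nrow(norm)))
  flags <- list()
  for (ci in seq_along(uniq)) {
    others <- setdiff(seq_along(uniq), ci)
    best <- NULL
    for (a in others) for (b in others) {
      if (a >= b) next
      score <- min(qual[ci, a], qual[ci, b])
      if (score < nMin) next
      ## the candidate must contain each parent's expressed genes, and the
      ## pair must jointly explain the candidate's
      ## thresholds leave headroom for ambient-driven background detection
      missA <- sum(pct[, a] > 0.6 & pct[, ci] < 0.4)
      missB <- sum(pct[, b] > 0.6 & pct[, ci] < 0.4)
      orphan <- sum(pct[, ci] > 0.6 & pct[, a] < 0.3 & pct[, b] < 0.3)
      if (missA > missMax || missB > missMax || orphan > orphanMax) next
      if (is.null(best) || score > best$score)
        best <- list(score = score, a = a, b = b)
    }
    if (!is.null(best))
      flags[[length(flags) + 1L]] <- data.frame(
        cluster = uniq[ci], parent1 = uniq[best$a], parent2 = uniq[best$b],
        nGenesParent1 = qual[ci, best$a], nGenesParent2 = qual[ci, best$b])
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(cluster = integer(), parent1 = integer(),
               parent2 = integer(), nGenesParent1 = integer(),
               nGenesParent2 = integer())
}

#' Marker-threshold cell-type labeling of clusters
#'
#' A cell is marker-positive when its normalized expression exceeds the
#' marker's threshold.  Each cluster receives the cell-type label whose
#' marker set has the highest mean positive fraction, provided that
#' fraction exceeds \code{minFraction}; otherwise "unassigned".
#'
#' @param x normalized input.
#' @param clusters a \linkS4class{ClusterResult}.
#' @param markerConfig data.frame with columns \code{gene},
#'   \code{threshold}, \code{cellType} (see \code{\link{readMarkerConfig}}).
#' @param minFraction minimum mean positive fraction (default 0.5).
#' @return named character vector, cluster label -> cell type; the matrix
#'   of per-cluster mean positive fractions is attached as attribute
#'   \code{"fractions"}.
#' @export
classifyCellTypes <- function(x, clusters, markerConfig,
                              minFraction = 0.5) {
  stopifnot(nrow(markerConfig) > 0)
  norm <- getLogNorm(x)
  missing <- !markerConfig$gene %in% rownames(norm)
  if (any(missing)) {
    warning("marker gene(s) absent from matrix, skipped: ",
            paste(markerConfig$gene[missing], collapse = ", "))
    markerConfig <- markerConfig[!missing, , drop = FALSE]
  }
  if (nrow(markerConfig) == 0L) stop("no usable marker genes")
  labs <- clusters@labels
  uniq <- sort(unique(labs))
  types <- unique(markerConfig$cellType)
  fr <- matrix(0, length(uniq), length(types),
               dimnames = list(as.character(uniq), types))
  for (ty in types) {
    mk <- markerConfig[markerConfig$cellType == ty, , drop = FALSE]
    posFrac <- vapply(uniq, function(cl) {
      cells <- which(labs == cl)
      mean(vapply(seq_len(nrow(mk)), function(r)
        mean(norm[mk$gene[r], cells] > mk$threshold[r]), 0))
    }, 0)
    fr[, ty] <- posFrac
  }
  lab <- apply(fr, 1, function(row) {
    if (max(row) > minFraction) colnames(fr)[which.max(row)] else
      "unassigned"
  })
  attr(lab, "fractions") <- fr
  lab
}

#' Read a marker configuration YAML
#'
#' Expected layout: a mapping cell type -> list of \code{gene}/
#' \code{threshold} pairs.
#'
#' @param path YAML file.
#' @return data.frame(gene, threshold, cellType).
#' @export
readMarkerConfig <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y), function(ty)
    data.frame(gene = vapply(y[[ty]], `[[`, "", "gene"),
               threshold = vapply(y[[ty]], function(e)
                 as.numeric(e$threshold), 0),
               cellType = ty, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
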