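#' @include AllClasses.R utils.R reduce.R
NULL

#' Independent component analysis of a (tumor) cell subset
#'
#' Runs fixed-point negentropy ICA (logcosh contrast, deflation) on a
#' variable genes x cells expression block, z-scaled per gene.  When
#' \code{nComponents = "auto"} the component count equals the number of
#' significant principal components (variance z-score above 2) of the same
#' input, mirroring the PCA-based dimensionality estimate.  Components are
#' sign-oriented so the heavier tail (skew) of each gene-weight vector is
#' positive, and cell scores are scaled to unit sample variance.
#'
#' @param x a \linkS4class{SingleCellExperiment} with a \code{lognorm}
#'   assay or a genes x cells normalized matrix, already restricted to the
#'   subset of interest (e.g. stromal clusters removed).
#' @param genes variable genes; \code{NULL} re-selects them on this subset
#'   with \code{\link{selectVariableGenes}} defaults.
#' @param nComponents "auto" or a positive integer.
#' @param seed RNG seed (ICA initialization).
#' @param nTail size of the stored top-gene tails (default 50).
#' @return an \linkS4class{ICAModel}.
#' @export
fitICA <- function(x, genes = NULL, nComponents = "auto", seed = 42,
                   nTail = 50) {
  norm <- getLogNorm(x)
  if (is.null(genes)) genes <- selectVariableGenes(norm)$genes
  if (inherits(genes, "VariableGeneSelection")) genes <- genes$genes
  X <- as.matrix(Matrix::t(norm[genes, , drop = FALSE]))
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  X <- X[, keep, drop = FALSE]
  genes <- genes[keep]
  X <- scale(X)
  nc <- if (identical(nComponents, "auto")) {
    sv <- svd(X, nu = 0, nv = 0)
    v <- sv$d^2 / max(nrow(X) - 1, 1)
    length(which(.pcZScores(v) > 2))
  } else as.integer(nComponents)
  if (is.na(nc) || nc < 1L)
    stop("nComponents must be >= 1 (auto found no significant dimension)")
  fit <- withSeed(seed, ica::icafast(X, nc = nc, center = TRUE,
                                     alg = "def", fun = "logcosh"))
  S <- fit$S; M <- fit$M
  ## orient: heavier weight tail positive; scale scores to unit variance
  for (j in seq_len(nc)) {
    w <- M[, j]
    sk <- mean((w - mean(w))^3)
    if (sk < 0) { S[, j] <- -S[, j]; M[, j] <- -M[, j] }
    s <- sd(S[, j])
    if (s > 0) { M[, j] <- M[, j] * s; S[, j] <- S[, j] / s }
  }
  rownames(S) <- rownames(X)
  rownames(M) <- genes
  colnames(S) <- colnames(M) <- paste0("IC", seq_len(nc))
  nTail <- min(as.integer(nTail), length(genes))
  topPos <- lapply(seq_len(nc), function(j)
    genes[order(M[, j], decreasing = TRUE)[seq_len(nTail)]])
  topNeg <- lapply(seq_len(nc), function(j)
    genes[order(M[, j])[seq_len(nTail)]])
  methods::new("ICAModel", scores = S, weights = M, topPos = topPos,
               topNeg = topNeg, nTail = nTail, seed = as.integer(seed))
}

#' Identify the differentiation component of an ICA model
#'
#' For each component and orientation, the enrichment score is the number
#' of differentiation markers in the top-\code{nTail} positive weight tail
#' minus the number in the negative tail (optionally penalized by
#' proliferation markers enriched the same way).  Returns the component
#' and orientation maximizing the score; ties go to the lower component
#' index.  With the returned orientation, cell scores increase with
#' differentiation.
#'
#' @param model an \linkS4class{ICAModel}.
#' @param diffMarkers differentiation marker genes.
#' @param prolifMarkers optional proliferation markers (expected in the
#'   opposite tail).
#' @return list with \code{component}, \code{orientation} (+1/-1),
#'   \code{scores} (component x orientation matrix) and \code{cellScores}
#'   (the oriented score vector of the selected component).
#' @export
identifyDifferentiationIC <- function(model, diffMarkers,
                                      prolifMarkers = NULL) {
  stopifnot(length(diffMarkers) > 0)
  genes <- rownames(model@weights)
  if (!any(diffMarkers %in% genes) &&
      !any(prolifMarkers %in% genes))
    stop("no marker present in the weight matrix")
  nc <- ncol(model@weights)
  sc <- matrix(NA_real_, nc, 2, dimnames = list(NULL, c("+", "-")))
  enr <- function(pos, neg) {
    s <- sum(diffMarkers %in% pos) - sum(diffMarkers %in% neg)
    if (length(prolifMarkers))
      s <- s + sum(prolifMarkers %in% neg) - sum(prolifMarkers %in% pos)
    s
  }
  for (j in seq_len(nc)) {
    sc[j, 1] <- enr(model@topPos[[j]], model@topNeg[[j]])
    sc[j, 2] <- enr(model@topNeg[[j]], model@topPos[[j]])
  }
  if (max(sc) <= 0 && all(sc == 0))
    stop("no component contains any marker in either tail")
  best <- which(sc == max(sc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  orientation <- if (best[2] == 1L) 1 else -1
  list(component = unname(best[1]), orientation = orientation,
       scores = sc,
       cellScores = orientation * model@scores[, best[1]])
}

#' Cell-cycle phase scoring from phase gene lists
#'
#' Per-cell phase score = mean of z-scored (across cells) expression of the
#' phase list's genes; the assigned phase is the argmax, and cells whose
#' scores are all negative are called "low-cycling".
#'
#' @param x normalized input.
#' @param phaseGenes named list of gene vectors, one per phase.
#' @return list with \code{scores} (cells x phases) and \code{phase}
#'   (character per cell).
#' @export
scoreCellCycle <- function(x, phaseGenes) {
  norm <- as.matrix(getLogNorm(x))
  scores <- vapply(names(phaseGenes), function(ph) {
    g <- intersect(phaseGenes[[ph]], rownames(norm))
    if (length(g) == 0L)
      stop("phase gene list '", ph, "' is empty after intersection")
    z <- t(scale(t(norm[g, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    colMeans(z)
  }, numeric(ncol(norm)))
  rownames(scores) <- colnames(norm)
  phase <- colnames(scores)[max.col(scores, ties.method = "first")]
  ## a cell with no positive phase score (e.g. all-identical input, where
  ## every z-score degenerates to 0) is not assigned a phase
  phase[apply(scores, 1, max) <= 0] <- "low-cycling"
  list(scores = scores, phase = stats::setNames(phase, colnames(norm)))
}

#' t-SNE layout of IC cell scores
#' @param model an \linkS4class{ICAModel} with at least 2 components.
#' @inheritParams embedTSNE
#' @return a \linkS4class{TSNELayout}.
#' @export
icTSNE <- function(model, perplexity = 30, seed = 42, ...) {
  if (ncol(model@scores) < 2L)
    stop("t-SNE needs >= 2 components; refit the ICA with nComponents >= 2")
  embedTSNE(model@scores, perplexity = perplexity, seed = seed, ...)
}

#' Default cell-cycle phase gene lists
#'
#' Reads the canonical phase gene resource shipped with the package
#' (\code{inst/extdata/cell_cycle_phases.yaml}); supply your own YAML of the
#' same shape for organism- or chemistry-specific lists.
#'
#' @param path optional path to an alternative YAML file.
#' @return named list of gene vectors, one per phase.
#' @export
defaultPhaseGenes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cell_cycle_phases.yaml",
                        package = "nodescope")
  yaml::read_yaml(path)
}
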