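#' @include AllClasses.R utils.R reduce.R
NULL

#' Build a diffusion operator over cells
#'
#' Finds each cell's k nearest neighbors (Euclidean, significant-PC space;
#' the cell itself is always included in its neighborhood), applies an
#' adaptive Gaussian kernel whose per-cell bandwidth is the distance to
#' the ceiling(k/3)-th neighbor, symmetrizes the affinity matrix and
#' row-normalizes it into a stochastic transition matrix.  Cells whose
#' bandwidth is zero (duplicated points) get uniform affinity over their
#' neighborhood.
#'
#' @param x a \linkS4class{PCAModel} (significant components) or a cells x
#'   dims embedding matrix.
#' @param k neighbor count, excluding self (default 12).
#' @return a \linkS4class{DiffusionOperator}.
#' @export
buildDiffusionOperator <- function(x, k = 12) {
  emb <- if (is(x, "PCAModel")) sigEmbeddings(x) else as.matrix(x)
  n <- nrow(emb)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must be in [1, n_cells - 1]")
  nn <- knnExact(emb, emb, k = k, selfIndex = seq_len(n))
  bwIdx <- ceiling(k / 3)
  sigma <- nn$dist[, bwIdx]
  i <- rep(seq_len(n), k + 1L)
  j <- c(seq_len(n), as.vector(nn$index))
  d <- c(rep(0, n), as.vector(nn$dist))
  sig <- sigma[i]
  a <- ifelse(sig > 0, exp(-(d / sig)^2), 1)
  A <- Matrix::sparseMatrix(i = i, j = j, x = a, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  P <- A / Matrix::rowSums(A)
  P <- methods::as(P, "CsparseMatrix")
  dimnames(P) <- list(rownames(emb), rownames(emb))
  methods::new("DiffusionOperator", P = P, k = k,
               bandwidthRule = sprintf(
                 "adaptive Gaussian, bandwidth = distance to neighbor %d",
                 bwIdx))
}

#' Diffuse (impute) expression values across similar cells
#'
#' imputed = P^t x values.  t = 0 returns the input unchanged; constant
#' genes are preserved for any t (row-stochastic operators fix constants).
#'
#' @param operator a \linkS4class{DiffusionOperator}.
#' @param values a genes x cells matrix (or a named vector over cells).
#' @param t nonnegative integer diffusion step count (default 3).
#' @return imputed values, same shape as the input.
#' @export
imputeExpression <- function(operator, values, t = 3) {
  if (t < 0 || t != round(t)) stop("t must be a nonnegative integer")
  vec <- is.null(dim(values))
  M <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(M) != nrow(operator@P))
    stop("values must cover the operator's cells")
  Pt <- Matrix::t(operator@P)
  for (s in seq_len(t)) M <- as.matrix(M %*% Pt)
  if (vec) stats::setNames(drop(M), names(values)) else M
}

#' Pearson correlation with t-distribution hypothesis test
#'
#' t = r * sqrt((n - 2) / (1 - r^2)), two-sided p on n - 2 df.
#'
#' @param x,y numeric vectors over the same cells (n >= 3).
#' @param arm optional arm label carried into the result.
#' @return list(r, t, p, n, arm, degenerate); a zero-variance input gives
#'   an NA correlation flagged via \code{degenerate}.
#' @export
correlateGenes <- function(x, y, arm = NA_character_) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = n,
                arm = arm, degenerate = TRUE))
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, t = tt, p = p, n = n, arm = arm, degenerate = FALSE)
}

#' ANCOVA treatment-interaction test for a gene pair
#'
#' Fits y ~ x * arm over cells and reports per-arm slopes and the
#' interaction F-test.  Cells are the observations, mirroring the source
#' analysis; the result carries an explicit pseudo-replication caveat
#' (cells within an animal are not independent).
#'
#' @param x,y numeric vectors (e.g. imputed expression of a regulator and
#'   a target gene).
#' @param arms per-cell arm labels (>= 2 arms, >= 3 cells each).
#' @return list(slopes, interactionF, interactionP, caveat).
#' @export
ancovaInteraction <- function(x, y, arms) {
  arm <- factor(arms)
  if (nlevels(arm) < 2L) stop("need at least 2 arms")
  if (any(tabulate(arm) < 3L)) stop("need at least 3 cells per arm")
  fit <- lm(y ~ x * arm)
  an <- anova(fit)
  row <- grep(":", rownames(an))
  slopes <- vapply(levels(arm), function(a) {
    unname(coef(lm(y[arm == a] ~ x[arm == a]))[2])
  }, 0)
  list(slopes = slopes,
       interactionF = an$`F value`[row],
       interactionP = an$`Pr(>F)`[row],
       caveat = paste("cells treated as independent observations;",
                      "within-animal correlation is not modeled"))
}
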