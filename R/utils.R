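#' @include AllClasses.R
NULL

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive a stage-specific seed from a global seed, kept inside 32-bit range.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

## Exact Euclidean k-nearest neighbours of the rows of `query` among the rows
## of `ref`, computed in chunks from the full distance decomposition
## |q - r|^2 = |q|^2 + |r|^2 - 2 q.r.  Ties are broken by reference row index
## (ascending), which makes results deterministic.  Set `selfIndex` to the
## matching reference row per query to exclude self-matches.
knnExact <- function(ref, query, k, selfIndex = NULL, chunk = 512L) {
  ref <- as.matrix(ref); query <- as.matrix(query)
  stopifnot(ncol(ref) == ncol(query), k >= 1L, k <= nrow(ref))
  nq <- nrow(query)
  refSq <- rowSums(ref^2)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  starts <- seq(1L, nq, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nq)
    qs <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(qs^2), refSq, "+") - 2 * tcrossprod(qs, ref)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(d2))) {
      di <- d2[i, ]
      if (!is.null(selfIndex)) di[selfIndex[s + i - 1L]] <- Inf
      ord <- order(di, seq_along(di))[seq_len(k)]
      idx[s + i - 1L, ] <- ord
      dst[s + i - 1L, ] <- sqrt(di[ord])
    }
  }
  list(index = idx, dist = dst)
}

## Counts accessor tolerant of plain matrices and SingleCellExperiment.
getCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

## Log-normalized accessor: requires normalizeLog() to have been run.
getLogNorm <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
      stop("no 'lognorm' assay: run normalizeLog() first")
    SummarizedExperiment::assay(x, "lognorm")
  } else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
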