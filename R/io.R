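#' @include utils.R
NULL

## Gene annotations from identifier conventions: a foreign-species prefix,
## the "mt-" mitochondrial prefix, and named transgenes.
annotateGenes <- function(ids, humanPrefix = "HUM", transgenes = "Yfp") {
  S4Vectors::DataFrame(
    species = ifelse(startsWith(ids, humanPrefix), "human", "mouse"),
    mito = startsWith(ids, "mt-"),
    transgene = ids %in% transgenes,
    row.names = ids)
}

#' Read a digital gene expression matrix
#'
#' Supports the dense TSV dialect (genes as rows, first column \code{gene},
#' header row of barcodes) and the MatrixMarket triplet dialect (a directory
#' holding \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}).  Gene
#' annotations come from the sidecar files when present, otherwise from
#' identifier conventions (foreign-species prefix, \code{mt-} prefix,
#' transgene names).
#'
#' @param path file (dense) or directory (mtx).
#' @param dialect \code{"dense"} or \code{"mtx"}.
#' @param humanPrefix,transgenes identifier conventions used when no sidecar
#'   annotations are available.
#' @return a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @export
readDGE <- function(path, dialect = c("dense", "mtx"),
                    humanPrefix = "HUM", transgenes = "Yfp") {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 1L || names(tab)[1] != "gene")
      stop("malformed header in ", path, ": first column must be 'gene'")
    ids <- tab[[1]]
    if (anyDuplicated(ids))
      stop("duplicate gene identifier: ", ids[duplicated(ids)][1])
    bcs <- names(tab)[-1]
    if (anyDuplicated(bcs))
      stop("duplicate barcode: ", bcs[duplicated(bcs)][1])
    m <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("negative or non-integer count at gene ", ids[bad[1, 1]],
           ", barcode ", bcs[bad[1, 2]])
    rownames(m) <- ids
    counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    rd <- annotateGenes(ids, humanPrefix, transgenes)
    cd <- S4Vectors::DataFrame(row.names = bcs)
  } else {
    counts <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")),
                          "CsparseMatrix")
    g <- read.delim(file.path(path, "genes.tsv"), stringsAsFactors = FALSE)
    b <- read.delim(file.path(path, "barcodes.tsv"), stringsAsFactors = FALSE)
    if (anyDuplicated(g$id))
      stop("duplicate gene identifier: ", g$id[duplicated(g$id)][1])
    if (anyDuplicated(b$barcode))
      stop("duplicate barcode: ", b$barcode[duplicated(b$barcode)][1])
    if (nrow(g) != nrow(counts) || nrow(b) != ncol(counts))
      stop("sidecar dimensions do not match matrix.mtx")
    if (any(counts@x < 0 | counts@x != round(counts@x)))
      stop("negative or non-integer counts in matrix.mtx")
    dimnames(counts) <- list(g$id, b$barcode)
    rd <- if (all(c("species", "mito", "transgene") %in% names(g)))
      S4Vectors::DataFrame(species = g$species, mito = as.logical(g$mito),
                           transgene = as.logical(g$transgene),
                           row.names = g$id)
    else annotateGenes(g$id, humanPrefix, transgenes)
    cd <- S4Vectors::DataFrame(row.names = b$barcode)
    for (col in setdiff(names(b), "barcode")) cd[[col]] <- b[[col]]
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Write a digital gene expression matrix
#'
#' Inverse of \code{\link{readDGE}}: dense TSV (one file) or MatrixMarket
#' triplets plus \code{genes.tsv}/\code{barcodes.tsv} sidecars (a directory).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param path output file (dense) or directory (mtx; created if needed).
#' @param dialect \code{"dense"} or \code{"mtx"}.
#' @export
writeDGE <- function(sce, path, dialect = c("dense", "mtx")) {
  dialect <- match.arg(dialect)
  counts <- getCounts(sce)
  if (dialect == "dense") {
    tab <- data.frame(gene = rownames(counts), as.matrix(counts),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    rd <- SummarizedExperiment::rowData(sce)
    g <- data.frame(id = rownames(counts),
                    species = rd$species %||% rep("mouse", nrow(counts)),
                    mito = rd$mito %||% startsWith(rownames(counts), "mt-"),
                    transgene = rd$transgene %||% rep(FALSE, nrow(counts)))
    write.table(g, file.path(path, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cd <- SummarizedExperiment::colData(sce)
    b <- data.frame(barcode = colnames(counts))
    for (col in names(cd)) b[[col]] <- cd[[col]]
    write.table(b, file.path(path, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write simulation ground truth as TSV
#' @param truth the ground-truth \code{DataFrame} from
#'   \code{\link{simulateCohort}}.
#' @param path output TSV path.
#' @export
writeGroundTruth <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
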