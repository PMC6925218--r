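#' @include utils.R
NULL

#' Quality-control thresholds
#'
#' Inclusion criteria for barcodes and genes.  Barcodes need more than
#' \code{minUMIs} total counts and more than \code{minGenes} detected genes;
#' barcodes more than \code{sdMultiplier} standard deviations above the
#' per-batch median total counts or detected genes, or whose mitochondrial
#' count fraction is more than \code{mitoSdMultiplier} SD above its median,
#' are excluded.  The SD multipliers conventionally lie between 4 and 5
#' (default 4.5); the center is the median and the spread the classical SD
#' about the mean by default, both configurable.
#'
#' @param minUMIs,minGenes lower content floors (strict: a barcode at the
#'   floor is removed).
#' @param sdMultiplier,mitoSdMultiplier upper outlier multipliers.
#' @param speciesPurity minimum target-species count fraction (strict).
#' @param minCellsPerGene detection floor for genes.
#' @param center "median" (default) or "mean".
#' @return a validated \code{QCThresholds} list.
#' @export
qcThresholds <- function(minUMIs = 500, minGenes = 500, sdMultiplier = 4.5,
                         mitoSdMultiplier = 4.5, speciesPurity = 0.90,
                         minCellsPerGene = 30,
                         center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(minUMIs > 0, minGenes > 0, sdMultiplier > 0,
            mitoSdMultiplier > 0, minCellsPerGene >= 0,
            speciesPurity > 0, speciesPurity <= 1)
  structure(list(minUMIs = minUMIs, minGenes = minGenes,
                 sdMultiplier = sdMultiplier,
                 mitoSdMultiplier = mitoSdMultiplier,
                 speciesPurity = speciesPurity,
                 minCellsPerGene = minCellsPerGene, center = center),
            class = "QCThresholds")
}

#' Species-purity (barnyard) filter
#'
#' Keeps barcodes whose target-species count fraction strictly exceeds
#' \code{purity} (a barcode at exactly the threshold is removed), then drops
#' the foreign-species gene rows.  With fewer than two species among the
#' genes the filter is a no-op with a warning.
#'
#' @param sce a \linkS4class{SingleCellExperiment} whose rowData has a
#'   \code{species} column.
#' @param purity fraction in (0, 1]; default 0.90.
#' @param targetSpecies species to retain; default "mouse".
#' @return list with the filtered \code{sce} and a \code{report} fragment
#'   (input/kept/removed barcode counts, dropped foreign genes).
#' @export
speciesPurityFilter <- function(sce, purity = 0.90,
                                targetSpecies = "mouse") {
  species <- SummarizedExperiment::rowData(sce)$species
  if (length(unique(species)) < 2L) {
    warning("fewer than 2 species among genes; species filter is a no-op")
    return(list(sce = sce,
                report = list(input = ncol(sce), kept = ncol(sce),
                              removedSpecies = 0L, foreignGenesDropped = 0L)))
  }
  counts <- getCounts(sce)
  tot <- Matrix::colSums(counts)
  tgt <- Matrix::colSums(counts[species == targetSpecies, , drop = FALSE])
  frac <- ifelse(tot > 0, tgt / tot, 0)
  keep <- frac > purity
  out <- sce[species == targetSpecies, keep]
  list(sce = out,
       report = list(input = ncol(sce), kept = sum(keep),
                     removedSpecies = sum(!keep),
                     foreignGenesDropped = sum(species != targetSpecies)))
}

## Per-batch QC metrics for one metric vector: removal above
## center + mult * SD (SD about the mean; degenerate SD = 0 removes nobody
## because the comparison is strict).
.upperOutlier <- function(x, mult, center) {
  ctr <- if (center == "median") median(x) else mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  x > ctr + mult * s
}

#' Barcode-level quality-control filter
#'
#' Applies the content floors and per-batch outlier criteria of
#' \code{\link{qcThresholds}}.  Median and SD are computed per batch (one
#' animal's sample) over all input barcodes of that batch.  Criteria are
#' attributed sequentially for reporting: low content (UMIs or genes), high
#' content, high mitochondrial fraction.
#'
#' @param sce a \linkS4class{SingleCellExperiment}; colData column
#'   \code{animal} defines batches (a single batch is assumed if absent).
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return list with the filtered \code{sce} and a \code{QCReport} list:
#'   removal counts per criterion, input/output sizes, pass fraction and
#'   per-animal cell counts.
#' @export
qcFilterCells <- function(sce, thresholds = qcThresholds()) {
  if (ncol(sce) == 0L) stop("empty matrix: no barcodes to filter")
  counts <- getCounts(sce)
  total <- Matrix::colSums(counts)
  nGene <- Matrix::colSums(counts > 0)
  mitoRows <- SummarizedExperiment::rowData(sce)$mito
  mitoFrac <- if (is.null(mitoRows) || !any(mitoRows)) rep(0, ncol(sce)) else
    ifelse(total > 0,
           Matrix::colSums(counts[mitoRows, , drop = FALSE]) / total, 0)
  batch <- SummarizedExperiment::colData(sce)$animal
  if (is.null(batch)) batch <- rep("batch1", ncol(sce))

  lowContent <- total <= thresholds$minUMIs | nGene <= thresholds$minGenes
  highContent <- highMito <- rep(FALSE, ncol(sce))
  for (b in unique(batch)) {
    i <- which(batch == b)
    highContent[i] <-
      .upperOutlier(total[i], thresholds$sdMultiplier, thresholds$center) |
      .upperOutlier(nGene[i], thresholds$sdMultiplier, thresholds$center)
    highMito[i] <- .upperOutlier(mitoFrac[i], thresholds$mitoSdMultiplier,
                                 thresholds$center)
  }
  remove <- lowContent | highContent | highMito
  if (all(remove))
    stop("all barcodes removed: QC thresholds appear misconfigured")
  ## sequential attribution for the report
  attLow <- lowContent
  attHigh <- highContent & !attLow
  attMito <- highMito & !attLow & !attHigh
  out <- sce[, !remove]
  report <- list(
    input = ncol(sce), output = ncol(out),
    removedLowContent = sum(attLow), removedHighContent = sum(attHigh),
    removedHighMito = sum(attMito),
    passFraction = ncol(out) / ncol(sce),
    perAnimal = table(batch[!remove]))
  class(report) <- "QCReport"
  list(sce = out, report = report)
}

#' Gene detection floor
#'
#' Keeps genes detected (count > 0) in at least \code{minCells} barcodes.
#' Transgene-flagged genes are exempt: lineage calls need them even when
#' rare.
#'
#' @param sce a \linkS4class{SingleCellExperiment}.
#' @param minCells detection floor (default 30).
#' @return the filtered \code{SingleCellExperiment}.
#' @export
filterGenes <- function(sce, minCells = 30) {
  counts <- getCounts(sce)
  detected <- Matrix::rowSums(counts > 0)
  tg <- SummarizedExperiment::rowData(sce)$transgene
  if (is.null(tg)) tg <- rep(FALSE, nrow(sce))
  sce[detected >= minCells | tg, ]
}

#' Per-cell scaling and log transformation
#'
#' value = log(1 + count * scaleTotal / barcodeTotal).  Zero counts map to
#' zero; the result is invariant to scaling all counts of a barcode.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with no zero-total
#'   barcode (guaranteed after QC).
#' @param scaleTotal per-cell scale target (default 1e4).
#' @return the \code{sce} with an added \code{lognorm} assay and
#'   normalization metadata.
#' @export
normalizeLog <- function(sce, scaleTotal = 1e4) {
  counts <- methods::as(getCounts(sce), "CsparseMatrix")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("zero-total barcode: run QC before normalizing")
  norm <- counts
  norm@x <- log1p(norm@x * scaleTotal /
                  rep.int(total, diff(norm@p)))
  SummarizedExperiment::assay(sce, "lognorm") <- norm
  S4Vectors::metadata(sce)$normalization <-
    list(scaleTotal = scaleTotal, log = "natural", offset = 1)
  sce
}

#' Full QC sequence: species purity, cell QC, gene floor
#'
#' Convenience wrapper applying the filters in their canonical order and
#' reconciling the report.
#'
#' @inheritParams qcFilterCells
#' @param targetSpecies species retained by the purity filter.
#' @return list(sce, report).
#' @export
runQC <- function(sce, thresholds = qcThresholds(),
                  targetSpecies = "mouse") {
  sp <- speciesPurityFilter(sce, thresholds$speciesPurity, targetSpecies)
  qc <- qcFilterCells(sp$sce, thresholds)
  out <- filterGenes(qc$sce, thresholds$minCellsPerGene)
  report <- qc$report
  report$removedSpecies <- sp$report$removedSpecies
  report$input <- sp$report$input
  report$passFraction <- ncol(out) / sp$report$input
  report$inputGenes <- nrow(sce)
  report$outputGenes <- nrow(out)
  list(sce = out, report = report)
}
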