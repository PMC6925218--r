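test_that("DGE round trips are lossless in both dialects", {
  co <- discreteCohort(2, nPer = 15)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "dge.tsv")
  writeDGE(co$sim$sce, f, "dense")
  back <- readDGE(f, "dense")
  expect_identical(as.matrix(getCounts(back)),
                   as.matrix(getCounts(co$sim$sce)))
  d <- file.path(dir, "mtx")
  writeDGE(co$sim$sce, d, "mtx")
  back2 <- readDGE(d, "mtx")
  expect_identical(as.matrix(getCounts(back2)),
                   as.matrix(getCounts(co$sim$sce)))
  expect_identical(
    as.character(SummarizedExperiment::colData(back2)$animal),
    as.character(SummarizedExperiment::colData(co$sim$sce)$animal))
})

test_that("dense parsing computes the stated layout and rejects bad input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "tiny.tsv")
  writeLines(c("gene\tbc1\tbc2", "g1\t0\t0", "g2\t1\t2", "g3\t5\t7"), f)
  sce <- readDGE(f, "dense")
  ## genes are rows: column sums are per-barcode totals
  expect_equal(unname(Matrix::colSums(getCounts(sce))), c(6, 9))
  writeLines(c("gene\tbc1", "g1\t1", "g1\t2"), f)
  expect_error(readDGE(f, "dense"), "duplicate gene")
  writeLines(c("gene\tbc1", "g1\t-1"), f)
  expect_error(readDGE(f, "dense"), "negative")
})

test_that("species purity keeps only barcodes strictly above the cutoff", {
  m <- matrix(c(95, 90, 100,
                 5, 10,   0), nrow = 2, byrow = TRUE,
              dimnames = list(c("mG", "HUM1"),
                              c("mostlyMouse", "boundary", "pure")))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(species = c("mouse", "human"),
                                   mito = FALSE, transgene = FALSE,
                                   row.names = rownames(m)))
  out <- speciesPurityFilter(sce, purity = 0.90)
  ## 95% mouse kept; exactly 90% removed (strict inequality); pure kept
  expect_identical(colnames(out$sce), c("mostlyMouse", "pure"))
  ## foreign gene rows dropped after filtering
  expect_identical(rownames(out$sce), "mG")
  expect_equal(out$report$removedSpecies, 1L)
})

test_that("pure foreign spike-ins are all removed from the cohort", {
  co <- studyCohort(11)
  sp <- speciesPurityFilter(co$sim$sce)
  kept <- co$sim$truth[match(colnames(sp$sce), co$sim$truth$barcode), ]
  expect_equal(sum(kept$species == "human"), 0L)
})

test_that("cell QC removes the engineered violations and reconciles", {
  sce <- qcFixture()
  res <- qcFilterCells(sce, qcThresholds(sdMultiplier = 4,
                                         mitoSdMultiplier = 4))
  expect_equal(ncol(res$sce), 16L)
  expect_true(all(startsWith(colnames(res$sce), "clean")))
  rep <- res$report
  expect_equal(rep$removedLowContent, 2L)
  expect_equal(rep$removedHighContent, 1L)
  expect_equal(rep$removedHighMito, 1L)
  expect_equal(rep$input - rep$removedLowContent - rep$removedHighContent -
               rep$removedHighMito, rep$output)
  expect_equal(rep$passFraction, 16 / 20)
})

test_that("boundary and degenerate QC cases follow the stated rules", {
  ## barcode with 499 total counts is removed by the UMI floor
  sce <- qcFixture()
  m <- as.matrix(getCounts(sce))
  m[, "lowUMI"] <- 0L
  m[seq_len(499), "lowUMI"] <- 1L  # 499 counts over 499 genes
  sce2 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
    rowData = SummarizedExperiment::rowData(sce),
    colData = SummarizedExperiment::colData(sce))
  res <- qcFilterCells(sce2, qcThresholds(sdMultiplier = 4,
                                          mitoSdMultiplier = 4))
  expect_false("lowUMI" %in% colnames(res$sce))
  ## identical barcodes (SD = 0) with totals above the floor are all kept
  mm <- matrix(2L, nrow = 600, ncol = 10,
               dimnames = list(rownames(m), sprintf("b%02d", 1:10)))
  sceEq <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(mm, sparse = TRUE)),
    rowData = SummarizedExperiment::rowData(sce))
  resEq <- qcFilterCells(sceEq, qcThresholds())
  expect_equal(ncol(resEq$sce), 10L)
  expect_error(qcFilterCells(sceEq[, 0]), "empty")
})

test_that("gene floor keeps well-detected and transgene genes only", {
  n <- 40
  m <- matrix(0L, nrow = 3, ncol = n,
              dimnames = list(c("g29", "g30", "Yfp"), sprintf("b%02d", 1:n)))
  m["g29", 1:29] <- 1L
  m["g30", 1:30] <- 1L
  m["Yfp", 1:5] <- 1L
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(species = "mouse", mito = FALSE,
                                   transgene = c(FALSE, FALSE, TRUE),
                                   row.names = rownames(m)))
  out <- filterGenes(sce, minCells = 30)
  expect_identical(rownames(out), c("g30", "Yfp"))
  expect_identical(rownames(filterGenes(sce, minCells = 0)), rownames(sce))
})

test_that("log normalization follows the formula and is scale invariant", {
  m <- matrix(c(10, 20,
                 9990, 19980), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)))
  norm <- getLogNorm(normalizeLog(sce, scaleTotal = 10000))
  expect_equal(norm["a", "c1"], log(11))
  ## doubling every count of a barcode leaves its normalized vector unchanged
  expect_equal(as.numeric(norm[, "c2"]), as.numeric(norm[, "c1"]))
  ## zero maps to zero
  m3 <- m; m3["a", "c2"] <- 0
  sce3 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m3, sparse = TRUE)))
  expect_equal(getLogNorm(normalizeLog(sce3))["a", "c2"], 0)
  m0 <- m; m0[, 1] <- 0
  sce0 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m0, sparse = TRUE)))
  expect_error(normalizeLog(sce0), "zero-total")
})

test_that("QC on the synthetic cohort removes stressed cells, not clean ones", {
  co <- studyCohort(11)
  truth <- co$sim$truth
  q <- suppressWarnings(runQC(co$sim$sce, panelThresholds()))
  kept <- colnames(q$sce)
  ## injected high-mito (stressed-tail) barcodes are almost all removed
  hi <- !truth$isDoublet & truth$species == "mouse" &
    truth$mitoFraction > 0.35
  expect_gte(mean(!(truth$barcode[hi] %in% kept)), 0.95)
  ## clean mid-distribution barcodes are never removed by the mito criterion
  mid <- !truth$isDoublet & truth$species == "mouse" &
    truth$mitoFraction < 0.15 &
    abs(truth$librarySize - 2000) < 800
  lost <- truth$barcode[mid][!(truth$barcode[mid] %in% kept)]
  lostGenes <- Matrix::colSums(getCounts(co$sim$sce)[, lost, drop = FALSE] > 0)
  ## any lost clean barcode fell to the content floors, not the mito rule
  expect_true(all(lostGenes <= 150 |
                  truth[lost, "librarySize"] <= 500))
})
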