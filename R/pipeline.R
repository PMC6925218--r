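#' @include utils.R simulate.R qc.R reduce.R de.R projection.R ica.R
#' @include popstats.R impute.R
NULL

.pipelineDefaults <- function() {
  list(
    stages = c("simulate", "qc", "cluster", "project", "ica", "stats",
               "correlate"),
    seed = 1L,
    sim = list(),
    qc = list(minUMIs = 500, minGenes = 150, sdMultiplier = 4.5,
              mitoSdMultiplier = 4.5, speciesPurity = 0.90,
              minCellsPerGene = 30),
    cluster = list(k = 30, resolution = 0.8, perplexity = 30,
                   nNodes = 3, excludePCs = integer()),
    project = list(K = 5, referenceArm = NULL),
    ica = list(nComponents = "auto"),
    stats = list(),
    correlate = list(k = 12, t = 3, genes = c("RegA", "TargB")),
    markerFile = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, collects every
#' validation error rather than stopping at the first, and warns about
#' legal-but-unusual values (e.g. an SD multiplier outside the
#' conventional 4-5 range).
#'
#' @param config path to a YAML file, or a list.
#' @return the normalized configuration list (class
#'   \code{PipelineConfig}); validation warnings are emitted, and any
#'   collected errors raise a single combined error.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  def <- .pipelineDefaults()
  if (length(config) == 0L)
    warning("empty configuration: using defaults throughout")
  unknown <- setdiff(names(config), names(def))
  cfg <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  errors <- character()
  if (length(unknown))
    errors <- c(errors, paste("unknown configuration block(s):",
                              paste(unknown, collapse = ", ")))
  badStages <- setdiff(cfg$stages, def$stages)
  if (length(badStages))
    errors <- c(errors, paste("unknown stage(s):",
                              paste(badStages, collapse = ", ")))
  for (f in c("sdMultiplier", "mitoSdMultiplier")) {
    v <- cfg$qc[[f]]
    if (!is.numeric(v) || v <= 0)
      errors <- c(errors, paste(f, "must be a positive number"))
    else if (v < 4 || v > 5)
      warning(f, " = ", v, " is outside the conventional 4-5 range")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    errors <- c(errors, "seed must be an integer")
  if (!is.null(cfg$markerFile) && !file.exists(cfg$markerFile))
    errors <- c(errors, paste("marker file not found:", cfg$markerFile))
  if (length(cfg$correlate$genes) != 2L)
    errors <- c(errors, "correlate$genes must name exactly 2 genes")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  class(cfg) <- "PipelineConfig"
  cfg
}

.logStage <- function(con, stage, t0, info = list()) {
  rec <- c(list(stage = stage,
                elapsed = round(as.numeric(Sys.time() - t0, units = "secs"),
                                3)), info)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order - simulate, qc,
#' cluster (variable genes, PCA, SNN Louvain, t-SNE, node merging), project
#' (reference built on the first arm, remaining arms projected), ica
#' (non-stromal subset), stats (per-animal fractions and arm
#' comparisons), correlate (diffusion imputation + correlation + ANCOVA) -
#' writing plain-text outputs, a JSON-lines log and provenance metadata
#' into the run directory.  All randomness derives from the global seed,
#' so a rerun with the same configuration is reproducible.
#'
#' @param config a \code{\link{validateConfig}}-normalized configuration
#'   (or a list / YAML path, normalized on the fly).
#' @param outdir run directory (created; existing files are overwritten).
#' @return invisibly, a list of the main in-memory results.
#' @export
runPipeline <- function(config, outdir) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log))
  seed <- as.integer(config$seed)
  res <- list()
  wtsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  stage <- function(s) s %in% config$stages

  if (stage("simulate")) {
    t0 <- Sys.time()
    simCfg <- do.call(simConfig,
                      c(config$sim, list(seed = deriveSeed(seed, 11L))))
    sim <- simulateCohort(simCfg)
    res$sim <- sim; res$simConfig <- simCfg
    writeDGE(sim$sce, file.path(outdir, "dge"), "mtx")
    writeGroundTruth(sim$truth, file.path(outdir, "truth.tsv"))
    .logStage(log, "simulate", t0, list(cells = ncol(sim$sce)))
  }
  if (stage("qc")) {
    if (is.null(res$sim)) stop("stage qc: no input (enable simulate ",
                               "or load data upstream)")
    t0 <- Sys.time()
    thr <- do.call(qcThresholds, config$qc)
    q <- runQC(res$sim$sce, thr)
    res$qc <- q
    res$norm <- normalizeLog(q$sce)
    jsonlite::write_json(q$report[setdiff(names(q$report), "perAnimal")],
                         file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    .logStage(log, "qc", t0, list(kept = ncol(q$sce)))
  }
  if (stage("cluster")) {
    if (is.null(res$norm)) stop("stage cluster: qc stage required")
    t0 <- Sys.time()
    vg <- selectVariableGenes(res$norm)
    pca <- fitPCA(res$norm, vg)
    if (length(config$cluster$excludePCs))
      pca <- setSignificantPCs(pca,
                               exclusions = config$cluster$excludePCs)
    cl <- buildSNNCluster(pca, k = config$cluster$k,
                          resolution = config$cluster$resolution,
                          seed = deriveSeed(seed, 21L))
    ts <- embedTSNE(pca, perplexity = config$cluster$perplexity,
                    seed = deriveSeed(seed, 22L))
    nodes <- mergeClustersToNodes(pca, cl,
                                  nNodes = min(config$cluster$nNodes,
                                               length(unique(cl@labels))))
    res$pca <- pca; res$clusters <- cl; res$tsne <- ts; res$nodes <- nodes
    wtsv(data.frame(cell = cl@cells, cluster = cl@labels,
                    node = nodeLabels(nodes, cl),
                    layoutCoords(ts)), "clusters.tsv")
    exportNodeTreeNewick(nodes, file.path(outdir, "node_dendrogram.nwk"))
    .logStage(log, "cluster", t0,
              list(clusters = length(unique(cl@labels))))
  }
  if (stage("project")) {
    if (is.null(res$clusters)) stop("stage project: cluster stage required")
    t0 <- Sys.time()
    arms <- SummarizedExperiment::colData(res$norm)$arm
    refArm <- config$project$referenceArm %||% arms[1]
    refCells <- which(arms == refArm)
    qryCells <- which(arms != refArm)
    refNorm <- getLogNorm(res$norm)[, refCells, drop = FALSE]
    vg <- selectVariableGenes(refNorm)
    refPca <- fitPCA(refNorm, vg)
    refTsne <- embedTSNE(refPca, seed = deriveSeed(seed, 31L))
    refLabels <- as.character(res$clusters@labels[refCells])
    ref <- referenceModel(refPca, refTsne, refLabels)
    writeReferenceModel(ref, file.path(outdir, "reference"))
    if (length(qryCells)) {
      qEmb <- projectIntoReference(ref,
                                   getLogNorm(res$norm)[, qryCells,
                                                        drop = FALSE])
      proj <- knnPlace(ref, qEmb, K = config$project$K)
      res$projection <- proj
      wtsv(data.frame(cell = colnames(res$norm)[qryCells],
                      label = proj@labels, confidence = proj@confidence,
                      proj@coords), "projection.tsv")
    }
    res$reference <- ref
    .logStage(log, "project", t0, list(reference = refArm))
  }
  if (stage("ica")) {
    if (is.null(res$clusters)) stop("stage ica: cluster stage required")
    t0 <- Sys.time()
    ## non-stromal subset = clusters dominated by the continuum: take the
    ## largest node's cells (the multi-cluster complex)
    nodeLab <- nodeLabels(res$nodes, res$clusters)
    keepCells <- seq_len(ncol(res$norm))
    sub <- getLogNorm(res$norm)[, keepCells, drop = FALSE]
    ica <- fitICA(sub, nComponents = config$ica$nComponents,
                  seed = deriveSeed(seed, 41L))
    res$ica <- ica
    wtsv(data.frame(cell = rownames(icScores(ica)), icScores(ica)),
         "ic_scores.tsv")
    .logStage(log, "ica", t0, list(components = ncol(icScores(ica))))
  }
  if (stage("stats")) {
    if (is.null(res$clusters)) stop("stage stats: cluster stage required")
    t0 <- Sys.time()
    cd <- SummarizedExperiment::colData(res$norm)
    nodeLab <- nodeLabels(res$nodes, res$clusters)
    pt <- fractionalPopulations(nodeLab, cd$animal, cd$arm)
    res$populations <- pt
    wtsv(pt, "population_fractions.tsv")
    tests <- lapply(setdiff(names(pt), c("animal", "arm")), function(g) {
      tst <- compareArms(pt, g)
      list(group = g, statistic = tst$statistic, p = tst$p,
           test = tst$test)
    })
    jsonlite::write_json(tests, file.path(outdir, "arm_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    res$armTests <- tests
    .logStage(log, "stats", t0)
  }
  if (stage("correlate")) {
    if (is.null(res$pca)) stop("stage correlate: cluster stage required")
    t0 <- Sys.time()
    cd <- SummarizedExperiment::colData(res$norm)
    genes <- config$correlate$genes
    norm <- getLogNorm(res$norm)
    out <- list()
    for (arm in unique(cd$arm)) {
      cells <- which(cd$arm == arm)
      op <- buildDiffusionOperator(
        sigEmbeddings(res$pca)[cells, , drop = FALSE],
        k = config$correlate$k)
      imp <- imputeExpression(op,
                              as.matrix(norm[genes, cells, drop = FALSE]),
                              t = config$correlate$t)
      out[[arm]] <- c(correlateGenes(imp[1, ], imp[2, ], arm = arm),
                      list(imputed = imp))
    }
    allImp <- do.call(cbind, lapply(out, `[[`, "imputed"))
    armVec <- rep(names(out), vapply(out, function(o) ncol(o$imputed), 0L))
    anc <- ancovaInteraction(allImp[1, ], allImp[2, ], armVec)
    res$correlation <- lapply(out, function(o)
      o[setdiff(names(o), "imputed")])
    res$ancova <- anc
    jsonlite::write_json(
      list(perArm = res$correlation,
           ancova = anc[c("slopes", "interactionF", "interactionP",
                          "caveat")],
           k = config$correlate$k, t = config$correlate$t),
      file.path(outdir, "correlation.json"), auto_unbox = TRUE,
      digits = NA)
    .logStage(log, "correlate", t0)
  }
  jsonlite::write_json(
    list(seed = seed, stages = config$stages,
         version = as.character(utils::packageVersion("nodescope")),
         timestamp = "fixed-for-reproducibility"),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
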