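test_that("variable gene selection matches a brute-force recomputation", {
  set.seed(1)
  n <- 60
  m <- matrix(rpois(100 * n, lambda = rep(exp(runif(100, -2, 1.5)), n)),
              nrow = 100, dimnames = list(sprintf("g%03d", 1:100),
                                          sprintf("c%02d", 1:n)))
  sel <- selectVariableGenes(m, nBins = 5)
  ## independent recomputation of the binned dispersion z-scores
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- cut(mu, 5, include.lowest = TRUE, labels = FALSE)
  z <- numeric(100)
  for (b in unique(bin)) {
    i <- bin == b
    z[i] <- if (sd(disp[i]) > 0) (disp[i] - mean(disp[i])) / sd(disp[i])
            else 0
  }
  manual <- rownames(m)[mu > 0.125 & mu < 3 & z >= 0.5]
  expect_setequal(sel$genes, manual)
  ## a zero-variance gene among positive-dispersion peers is excluded
  m2 <- m; m2[1, ] <- 2
  sel2 <- selectVariableGenes(m2, nBins = 5)
  expect_false(rownames(m2)[1] %in% sel2$genes)
  ## genes below the mean floor are excluded regardless of dispersion
  low <- rownames(m)[rowMeans(m) <= 0.125]
  expect_length(intersect(sel$genes, low), 0)
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(7)
  m <- matrix(rnorm(50 * 30), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("c%02d", 1:30)))
  fit <- fitPCA(m, rownames(m))
  X <- scale(t(m))
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(pcVariance(fit)[1:10], ev[1:10], tolerance = 1e-6)
  ## embeddings are the scaled expression times the loadings
  expect_equal(unname(cellEmbeddings(fit)),
               unname(X %*% geneLoadings(fit)), tolerance = 1e-8)
  ## rank-1 data concentrate all variance in component 1
  v <- rnorm(30)
  r1 <- outer(rnorm(20), v) ; rownames(r1) <- sprintf("h%02d", 1:20)
  colnames(r1) <- sprintf("c%02d", 1:30)
  fit1 <- fitPCA(r1, rownames(r1))
  expect_gt(pcVariance(fit1)[1] / sum(pcVariance(fit1)), 0.999)
})

test_that("significant component selection follows the variance z-score rule", {
  mkModel <- function(vars) methods::new("PCAModel",
    loadings = matrix(0, 2, length(vars)),
    embeddings = matrix(0, 3, length(vars)),
    sdev = sqrt(vars), zScores = numeric(length(vars)),
    sigPCs = 1L, excludedPCs = integer(), varGenes = c("a", "b"),
    center = c(0, 0), scale = c(1, 1), zThreshold = 2)
  ## hand-computed on [10, 1 x 9]: z1 = (10 - 1.9) / 2.846 = 2.846 > 2
  fake <- mkModel(c(10, rep(1, 9)))
  expect_identical(selectSignificantPCs(fake), 1L)
  ## two dominant components over a long noise tail
  fake2 <- mkModel(c(30, 20, rep(1, 48)))
  expect_identical(selectSignificantPCs(fake2), c(1L, 2L))
  ## exclusions remove a component from the set
  expect_identical(selectSignificantPCs(fake2, exclusions = 2L), 1L)
  ## equal variances give an empty set, which errors
  expect_error(selectSignificantPCs(mkModel(rep(1, 10))), "no significant")
  ## the selected set is invariant to permuting the variance vector
  perm <- c(5L, 2L, 1L, 3L, 4L, 6:50)
  fake4 <- mkModel(c(30, 20, rep(1, 48))[perm])
  expect_setequal(match(selectSignificantPCs(fake2), perm),
                  selectSignificantPCs(fake4))
})

test_that("SNN Louvain separates well-separated blobs and is deterministic", {
  set.seed(3)
  blob <- rbind(matrix(rnorm(100 * 2), ncol = 2),
                matrix(rnorm(100 * 2, mean = 50), ncol = 2))
  rownames(blob) <- sprintf("c%03d", 1:200)
  truth <- rep(0:1, each = 100)
  cl <- buildSNNCluster(blob, k = 50, seed = 1)
  expect_equal(length(unique(cl@labels)), 2L)
  expect_equal(ari(truth, cl@labels), 1)
  ## identical input and seed give identical labels
  cl2 <- buildSNNCluster(blob, k = 50, seed = 1)
  expect_identical(cl@labels, cl2@labels)
  ## resolution -> 0 merges everything into one community; modularity can
  ## never merge disconnected components, so the limit is checked on two
  ## adjacent (SNN-connected) blobs
  near <- rbind(matrix(rnorm(100 * 2), ncol = 2),
                matrix(rnorm(100 * 2, mean = 3), ncol = 2))
  rownames(near) <- sprintf("n%03d", 1:200)
  nHigh <- length(unique(buildSNNCluster(near, k = 30, resolution = 0.8,
                                         seed = 1)@labels))
  cl0 <- buildSNNCluster(near, k = 30, resolution = 1e-3, seed = 1)
  expect_equal(length(unique(cl0@labels)), 1L)
  expect_gte(nHigh, 2L)
  ## degenerate embeddings yield a single cluster with a warning
  same <- matrix(1, nrow = 30, ncol = 2)
  expect_warning(cld <- buildSNNCluster(same, k = 5, seed = 1),
                 "degenerate")
  expect_equal(length(unique(cld@labels)), 1L)
})

test_that("t-SNE is seeded, separation preserving, and guards perplexity", {
  set.seed(4)
  blob <- rbind(matrix(rnorm(60 * 3), ncol = 3),
                matrix(rnorm(60 * 3, mean = 50), ncol = 3))
  rownames(blob) <- sprintf("c%03d", 1:120)
  a <- embedTSNE(blob, perplexity = 10, seed = 2)
  b <- embedTSNE(blob, perplexity = 10, seed = 2)
  expect_identical(layoutCoords(a), layoutCoords(b))
  grp <- rep(1:2, each = 60)
  cents <- rbind(colMeans(layoutCoords(a)[grp == 1, ]),
                 colMeans(layoutCoords(a)[grp == 2, ]))
  within <- mean(c(sqrt(rowSums(sweep(layoutCoords(a)[grp == 1, ], 2,
                                      cents[1, ])^2)),
                   sqrt(rowSums(sweep(layoutCoords(a)[grp == 2, ], 2,
                                      cents[2, ])^2))))
  expect_gt(sqrt(sum((cents[1, ] - cents[2, ])^2)), 5 * within)
  expect_error(embedTSNE(blob, perplexity = 40, seed = 1), "perplexity")
})

test_that("node merging follows centroid distances and cut size", {
  ## three clusters with d(1,2) = 1, d(1,3) = d(2,3) ~ 10: first merge 1+2
  emb <- rbind(matrix(rnorm(40, sd = 0.01), 20, 2),
               matrix(rnorm(40, sd = 0.01), 20, 2) + c(1, 0),
               matrix(rnorm(40, sd = 0.01), 20, 2) + c(5, 8.66))
  rownames(emb) <- sprintf("c%02d", 1:60)
  fake <- methods::new("PCAModel",
    loadings = matrix(0, 2, 2), embeddings = emb,
    sdev = c(1, 1), zScores = c(3, 3), sigPCs = c(1L, 2L),
    excludedPCs = integer(), varGenes = c("a", "b"),
    center = c(0, 0), scale = c(1, 1), zThreshold = 2)
  cl <- methods::new("ClusterResult", labels = rep(0:2, each = 20L),
                     cells = rownames(emb),
                     snn = Matrix::Matrix(0, 60, 60, sparse = TRUE),
                     modularity = 0.5, resolution = 0.8, k = 5L, seed = 1L)
  tree <- mergeClustersToNodes(fake, cl, nNodes = 2)
  asg <- nodeAssignment(tree)
  expect_equal(asg[["0"]], asg[["1"]])
  expect_false(asg[["0"]] == asg[["2"]])
  ## merge heights are monotone non-decreasing (average linkage)
  expect_true(all(diff(tree@dendrogram$height) >= -1e-12))
  ## nNodes = nClusters puts each cluster in its own node
  t3 <- mergeClustersToNodes(fake, cl, nNodes = 3)
  expect_equal(length(unique(nodeAssignment(t3))), 3L)
  expect_error(mergeClustersToNodes(fake, cl, nNodes = 4), "exceeds")
})

test_that("marker thresholds label clusters by their programmed type", {
  m <- matrix(0, 3, 40, dimnames = list(c("Aqp4", "Cd68", "Other"),
                                        sprintf("c%02d", 1:40)))
  m["Aqp4", 1:20] <- 3
  m["Cd68", 21:40] <- 3
  cl <- methods::new("ClusterResult", labels = rep(0:1, each = 20L),
                     cells = colnames(m),
                     snn = Matrix::Matrix(0, 40, 40, sparse = TRUE),
                     modularity = 0.5, resolution = 0.8, k = 5L, seed = 1L)
  mc <- data.frame(gene = c("Aqp4", "Cd68"), threshold = c(1, 1),
                   cellType = c("astrocyte", "microglia"))
  lab <- classifyCellTypes(m, cl, mc)
  expect_equal(unname(lab[c("0", "1")]), c("astrocyte", "microglia"))
  ## all fractions below the floor -> unassigned
  lab2 <- classifyCellTypes(m, cl, transform(mc, threshold = 10))
  expect_true(all(lab2 == "unassigned"))
  ## an absent marker gene warns and is skipped
  mc3 <- rbind(mc, data.frame(gene = "Missing", threshold = 1,
                              cellType = "astrocyte"))
  expect_warning(classifyCellTypes(m, cl, mc3), "absent")
})

test_that("cluster cell types recover the generating populations", {
  co <- clusteredCohort(11)
  tiers <- c("early", "mid", "late")
  mc <- do.call(rbind, c(
    lapply(names(co$cfg$populations), function(p) data.frame(
      gene = co$cfg$populations[[p]]$markers[1:5], threshold = 1,
      cellType = p)),
    lapply(tiers, function(w) data.frame(
      gene = co$cfg$trajectory[[paste0(
        "markers", toupper(substring(w, 1, 1)),
        substring(w, 2))]][1:5],
      threshold = 1, cellType = paste0("CGNP_", w)))))
  lab <- classifyCellTypes(co$norm, co$cl, mc)
  ## expected label per cluster from the simulation truth
  truthLab <- ifelse(co$truth$population == "CGNP",
                     paste0("CGNP_", tiers[co$truth$tier]),
                     co$truth$population)
  agree <- vapply(sort(unique(co$cl@labels)), function(clu) {
    i <- co$cl@labels == clu & !co$truth$isDoublet
    maj <- names(sort(table(truthLab[i]), decreasing = TRUE))[1]
    identical(unname(lab[as.character(clu)]), maj)
  }, TRUE)
  expect_gte(mean(agree), 0.9)
})
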