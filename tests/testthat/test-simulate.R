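test_that("empty and invalid configurations are handled", {
  cfg0 <- simConfig(nCellsPerAnimal = c(A = 0, B = 0), trajectory = NA,
                    nAnimalsPerArm = 1L, arms = "vehicle",
                    lineageFraction = c(), seed = 1)
  out <- simulateCohort(cfg0)
  expect_equal(ncol(out$sce), 0L)
  expect_equal(nrow(out$truth), 0L)
  expect_error(simConfig(nCellsPerAnimal = c()), "population")
  expect_error(simConfig(doubletRate = 1), "rates")
  expect_error(applyTreatmentEffect(simConfig(seed = 1), "placebo"),
               "unknown arm")
})

test_that("the same config and seed reproduce bit-identical cohorts", {
  cfg <- simConfig(nCellsPerAnimal = c(A = 30, CGNP = 50),
                   nAnimalsPerArm = 1L, seed = 5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(as.matrix(getCounts(a$sce)), as.matrix(getCounts(b$sce)))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("mean counts match the analytic multinomial expectation", {
  cfg <- simConfig(nCellsPerAnimal = c(A = 500), trajectory = NA,
                   nAnimalsPerArm = 1L, arms = "vehicle",
                   ambientRate = 0, spikeinRate = 0, doubletRate = 0,
                   mitoDist = NULL, lineageFraction = c(A = 0.3),
                   libraryMean = 2000, librarySize = Inf,
                   animalSizeSD = 0, nHuman = 0L, seed = 3)
  sim <- simulateCohort(cfg)
  counts <- as.matrix(getCounts(sim$sce))
  expected <- 2000 * expectedProfile(cfg, "A")
  obs <- rowMeans(counts)
  ## per-gene SE of the mean under multinomial sampling
  se <- sqrt(pmax(expected * (1 - expectedProfile(cfg, "A")), 1e-9) / 500)
  frac <- mean(abs(obs - expected[rownames(counts)]) <=
               3 * se[rownames(counts)] + 1e-9)
  expect_gt(frac, 0.98)
  ## column sums equal the (fixed) library size
  expect_true(all(colSums(counts) == 2000))
})

test_that("doublet injection sums parent columns and respects rate", {
  co <- discreteCohort(8, nPer = 50)
  n0 <- ncol(co$sim$sce)
  dd <- injectDoublets(co$sim$sce, co$sim$truth, 0.1, seed = 4)
  nD <- sum(dd$truth$isDoublet)
  expect_equal(nD, floor(0.1 * n0))
  counts <- as.matrix(getCounts(dd$sce))
  for (i in which(dd$truth$isDoublet)) {
    expect_false(dd$truth$parent1[i] == "" || dd$truth$parent2[i] == "")
  }
  ## column sum of each doublet equals the sum of its parents' library sizes
  expect_true(all(colSums(counts[, dd$truth$isDoublet, drop = FALSE]) ==
                  dd$truth$librarySize[dd$truth$isDoublet]))
  ## rate 0 is the identity
  same <- injectDoublets(co$sim$sce, co$sim$truth, 0)
  expect_identical(same$sce, co$sim$sce)
})

test_that("treatment effects rescale fractions and flip the coupling", {
  cfg <- simConfig(nCellsPerAnimal = c(A = 100, B = 100), trajectory = NA,
                   nAnimalsPerArm = 1L, arms = c("vehicle", "treated"),
                   popMultipliers = list(vehicle = NULL,
                                         treated = c(A = 0.5)),
                   lineageFraction = c(), seed = 2)
  veh <- applyTreatmentEffect(cfg, "vehicle")
  trt <- applyTreatmentEffect(cfg, "treated")
  expect_equal(unname(veh$armFractions), c(0.5, 0.5))
  expect_equal(unname(trt$armFractions), c(1 / 3, 2 / 3))
  expect_equal(veh$armCouplingSign, 1)
  expect_equal(trt$armCouplingSign, -1)
})

test_that("regulator-target coupling is positive in vehicle, negative in treated", {
  cfg <- simConfig(nCellsPerAnimal = c(A = 1000), trajectory = NA,
                   nAnimalsPerArm = 1L, arms = c("vehicle", "treated"),
                   spikeinRate = 0, doubletRate = 0, mitoDist = NULL,
                   lineageFraction = c(), nHuman = 0L, seed = 10)
  sim <- simulateCohort(cfg)
  norm <- getLogNorm(normalizeLog(sim$sce))
  arm <- sim$truth$arm
  rv <- cor(norm["RegA", arm == "vehicle"],
            norm["TargB", arm == "vehicle"])
  rt <- cor(norm["RegA", arm == "treated"],
            norm["TargB", arm == "treated"])
  expect_gt(rv, 0.3)
  expect_lt(rt, -0.3)
})

test_that("cohort rates match their configured distributions", {
  co <- studyCohort(11)
  truth <- co$sim$truth
  sing <- !truth$isDoublet
  ## spike-in fraction within 2 binomial SD
  n <- sum(sing)
  pHum <- mean(truth$species[sing] == "human")
  expect_lt(abs(pHum - co$cfg$spikeinRate),
            2 * sqrt(co$cfg$spikeinRate * (1 - co$cfg$spikeinRate) / n))
  ## transgene-positive fraction per population within 2 binomial SD
  for (p in c("CGNP", "astrocyte", "endothelial")) {
    i <- sing & truth$population == p
    lf <- if (p == "endothelial") 0 else
      if (p == "CGNP") co$cfg$trajectory$lineageFraction else
      co$cfg$populations[[p]]$lineageFraction
    tol <- 2 * sqrt(max(lf * (1 - lf), 0.25 / sum(i)) / sum(i))
    expect_lt(abs(mean(truth$lineage[i]) - lf), tol + 1e-9)
  }
  ## drawn mitochondrial fractions match the configured distribution
  drawn <- truth$mitoFraction[sing & truth$species == "mouse"]
  ref <- withr::with_seed(1, nodescope:::sampleMitoFraction(
    co$cfg$mitoDist, 20000))
  expect_gt(suppressWarnings(ks.test(drawn, ref)$p.value), 0.01)
  ## column sums equal drawn library sizes before doublet injection
  counts <- getCounts(co$sim$sce)
  expect_true(all(Matrix::colSums(counts[, sing]) ==
                  truth$librarySize[sing]))
})
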