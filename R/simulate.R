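#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## Synthetic Drop-seq cohort generator.
##
## The generator emulates the statistical structure of a two-arm single-cell
## tumor cohort: several discrete stromal populations, one multi-state
## differentiation continuum, cell-cycle structure in the proliferative part
## of the continuum, doublets, ambient RNA, mitochondrial stress with a heavy
## upper tail, a foreign-species spike-in, a Cre-activated lineage reporter,
## and arm-dependent population shifts plus a regulator/target expression
## coupling whose sign flips with treatment.
## ---------------------------------------------------------------------------

#' Build a simulation configuration
#'
#' Constructs the full cohort blueprint: the gene panel (housekeeping,
#' dose-graded, population markers, cell-cycle phase, mitochondrial,
#' transgene, foreign-species and coupling genes) and per-population
#' expression programs (probability vectors over genes), plus all cohort- and
#' cell-level rates.  Programs are drawn once, deterministically from
#' \code{seed}, so the same configuration always describes the same cohort
#' distribution.
#'
#' Discrete populations share housekeeping genes at identical weights and
#' "graded" genes whose per-population weight is either 1x or
#' \code{gradedRatio}x a common base; each population additionally owns a
#' block of exclusive marker genes.  The trajectory population interpolates
#' linearly between an "early" and a "late" program along pseudotime, with
#' pseudotime drawn from a three-component mixture of Beta bumps (progenitor
#' / intermediate / differentiated tiers).  Proliferative (early-pseudotime)
#' trajectory cells express four phase gene sets on a cyclic schedule over a
#' latent angle.
#'
#' @param nCellsPerAnimal named integer vector of expected cells per animal
#'   for every population (the trajectory population included).
#' @param trajectory name of the population treated as the differentiation
#'   continuum, or \code{NA} for a purely discrete cohort.
#' @param nAnimalsPerArm animals per treatment arm.
#' @param arms arm labels; the first is the untreated reference arm.
#' @param doubletRate fraction of barcodes to add as same-animal doublets.
#' @param ambientRate fraction of each cell's counts drawn from the pooled
#'   ambient profile.
#' @param spikeinRate fraction of barcodes that are foreign-species cells.
#' @param lineageFraction named per-population probability that a cell
#'   expresses the lineage-reporter transgene; unnamed populations get 0.
#' @param popMultipliers per-arm named multipliers on population fractions
#'   (renormalized); see \code{\link{applyTreatmentEffect}}.
#' @param tierWeights per-arm mixture weights of the three pseudotime tiers.
#' @param couplingSign per-arm sign (+1/-1) of the regulator-target coupling.
#' @param couplingStrength amplitude of the per-cell coupling modulation.
#' @param libraryMean,librarySize negative-binomial mean and size of the
#'   per-cell total count; \code{librarySize = Inf} fixes the library size.
#' @param animalSizeSD log-normal SD of the per-animal library-size scalar
#'   offset (the only batch effect modeled).
#' @param mitoDist list with \code{shape1}, \code{shape2} (Beta parameters of
#'   the baseline mitochondrial fraction), \code{highProb} and
#'   \code{highShape1}, \code{highShape2} (the heavy stressed-cell tail);
#'   \code{NULL} disables mitochondrial counts.
#' @param nHousekeeping,nBackground,nGraded,gradedRatio,nMarkers,
#'   nTrajMarkers,markerMass,nMito,nHuman,nPhaseGenes,phaseMass gene-panel
#'   sizes and masses.
#' @param couplingMass total program mass of the two coupling genes.
#' @param yfpMass program mass of the transgene in lineage-positive cells.
#' @param seed integer seed; all program draws derive from it.
#' @return an object of class \code{SimConfig} (a validated list).
#' @export
simConfig <- function(
    nCellsPerAnimal = c(astrocyte = 25, oligodendrocyte = 25, microglia = 20,
                        endothelial = 20, fibroblast = 15, neuron = 15,
                        CGNP = 160),
    trajectory = "CGNP",
    nAnimalsPerArm = 5L,
    arms = c("vehicle", "treated"),
    doubletRate = 0.05,
    ambientRate = 0.02,
    spikeinRate = 0.05,
    lineageFraction = c(CGNP = 0.8, astrocyte = 0.15, oligodendrocyte = 0.15),
    popMultipliers = list(vehicle = NULL, treated = c(CGNP = 0.6)),
    tierWeights = list(vehicle = c(0.45, 0.35, 0.20),
                       treated = c(0.15, 0.30, 0.55)),
    couplingSign = c(vehicle = 1, treated = -1),
    couplingStrength = 0.85,
    libraryMean = 2000, librarySize = 8, animalSizeSD = 0.1,
    mitoDist = list(shape1 = 2.5, shape2 = 60, highProb = 0.02,
                    highShape1 = 18, highShape2 = 12),
    nHousekeeping = 150L, nBackground = 300L, nGraded = 200L,
    gradedRatio = 2.1,
    nMarkers = 30L, nTrajMarkers = 60L, markerMass = 0.25, nMito = 10L,
    nHuman = 100L,
    nPhaseGenes = 8L, phaseMass = 0.02, couplingMass = 0.008,
    yfpMass = 0.004, seed = 1L) {

  pops <- names(nCellsPerAnimal)
  if (is.null(pops) || length(pops) == 0L)
    stop("invalid config: at least one named population is required")
  if (anyDuplicated(pops)) stop("invalid config: duplicate population names")
  if (any(nCellsPerAnimal < 0)) stop("invalid config: negative cell counts")
  rates <- c(doubletRate = doubletRate, ambientRate = ambientRate,
             spikeinRate = spikeinRate)
  if (any(rates < 0 | rates >= 1))
    stop("invalid config: rates must lie in [0, 1)")
  if (!is.na(trajectory) && !trajectory %in% pops)
    stop("invalid config: trajectory population '", trajectory,
         "' not in nCellsPerAnimal")
  if (nHousekeeping + nGraded + nMarkers < 1L)
    stop("invalid config: gene panel is empty")
  if (!all(arms %in% names(tierWeights)) && !is.na(trajectory))
    tierWeights <- stats::setNames(rep(tierWeights[1], length(arms)), arms)
  lf <- stats::setNames(rep(0, length(pops)), pops)
  lf[intersect(names(lineageFraction), pops)] <-
    lineageFraction[intersect(names(lineageFraction), pops)]
  if (any(lf < 0 | lf >= 1))
    stop("invalid config: lineage fractions must lie in [0, 1)")

  phases <- c("G1", "S", "G2", "M")

  panel <- withSeed(deriveSeed(seed, 1L), {
    hk <- c(sprintf("Hk%03d", seq_len(nHousekeeping)),
            sprintf("Bg%03d", seq_len(nBackground)))
    gr <- sprintf("Gr%03d", seq_len(nGraded))
    ## housekeeping plus a low-expression background block: most of a real
    ## transcriptome is uninformative, and the binned dispersion z-scoring
    ## assumes such genes populate the bins
    wHk <- c(exp(rnorm(nHousekeeping, 0, 1)),
             exp(rnorm(nBackground, -1.7, 0.8)))
    wGrBase <- exp(rnorm(nGraded, 0.7, 0.4))

    markerIds <- list()
    for (p in setdiff(pops, trajectory))
      markerIds[[p]] <- sprintf("%sMk%02d", p, seq_len(nMarkers))
    if (!is.na(trajectory)) {
      markerIds[[paste0(trajectory, ".early")]] <-
        sprintf("%sEarlyMk%02d", trajectory, seq_len(nTrajMarkers))
      markerIds[[paste0(trajectory, ".mid")]] <-
        sprintf("%sMidMk%02d", trajectory, seq_len(nTrajMarkers))
      markerIds[[paste0(trajectory, ".late")]] <-
        sprintf("%sLateMk%02d", trajectory, seq_len(nTrajMarkers))
    }
    markerW <- lapply(markerIds, function(ids) {
      w <- exp(rnorm(length(ids), 0, 0.5)); w / sum(w)
    })

    phaseIds <- lapply(stats::setNames(phases, phases), function(p)
      sprintf("Ph%s%02d", p, seq_len(nPhaseGenes)))
    phaseW <- lapply(phaseIds, function(ids) {
      w <- exp(rnorm(length(ids), 0, 0.3)); w / sum(w)
    })

    mitoIds <- if (nMito > 0) sprintf("mt-Mito%02d", seq_len(nMito))
               else character()
    mitoW <- if (nMito > 0) {
      w <- exp(rnorm(nMito, 0, 0.5)); w / sum(w)
    } else numeric()

    humIds <- if (nHuman > 0) sprintf("HUM%03d", seq_len(nHuman))
              else character()
    humW <- if (nHuman > 0) { w <- exp(rnorm(nHuman, 0, 1)); w / sum(w) }
            else numeric()

    coupIds <- c("RegA", "TargB")

    mouseIds <- c(hk, gr, unlist(markerIds, use.names = FALSE),
                  unlist(phaseIds, use.names = FALSE), coupIds, "Yfp")
    allIds <- c(mouseIds, mitoIds, humIds)
    genes <- data.frame(
      id = allIds,
      species = c(rep("mouse", length(mouseIds) + length(mitoIds)),
                  rep("human", length(humIds))),
      mito = allIds %in% mitoIds,
      transgene = allIds == "Yfp",
      stringsAsFactors = FALSE)

    ## per-population graded multipliers (1x or gradedRatio x)
    gradedMult <- list()
    for (p in setdiff(pops, trajectory))
      gradedMult[[p]] <- ifelse(runif(nGraded) < 0.5, 1, gradedRatio)
    if (!is.na(trajectory)) {
      gradedMult[[paste0(trajectory, ".early")]] <-
        ifelse(runif(nGraded) < 0.5, 1, gradedRatio)
      gradedMult[[paste0(trajectory, ".late")]] <-
        ifelse(runif(nGraded) < 0.5, 1, gradedRatio)
    }

    list(genes = genes, hk = hk, gr = gr, wHk = wHk, wGrBase = wGrBase,
         markerIds = markerIds, markerW = markerW, gradedMult = gradedMult,
         phaseIds = phaseIds, phaseW = phaseW,
         mitoIds = mitoIds, mitoW = mitoW, humIds = humIds, humW = humW,
         coupIds = coupIds)
  })

  nGenesAll <- nrow(panel$genes)
  zeroProg <- stats::setNames(rep(0, nGenesAll), panel$genes$id)

  ## compose a mouse program (over all genes, zero outside mouse non-mito)
  composeProgram <- function(markerKeys, markerFracs, gradedKey) {
    base <- zeroProg
    base[panel$hk] <- panel$wHk
    gm <- if (is.list(gradedKey)) {
      ## interpolation: list(keys, fracs)
      m <- rep(0, length(panel$gr))
      for (i in seq_along(gradedKey$keys))
        m <- m + gradedKey$fracs[i] * panel$gradedMult[[gradedKey$keys[i]]]
      m
    } else panel$gradedMult[[gradedKey]]
    base[panel$gr] <- panel$wGrBase * gm
    baseMass <- 1 - markerMass - couplingMass
    base <- base / sum(base) * baseMass
    for (i in seq_along(markerKeys)) {
      ids <- panel$markerIds[[markerKeys[i]]]
      base[ids] <- base[ids] +
        markerMass * markerFracs[i] * panel$markerW[[markerKeys[i]]]
    }
    base[panel$coupIds] <- couplingMass / 2
    base
  }

  populations <- list()
  for (p in setdiff(pops, trajectory)) {
    populations[[p]] <- list(
      name = p, nCellsPerAnimal = unname(nCellsPerAnimal[p]),
      program = composeProgram(p, 1, p),
      markers = panel$markerIds[[p]], lineageFraction = unname(lf[p]))
  }

  trajCfg <- NULL
  if (!is.na(trajectory)) {
    ek <- paste0(trajectory, ".early"); lk <- paste0(trajectory, ".late")
    mk <- paste0(trajectory, ".mid")
    waveVec <- function(key) {
      v <- zeroProg; v[panel$markerIds[[key]]] <- panel$markerW[[key]]; v
    }
    trajCfg <- list(
      name = trajectory,
      nCellsPerAnimal = unname(nCellsPerAnimal[trajectory]),
      baseEarly = composeProgram(character(), numeric(),
                                 list(keys = c(ek, lk), fracs = c(1, 0))),
      baseLate = composeProgram(character(), numeric(),
                                list(keys = c(ek, lk), fracs = c(0, 1))),
      waveEarly = waveVec(ek), waveMid = waveVec(mk), waveLate = waveVec(lk),
      markerMass = markerMass,
      markersEarly = panel$markerIds[[ek]],
      markersMid = panel$markerIds[[mk]],
      markersLate = panel$markerIds[[lk]],
      lineageFraction = unname(lf[trajectory]),
      tierCenters = c(0.12, 0.50, 0.88), tierConc = 100,
      cyclingTmax = 0.45, cyclingProb = 0.6)
  }

  cfg <- list(
    genes = panel$genes, populations = populations, trajectory = trajCfg,
    phaseGenes = panel$phaseIds,
    phaseProgram = lapply(stats::setNames(phases, phases), function(p) {
      v <- zeroProg; v[panel$phaseIds[[p]]] <- panel$phaseW[[p]]; v
    }),
    phases = phases, phaseMass = phaseMass,
    mitoProgram = { v <- zeroProg
                    if (length(panel$mitoIds)) v[panel$mitoIds] <- panel$mitoW
                    v },
    humanProgram = { v <- zeroProg
                     if (length(panel$humIds)) v[panel$humIds] <- panel$humW
                     v },
    coupling = list(regulator = "RegA", target = "TargB",
                    strength = couplingStrength, sign = couplingSign),
    nAnimalsPerArm = as.integer(nAnimalsPerArm), arms = arms,
    popMultipliers = popMultipliers, tierWeights = tierWeights,
    doubletRate = doubletRate, ambientRate = ambientRate,
    spikeinRate = spikeinRate,
    libraryMean = libraryMean, librarySize = librarySize,
    animalSizeSD = animalSizeSD, mitoDist = mitoDist,
    yfpMass = yfpMass, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Specialize a configuration for one treatment arm
#'
#' Rescales population fractions by the arm's multipliers (renormalized so
#' the per-animal total is unchanged), replaces the trajectory tier weights
#' with the arm's (shifting the pseudotime distribution toward the
#' differentiated end for the treated arm under the defaults), and fixes the
#' sign of the regulator-target coupling for the arm.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param arm one of \code{config$arms}.
#' @return a \code{SimConfig} with arm-effective fractions, tier weights and
#'   coupling sign (fields \code{armFractions}, \code{armTierWeights},
#'   \code{armCouplingSign} added).
#' @export
applyTreatmentEffect <- function(config, arm) {
  stopifnot(inherits(config, "SimConfig"))
  if (!arm %in% config$arms) stop("unknown arm label: ", arm)
  popN <- vapply(config$populations, function(p) p$nCellsPerAnimal, 0)
  if (!is.null(config$trajectory))
    popN[config$trajectory$name] <- config$trajectory$nCellsPerAnimal
  mult <- stats::setNames(rep(1, length(popN)), names(popN))
  m <- config$popMultipliers[[arm]]
  if (!is.null(m)) mult[intersect(names(m), names(popN))] <-
      m[intersect(names(m), names(popN))]
  w <- popN * mult
  frac <- if (sum(w) > 0) w / sum(w) else w
  out <- config
  out$armFractions <- frac
  out$armTierWeights <- if (!is.null(config$trajectory))
    config$tierWeights[[arm]] %||% config$tierWeights[[1]] else NULL
  out$armCouplingSign <- unname(config$coupling$sign[arm])
  if (is.na(out$armCouplingSign)) out$armCouplingSign <- 1
  out
}

## mitochondrial-fraction sampler implied by a config
sampleMitoFraction <- function(mitoDist, n) {
  if (is.null(mitoDist) || n == 0L) return(rep(0, n))
  f <- rbeta(n, mitoDist$shape1, mitoDist$shape2)
  hi <- runif(n) < mitoDist$highProb
  if (any(hi)) f[hi] <- rbeta(sum(hi), mitoDist$highShape1,
                              mitoDist$highShape2)
  f
}

## expected full gene-probability profile of a discrete population
## (marginalizing coupling, lineage, mito and ambient, all linear in
## expectation); used by the analytic mean-count oracle.
expectedProfile <- function(config, population, arm = config$arms[1]) {
  stopifnot(inherits(config, "SimConfig"))
  p <- config$populations[[population]]$program
  lfr <- config$populations[[population]]$lineageFraction
  p <- (1 - lfr * config$yfpMass) * p
  p["Yfp"] <- p["Yfp"] + lfr * config$yfpMass
  amb <- ambientProfile(config)
  p <- (1 - config$ambientRate) * p + config$ambientRate * amb
  fbar <- if (is.null(config$mitoDist)) 0 else {
    md <- config$mitoDist
    (1 - md$highProb) * md$shape1 / (md$shape1 + md$shape2) +
      md$highProb * md$highShape1 / (md$highShape1 + md$highShape2)
  }
  p <- (1 - fbar) * p + fbar * config$mitoProgram
  p
}

## pooled ambient profile: average mouse program plus the spike-in share
ambientProfile <- function(config) {
  progs <- lapply(config$populations, `[[`, "program")
  if (!is.null(config$trajectory))
    progs <- c(progs, list(trajProgram(config$trajectory, 0.5)))
  mouse <- Reduce(`+`, progs) / length(progs)
  (1 - config$spikeinRate) * mouse + config$spikeinRate * config$humanProgram
}

#' Simulate a Drop-seq-like cohort with ground truth
#'
#' Draws every barcode's counts as a multinomial allocation of a
#' negative-binomially drawn library size over the cell's composed gene
#' probability vector (population program or pseudotime-interpolated
#' trajectory program, cyclic phase programs for cycling cells, per-cell
#' regulator/target coupling modulation, lineage-reporter mass, ambient
#' pool admixture, and a per-cell mitochondrial fraction), then appends
#' foreign-species spike-in barcodes and same-animal doublets.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a list with \code{sce}, a
#'   \linkS4class{SingleCellExperiment} (assay \code{"counts"}, rowData
#'   \code{species}/\code{mito}/\code{transgene}, colData
#'   \code{animal}/\code{arm}), and \code{truth}, a
#'   \code{\link[S4Vectors]{DataFrame}} with one record per emitted barcode
#'   (population, tier, pseudotime, phase, doublet status and parents,
#'   species, lineage flag, drawn mitochondrial fraction and library size).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (nrow(config$genes) == 0L) stop("invalid config: zero genes")
  if (length(config$populations) == 0L && is.null(config$trajectory))
    stop("invalid config: zero populations")
  geneIds <- config$genes$id
  G <- length(geneIds)
  amb <- ambientProfile(config)
  phases <- config$phases
  phaseCenters <- stats::setNames((seq_along(phases) - 1) * 2 * pi /
                                  length(phases), phases)

  res <- withSeed(deriveSeed(config$seed, 2L), {
    cols <- list(); truthRows <- list(); counts <- list()
    cellIdx <- 0L
    for (arm in config$arms) {
      eff <- applyTreatmentEffect(config, arm)
      s <- eff$armCouplingSign
      for (a in seq_len(config$nAnimalsPerArm)) {
        animal <- sprintf("%s_m%d", arm, a)
        animalFactor <- exp(rnorm(1, 0, config$animalSizeSD))
        nTot <- round(sum(vapply(config$populations,
                                 function(p) p$nCellsPerAnimal, 0)) +
                      (if (!is.null(config$trajectory))
                         config$trajectory$nCellsPerAnimal else 0))
        if (nTot == 0L) next
        nHuman <- rbinom(1, nTot, config$spikeinRate)
        nMouse <- nTot - nHuman
        popCells <- if (nMouse > 0 && sum(eff$armFractions) > 0)
          drop(rmultinom(1, nMouse, eff$armFractions)) else
          stats::setNames(rep(0L, length(eff$armFractions)),
                          names(eff$armFractions))
        plan <- c(rep(names(popCells), popCells), rep(".human", nHuman))
        mitoF <- sampleMitoFraction(config$mitoDist, length(plan))
        for (ci in seq_along(plan)) {
          cellIdx <- cellIdx + 1L
          bc <- sprintf("cell%05d", cellIdx)
          pop <- plan[ci]
          pst <- NA_real_; tier <- NA_integer_; phase <- "none"
          lineage <- FALSE
          if (pop == ".human") {
            p <- config$humanProgram
            species <- "human"
            f <- 0
          } else {
            species <- "mouse"
            f <- mitoF[ci]
            isTraj <- !is.null(config$trajectory) &&
              pop == config$trajectory$name
            if (isTraj) {
              tj <- config$trajectory
              tier <- sample.int(length(tj$tierCenters), 1,
                                 prob = eff$armTierWeights)
              ctr <- tj$tierCenters[tier]
              pst <- rbeta(1, ctr * tj$tierConc, (1 - ctr) * tj$tierConc)
              p <- trajProgram(tj, pst)
              if (pst < tj$cyclingTmax && runif(1) < tj$cyclingProb) {
                theta <- runif(1, 0, 2 * pi)
                w <- pmax(cos(theta - phaseCenters), 0)^2
                phase <- phases[which.max(w)]
                pp <- Reduce(`+`, Map(`*`, w / sum(w),
                                      config$phaseProgram[phases]))
                p <- (1 - config$phaseMass) * p + config$phaseMass * pp
              }
              lfr <- tj$lineageFraction
            } else {
              p <- config$populations[[pop]]$program
              lfr <- config$populations[[pop]]$lineageFraction
            }
            ## arm-signed regulator/target coupling over a latent factor
            u <- runif(1, -1, 1)
            p[config$coupling$regulator] <-
              p[config$coupling$regulator] *
              (1 + config$coupling$strength * u)
            p[config$coupling$target] <-
              p[config$coupling$target] *
              (1 + s * config$coupling$strength * u)
            p <- p / sum(p)
            lineage <- runif(1) < lfr
            if (lineage) {
              p <- (1 - config$yfpMass) * p
              p["Yfp"] <- p["Yfp"] + config$yfpMass
            }
          }
          p <- (1 - config$ambientRate) * p + config$ambientRate * amb
          if (f > 0) p <- (1 - f) * p + f * config$mitoProgram
          L <- if (is.infinite(config$librarySize))
            round(config$libraryMean * animalFactor)
          else rnbinom(1, size = config$librarySize,
                       mu = config$libraryMean * animalFactor)
          cnt <- if (L > 0) drop(rmultinom(1, L, p)) else rep(0L, G)
          counts[[cellIdx]] <- as.integer(cnt)
          cols[[cellIdx]] <- bc
          truthRows[[cellIdx]] <- data.frame(
            barcode = bc, population = pop, tier = tier, animal = animal,
            arm = arm, pseudotime = pst, phase = phase, isDoublet = FALSE,
            parent1 = NA_character_, parent2 = NA_character_,
            species = species, lineage = lineage, mitoFraction = f,
            librarySize = L, stringsAsFactors = FALSE)
        }
      }
    }
    list(counts = counts, cols = cols, truthRows = truthRows)
  })

  if (length(res$cols) == 0L) {
    mat <- Matrix::Matrix(0L, nrow = G, ncol = 0, sparse = TRUE)
    rownames(mat) <- geneIds
    truth <- S4Vectors::DataFrame(
      barcode = character(), population = character(), tier = integer(),
      animal = character(), arm = character(), pseudotime = numeric(),
      phase = character(), isDoublet = logical(), parent1 = character(),
      parent2 = character(), species = character(), lineage = logical(),
      mitoFraction = numeric(), librarySize = numeric())
  } else {
    mat <- matrix(unlist(res$counts), nrow = G,
                  dimnames = list(geneIds, unlist(res$cols)))
    mat <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
    truth <- S4Vectors::DataFrame(do.call(rbind, res$truthRows))
    rownames(truth) <- truth$barcode
  }

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = mat),
    rowData = S4Vectors::DataFrame(config$genes[, c("species", "mito",
                                                    "transgene")],
                                   row.names = geneIds),
    colData = S4Vectors::DataFrame(
      animal = truth$animal, arm = truth$arm,
      row.names = colnames(mat)))
  S4Vectors::metadata(sce)$simSeed <- config$seed

  if (config$doubletRate > 0 && ncol(sce) > 0) {
    dd <- injectDoublets(sce, truth, config$doubletRate,
                         seed = deriveSeed(config$seed, 3L))
    sce <- dd$sce; truth <- dd$truth
  }
  list(sce = sce, truth = truth)
}

#' Inject artificial doublet barcodes
#'
#' Appends \code{floor(rate * n)} new barcodes per animal, each the gene-wise
#' sum of two distinct randomly paired singlet barcodes of that animal
#' (sampling without replacement within a pair).  Truth records the parent
#' populations and sets the doublet flag.
#'
#' @param sce a \linkS4class{SingleCellExperiment} of counts.
#' @param truth the matching ground-truth \code{DataFrame}.
#' @param rate doublet fraction in [0, 1), relative to current barcodes.
#' @param seed RNG seed.
#' @param parents optional character pair restricting the two parent
#'   populations (one parent drawn from each); default unrestricted.
#' @return list with augmented \code{sce} and \code{truth}.
#' @export
injectDoublets <- function(sce, truth, rate, seed = 1L, parents = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || ncol(sce) == 0L) return(list(sce = sce, truth = truth))
  counts <- getCounts(sce)
  singlet <- !truth$isDoublet
  newCols <- list(); newTruth <- list(); k <- 0L
  withSeed(seed, {
    for (animal in unique(truth$animal)) {
      inAnimal <- which(singlet & truth$animal == animal)
      if (!is.null(parents)) {
        poolA <- inAnimal[truth$population[inAnimal] == parents[1]]
        poolB <- inAnimal[truth$population[inAnimal] == parents[2]]
        nD <- floor(rate * length(inAnimal))
        if (length(poolA) < 1L || length(poolB) < 1L) {
          warning("animal ", animal, " lacks singlets of the requested ",
                  "parent populations; skipped")
          next
        }
      } else if (length(inAnimal) < 2L) {
        warning("animal ", animal, " has fewer than 2 singlets; skipped")
        next
      } else nD <- floor(rate * length(inAnimal))
      if (nD < 1L) next
      for (d in seq_len(nD)) {
        pair <- if (is.null(parents)) sample(inAnimal, 2L) else {
          p1 <- sample(poolA, 1L)
          p2 <- sample(setdiff(poolB, p1), 1L)
          c(p1, p2)
        }
        k <- k + 1L
        newCols[[k]] <- as.integer(counts[, pair[1]] + counts[, pair[2]])
        newTruth[[k]] <- data.frame(
          barcode = sprintf("doublet%05d", k), population = "doublet",
          tier = NA_integer_, animal = animal, arm = truth$arm[pair[1]],
          pseudotime = NA_real_, phase = "none", isDoublet = TRUE,
          parent1 = truth$population[pair[1]],
          parent2 = truth$population[pair[2]],
          species = truth$species[pair[1]],
          lineage = truth$lineage[pair[1]] || truth$lineage[pair[2]],
          mitoFraction = NA_real_,
          librarySize = truth$librarySize[pair[1]] +
            truth$librarySize[pair[2]],
          stringsAsFactors = FALSE)
      }
    }
  })
  if (k == 0L) return(list(sce = sce, truth = truth))
  add <- matrix(unlist(newCols), nrow = nrow(counts),
                dimnames = list(rownames(counts),
                                vapply(newTruth, `[[`, "", "barcode")))
  addTruth <- S4Vectors::DataFrame(do.call(rbind, newTruth))
  rownames(addTruth) <- addTruth$barcode
  full <- cbind(as.matrix(counts), add)
  truthOut <- rbind(truth, addTruth)
  sceOut <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(full, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = SummarizedExperiment::rowData(sce),
    colData = S4Vectors::DataFrame(animal = truthOut$animal,
                                   arm = truthOut$arm,
                                   row.names = colnames(full)))
  S4Vectors::metadata(sceOut) <- S4Vectors::metadata(sce)
  list(sce = sceOut, truth = truthOut)
}

## Trajectory program at pseudotime t: affine interpolation of the
## marker-free base plus three stage-specific marker waves.  The waves are
## piecewise linear - early max(0, 1-2t), mid 1-|2t-1|, late max(0, 2t-1) -
## and sum to 1, so the marker block keeps constant mass while individual
## waves switch on and off between adjacent differentiation stages.
trajProgram <- function(tj, t) {
  wE <- max(0, 1 - 2 * t); wL <- max(0, 2 * t - 1); wM <- 1 - wE - wL
  (1 - t) * tj$baseEarly + t * tj$baseLate +
    tj$markerMass * (wE * tj$waveEarly + wM * tj$waveMid + wL * tj$waveLate)
}
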