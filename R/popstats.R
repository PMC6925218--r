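#' @include utils.R
NULL

#' Per-animal fractional population table
#'
#' Fractions are normalized to the total number of cells per animal, so
#' the animal is the statistical unit of all downstream cohort tests.
#'
#' @param groups per-cell group label (node, cluster or cell type).
#' @param animals per-cell animal id.
#' @param arms optional per-cell arm label (constant within animal).
#' @return data.frame with columns \code{animal}, \code{arm} (if given)
#'   and one fraction column per group; rows sum to 1 across groups.
#' @export
fractionalPopulations <- function(groups, animals, arms = NULL) {
  stopifnot(length(groups) == length(animals))
  keep <- !is.na(groups) & !is.na(animals)
  if (!all(keep)) warning(sum(!keep), " cells without group/animal dropped")
  groups <- groups[keep]; animals <- animals[keep]
  if (!is.null(arms)) arms <- arms[keep]
  tab <- table(animals, groups)
  tot <- rowSums(tab)
  empty <- tot == 0
  if (any(empty)) {
    warning("animal(s) with zero cells excluded: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]; tot <- tot[!empty]
  }
  fr <- sweep(unclass(tab), 1, tot, "/")
  out <- data.frame(animal = rownames(fr), stringsAsFactors = FALSE)
  if (!is.null(arms)) {
    armOf <- tapply(as.character(arms), animals, function(v) v[1])
    out$arm <- as.character(armOf[out$animal])
  }
  out <- cbind(out, as.data.frame(fr))
  rownames(out) <- out$animal
  out
}

#' Compare a group's per-animal fractions across arms
#'
#' @param table a \code{\link{fractionalPopulations}} data.frame with an
#'   \code{arm} column.
#' @param group the group (column) to test.
#' @param test "one_way_anova" or "two_sample_t" (Student's, equal
#'   variance; for two arms F = t^2 and the p-values agree).
#' @return list(statistic, df, p, test).
#' @export
compareArms <- function(table, group,
                        test = c("one_way_anova", "two_sample_t")) {
  test <- match.arg(test)
  stopifnot(group %in% names(table), "arm" %in% names(table))
  y <- table[[group]]
  arm <- factor(table$arm)
  if (any(tabulate(arm) < 2)) stop("need >= 2 animals per arm")
  if (var(y) == 0)
    return(list(statistic = 0, df = c(nlevels(arm) - 1,
                                      length(y) - nlevels(arm)),
                p = 1, test = test))
  if (test == "one_way_anova") {
    fit <- aov(y ~ arm)
    sm <- summary(fit)[[1]]
    list(statistic = sm$`F value`[1], df = sm$Df, p = sm$`Pr(>F)`[1],
         test = test)
  } else {
    if (nlevels(arm) != 2) stop("two_sample_t needs exactly 2 arms")
    tt <- t.test(y ~ arm, var.equal = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, test = test)
  }
}

#' Per-animal marker-positive fractions within groups
#'
#' A cell is marker-positive when its normalized expression strictly
#' exceeds the threshold.  Fractions are count-backed; a group absent in
#' an animal yields a missing value, not zero.
#'
#' @param x normalized input (\code{lognorm} assay or matrix).
#' @param groups,animals per-cell labels.
#' @param marker gene identifier.
#' @param threshold positivity cutoff on normalized expression.
#' @return data.frame(animal, group, n, nPos, fraction).
#' @export
markerPositiveFraction <- function(x, groups, animals, marker, threshold) {
  norm <- getLogNorm(x)
  if (!marker %in% rownames(norm)) stop("marker not present: ", marker)
  stopifnot(length(groups) == ncol(norm), length(animals) == ncol(norm))
  pos <- as.vector(norm[marker, ] > threshold)
  grid <- expand.grid(animal = unique(animals), group = unique(groups),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(a, g) sum(animals == a & groups == g),
                   grid$animal, grid$group)
  grid$nPos <- mapply(function(a, g) sum(pos & animals == a & groups == g),
                      grid$animal, grid$group)
  grid$fraction <- ifelse(grid$n > 0, grid$nPos / grid$n, NA_real_)
  grid
}

#' Two-way fixed-effects ANOVA on marker-positive rates
#'
#' Fits fraction ~ group + animal on a
#' \code{\link{markerPositiveFraction}} table and reports per-effect F and
#' p plus all pairwise group contrasts with Bonferroni adjustment.
#'
#' @param table data.frame with \code{fraction}, \code{group},
#'   \code{animal}.
#' @return list with \code{effects} (data.frame: effect, F, p) and
#'   \code{contrasts} (pairwise group contrasts).
#' @export
twoWayAnovaRates <- function(table) {
  tab <- table[!is.na(table$fraction), , drop = FALSE]
  if (length(unique(tab$group)) < 2L || length(unique(tab$animal)) < 2L)
    stop("each factor needs at least two levels")
  if (var(tab$fraction) == 0) {
    eff <- data.frame(effect = c("group", "animal"), F = c(0, 0),
                      p = c(1, 1))
    return(list(effects = eff, contrasts = NULL))
  }
  tab$group <- factor(tab$group); tab$animal <- factor(tab$animal)
  fit <- aov(fraction ~ group + animal, data = tab)
  sm <- summary(fit)[[1]]
  eff <- data.frame(effect = trimws(rownames(sm))[1:2],
                    F = sm$`F value`[1:2], p = sm$`Pr(>F)`[1:2])
  em <- emmeans::emmeans(fit, "group")
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "bonferroni"))
  list(effects = eff, contrasts = ct)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p by summing the probabilities of all tables with the
#' observed margins whose probability does not exceed the observed
#' table's; the conditional maximum-likelihood odds ratio is reported.
#' A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list(oddsRatio, p).
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  ft <- fisher.test(tab)
  list(oddsRatio = unname(ft$estimate), p = ft$p.value)
}

#' Upper-tail hypergeometric overlap test for two gene sets
#'
#' p = P(X >= observed overlap) for X ~ hypergeometric(|universe|,
#' |set A|, |set B|).
#'
#' @param setA,setB gene sets (subsets of \code{universe}).
#' @param universe the background gene set.
#' @return list(overlap, expected, p).
#' @export
hypergeomOverlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  obs <- length(intersect(setA, setB))
  N <- length(universe); m <- length(setA); k <- length(setB)
  list(overlap = obs, expected = m * k / N,
       p = phyper(obs - 1, m, N - m, k, lower.tail = FALSE))
}

#' Fold change between two fractions
#'
#' @param fracTreated,fracVehicle the two fractions (or means); the
#'   denominator must be positive.
#' @return the ratio fracTreated / fracVehicle.
#' @seealso \code{\link{foldChangeOfRatios}} for the mean-of-per-animal
#'   ratios companion, \code{\link{foldChangeBound}} when the denominator
#'   is zero.
#' @export
foldChange <- function(fracTreated, fracVehicle) {
  if (fracVehicle <= 0) stop("zero denominator: use foldChangeBound()")
  fracTreated / fracVehicle
}

#' Mean of per-animal fold ratios with its standard error
#' @param treated,vehicle per-animal fraction vectors (paired by position).
#' @return list(fc, sem, n).
#' @export
foldChangeOfRatios <- function(treated, vehicle) {
  if (any(vehicle <= 0)) stop("zero denominator in per-animal ratios")
  r <- treated / vehicle
  list(fc = mean(r), sem = sd(r) / sqrt(length(r)), n = length(r))
}

#' Lower bound on a fold change when the denominator is below detection
#' @param fracTreated observed numerator fraction.
#' @param detectionFloor smallest detectable denominator fraction.
#' @return list(bound, label) - "the fold change is at least `bound`".
#' @export
foldChangeBound <- function(fracTreated, detectionFloor) {
  stopifnot(detectionFloor > 0)
  b <- fracTreated / detectionFloor
  list(bound = b, label = sprintf(">= %.3g-fold", b))
}
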