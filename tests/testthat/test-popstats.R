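test_that("fractional populations normalize per animal", {
  groups <- c("A", "A", "B", "C", "A", "B")
  animals <- c("m1", "m1", "m1", "m1", "m2", "m2")
  pt <- fractionalPopulations(groups, animals,
                              arms = rep(c("vehicle", "treated"), c(4, 2)))
  expect_equal(pt["m1", "A"], 0.5)
  expect_equal(unname(rowSums(pt[, c("A", "B", "C")])), c(1, 1))
  expect_identical(pt$arm, c("vehicle", "treated"))
  ## single group: all fractions 1
  pt1 <- fractionalPopulations(rep("only", 4), rep(c("m1", "m2"), 2))
  expect_true(all(pt1$only == 1))
})

test_that("arm means on the simulated cohort track the programmed multipliers", {
  co <- studyCohort(11)
  sing <- !co$truth$isDoublet & co$truth$species == "mouse"
  pt <- fractionalPopulations(co$truth$population[sing],
                              co$truth$animal[sing], co$truth$arm[sing])
  for (arm in c("vehicle", "treated")) {
    eff <- applyTreatmentEffect(co$cfg, arm)
    sub <- pt[pt$arm == arm, ]
    for (p in c("CGNP", "astrocyte")) {
      est <- mean(sub[[p]])
      sem <- sd(sub[[p]]) / sqrt(nrow(sub))
      expect_lt(abs(est - eff$armFractions[[p]]), 3 * sem + 0.01)
    }
  }
})

test_that("arm comparisons cover ANOVA, t and degenerate conventions", {
  tab <- data.frame(animal = sprintf("m%d", 1:6),
                    arm = rep(c("vehicle", "treated"), each = 3),
                    g = c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5))
  ## identical per-animal values within arms, different between: textbook
  set.seed(1)
  tab$g <- tab$g + rnorm(6, 0, 1e-3)
  a <- compareArms(tab, "g", "one_way_anova")
  expect_lt(a$p, 0.01)
  ## hand-computed F from between/within mean squares
  g1 <- tab$g[1:3]; g2 <- tab$g[4:6]
  gm <- mean(tab$g)
  ssb <- 3 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(a$statistic, (ssb / 1) / (ssw / 4), tolerance = 1e-10)
  ## two arms: F = t^2 and equal p
  tt <- compareArms(tab, "g", "two_sample_t")
  expect_equal(tt$statistic^2, a$statistic, tolerance = 1e-10)
  expect_equal(tt$p, a$p, tolerance = 1e-12)
  ## identical values everywhere: F = 0, p = 1 convention
  tab0 <- transform(tab, g = 0.2)
  expect_equal(compareArms(tab0, "g")$p, 1)
})

test_that("marker-positive fractions are count-backed with missing groups", {
  m <- matrix(c(2, 2, 0, 0,
                0, 0, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("Yfp", "x"), sprintf("c%d", 1:4)))
  mf <- markerPositiveFraction(m, groups = c("g1", "g1", "g2", "g2"),
                               animals = c("m1", "m1", "m1", "m2"),
                               marker = "Yfp", threshold = 0)
  expect_equal(mf$fraction[mf$animal == "m1" & mf$group == "g1"], 1)
  expect_equal(mf$fraction[mf$animal == "m1" & mf$group == "g2"], 0)
  ## group absent in an animal: missing, not zero
  expect_true(is.na(mf$fraction[mf$animal == "m2" & mf$group == "g1"]))
  ## threshold above the maximum: all zero
  mf2 <- markerPositiveFraction(m, c("g1", "g1", "g2", "g2"),
                                c("m1", "m1", "m1", "m1"), "Yfp", 10)
  expect_true(all(mf2$fraction == 0))
  expect_error(markerPositiveFraction(m, "g", "m", "absent", 0), "marker")
})

test_that("two-way ANOVA separates a programmed lineage-rate effect", {
  set.seed(4)
  groups <- c("astrocyte", "oligodendrocyte", "endothelial", "vascular",
              "microglia")
  rate <- c(0.3, 0.3, 0, 0, 0)
  tab <- expand.grid(animal = sprintf("m%d", 1:5), group = groups,
                     stringsAsFactors = FALSE)
  tab$fraction <- rate[match(tab$group, groups)] +
    abs(rnorm(nrow(tab), 0, 0.02))
  res <- twoWayAnovaRates(tab)
  expect_lt(res$effects$p[res$effects$effect == "group"], 0.001)
  glialVsVasc <- subset(res$contrasts,
                        grepl("astrocyte|oligodendrocyte", contrast) &
                        grepl("endothelial|vascular|microglia", contrast))
  expect_true(all(glialVsVasc$p.value < 0.001))
  ## swapping the factor labels swaps effect rows, p unchanged
  res2 <- twoWayAnovaRates(data.frame(fraction = tab$fraction,
                                      group = tab$animal,
                                      animal = tab$group))
  expect_equal(sort(res$effects$p), sort(res2$effects$p), tolerance = 1e-12)
  ## all-equal fractions: zero F by convention
  tabEq <- transform(tab, fraction = 0.1)
  expect_equal(twoWayAnovaRates(tabEq)$effects$F, c(0, 0))
})

test_that("Fisher's exact test matches exhaustive enumeration", {
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(3, 3, 3, 3), 2))$p, 1)
  ## row swap: p unchanged, odds ratio inverted
  a <- fisherExact2x2(matrix(c(7, 2, 3, 8), 2))
  b <- fisherExact2x2(matrix(c(3, 8, 7, 2), 2))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$oddsRatio, 1 / b$oddsRatio, tolerance = 1e-6)
  ## zero margin: p = 1
  expect_equal(fisherExact2x2(matrix(c(0, 0, 4, 6), 2))$p, 1)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  ## independent enumeration oracle on a sample of small tables
  enumP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    as <- max(0, c1 - r2):min(r1, c1)
    pr <- dhyper(as, r1, r2, c1)
    pObs <- dhyper(tab[1, 1], r1, r2, c1)
    sum(pr[pr <= pObs * (1 + 1e-7)])
  }
  set.seed(6)
  for (i in 1:25) {
    tab <- matrix(sample(0:9, 4, TRUE), 2)
    expect_equal(fisherExact2x2(tab)$p, enumP(tab), tolerance = 1e-9)
  }
})

test_that("hypergeometric overlap matches closed forms and is monotone", {
  expect_equal(hypergeomOverlap(letters[1:5], letters[1:5], letters[1:10])$p,
               1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeomOverlap(letters[1:3], letters[4:6], letters[1:10])$p,
               1)
  ## set B = universe forces full overlap, p = 1
  expect_equal(hypergeomOverlap(letters[1:4], letters[1:10],
                                letters[1:10])$p, 1)
  expect_error(hypergeomOverlap(c("zz"), letters[1:3], letters[1:3]),
               "subsets")
  ## p is non-increasing in the observed overlap at fixed sizes
  ps <- vapply(0:5, function(k) {
    a <- letters[1:5]
    b <- c(letters[seq_len(k)], LETTERS[seq_len(5 - k)])
    hypergeomOverlap(a, b, c(letters[1:10], LETTERS[1:10]))$p
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("fold changes reproduce the published-scale arithmetic", {
  ## tumor 8.73% vs wild-type 0.04% GFAP+ fractions: above the 200-fold bound
  expect_equal(foldChange(8.73, 0.04), 218.25, tolerance = 1e-12)
  expect_gt(foldChange(8.73, 0.04), 200)
  expect_equal(foldChange(0.3, 0.3), 1)
  ## reciprocity
  expect_equal(foldChange(2, 5) * foldChange(5, 2), 1, tolerance = 1e-12)
  expect_error(foldChange(1, 0), "denominator")
  fr <- foldChangeOfRatios(c(0.2, 0.3), c(0.1, 0.1))
  expect_equal(fr$fc, 2.5)
  b <- foldChangeBound(8.73, 0.04)
  expect_match(b$label, ">=")
})
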