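test_that("response matrices carry the rare/common coding and balance", {
  sim <- simulateExperiment(experimentDesign(), seed = 41)
  lines <- buildLineRecords(PoolSeqCounts(sim$counts), sim$design)
  rm <- responseMatrix(lines, "s_I")
  expect_equal(nrow(rm), 12L)
  expect_equal(as.character(rm$sf[lines$start_freq == 0.2][1]), "rare")
  expect_equal(as.character(rm$sf[lines$start_freq == 0.8][1]), "common")
  expect_equal(attr(rm, "response"), "s_I")

  unbalanced <- rm[-1, ]
  expect_error(rmAnova(unbalanced), "unbalanced")
  oneLevel <- rm
  oneLevel$environment <- factor("homogeneous")
  expect_error(rmAnova(oneLevel), "two levels")
})

test_that("split-plot ANOVA has the canonical df and additive SS", {
  rm <- makeRespMatrix(42)
  tab <- rmAnova(rm)
  expect_equal(tab$df, c(1, 1, 1, 8, 1, 1, 1, 1, 8))
  expect_equal(tab$stratum, rep(c("between", "within"), c(4, 5)))
  expect_equal(sum(tab$df), 23)  # 12 lines x 2 measures - 1
  # SS additivity per stratum against the raw decomposition
  y <- c(rm$y1, rm$y2)
  lineMeans <- (rm$y1 + rm$y2) / 2
  ssBetween <- 2 * sum((lineMeans - mean(y))^2)
  ssWithin <- sum((y - rep(lineMeans, 2))^2)
  expect_equal(sum(tab$SS[tab$stratum == "between"]), ssBetween)
  expect_equal(sum(tab$SS[tab$stratum == "within"]), ssWithin)
})

test_that("a flat response yields zero SS and flagged F ratios", {
  rm <- makeRespMatrix(43)
  rm$y1 <- 0.7
  rm$y2 <- 0.7
  tab <- rmAnova(rm)
  expect_equal(tab$SS, rep(0, 9))
  expect_true(all(is.nan(tab$F[tab$term != "Residual"])))
})

test_that("ANOVA F matches the cell-mean/difference-score GLM oracle", {
  for (seed in 1:10) {
    rm <- makeRespMatrix(seed)
    tab <- rmAnova(rm)
    got <- setNames(tab$F[tab$term != "Residual"],
                    tab$term[tab$term != "Residual"])
    want <- oracleSplitPlotF(rm)
    expect_equal(got[names(want)], want, tolerance = 1e-8)
  }
})

test_that("ANOVA is invariant to row order and to measure swapping", {
  rm <- makeRespMatrix(44)
  tab <- rmAnova(rm)
  shuffled <- rm[sample(nrow(rm)), ]
  expect_equal(rmAnova(shuffled), tab)
  swapped <- rm
  swapped$y1 <- rm$y2
  swapped$y2 <- rm$y1
  expect_equal(rmAnova(swapped)$F, tab$F)
})

test_that("permutation p agrees with the exhaustive lm-based oracle", {
  rm <- makeRespMatrix(45, reps = 2L)       # 8 lines: enumerable
  rm$y1[rm$sf == "rare"] <- rm$y1[rm$sf == "rare"] + 1.2
  rm$y2[rm$sf == "rare"] <- rm$y2[rm$sf == "rare"] + 1.2
  m <- (rm$y1 + rm$y2) / 2
  labels <- paste(rm$sf, rm$environment)

  # exhaustive: every distinct assignment of the 8 label pairs is equally
  # likely under uniform permutation (equal multiplicity 2!^4), so enumerate
  # the 8!/2!^4 = 2520 distinct arrangements directly
  lvl <- unique(labels)
  distinctAssignments <- matrix(NA_character_, 0, 8)
  for (i in utils::combn(8, 2, simplify = FALSE)) {
    restI <- setdiff(1:8, i)
    for (j in utils::combn(restI, 2, simplify = FALSE)) {
      restJ <- setdiff(restI, j)
      for (k in utils::combn(restJ, 2, simplify = FALSE)) {
        lab <- character(8)
        lab[i] <- lvl[1]; lab[j] <- lvl[2]; lab[k] <- lvl[3]
        lab[setdiff(restJ, k)] <- lvl[4]
        distinctAssignments <- rbind(distinctAssignments, lab)
      }
    }
  }
  expect_equal(nrow(distinctAssignments), 2520L)
  fObs <- lmBetweenF(m, rm, "SF")
  fAll <- apply(distinctAssignments, 1, function(lab) {
    d <- rm
    d$sf <- factor(sub(" .*", "", lab), levels = levels(rm$sf))
    d$environment <- factor(sub(".* ", "", lab),
                            levels = levels(rm$environment))
    lmBetweenF(m, d, "SF")
  })
  pExh <- (sum(fAll >= fObs - 1e-12) + 1) / (length(fAll) + 1)

  nPerm <- 4000L
  pHat <- permutationTestBetween(rm, "SF", nPerm = nPerm, seed = 46)
  se <- sqrt(pExh * (1 - pExh) / nPerm)
  expect_lt(abs(pHat - pExh), 2 * se + 2 / nPerm)
})

test_that("permutation test is reproducible and maximal on flat data", {
  rm <- makeRespMatrix(47)
  p1 <- permutationTestBetween(rm, "E", nPerm = 999, seed = 48)
  p2 <- permutationTestBetween(rm, "E", nPerm = 999, seed = 48)
  expect_identical(p1, p2)
  flat <- rm
  flat$y1 <- 1
  flat$y2 <- 1
  expect_equal(permutationTestBetween(flat, "SF", nPerm = 99, seed = 1), 1)
})

test_that("permutation and parametric p agree on Gaussian null data", {
  diffs <- vapply(1:150, function(seed) {
    rm <- makeRespMatrix(seed + 500)
    tab <- rmAnova(rm, nPerm = 599, seed = seed)
    between <- tab[tab$stratum == "between" & tab$term != "Residual", ]
    mean(abs(between$p - between$p_perm))
  }, numeric(1))
  expect_lt(mean(diffs), 0.03)
})

test_that("bootstrap intervals behave on degenerate and binary data", {
  same <- bootstrapMeanCI(rep(0.4, 6), nBoot = 199, seed = 1)
  expect_equal(c(same$lower, same$upper), c(0.4, 0.4))
  mix <- bootstrapMeanCI(rep(c(0, 1), 6), nBoot = 2000, seed = 2)
  expect_equal(mix$estimate, 0.5)
  expect_true(mix$lower >= 0 && mix$upper <= 1)
  expect_true(mix$lower <= mix$estimate && mix$estimate <= mix$upper)
  expect_warning(one <- bootstrapMeanCI(0.3, nBoot = 99), "single value")
  expect_equal(c(one$lower, one$upper), c(0.3, 0.3))
  expect_error(bootstrapMeanCI(numeric(0)), "no values")
  x <- rnorm(10)
  expect_identical(bootstrapMeanCI(x, nBoot = 499, seed = 3),
                   bootstrapMeanCI(x, nBoot = 499, seed = 3))
})

test_that("the global t-test reduces each line to its mean estimate", {
  res <- globalTTest(c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_warning(flat <- globalTTest(rep(0, 5)), "zero variance")
  expect_true(is.nan(flat$t))
  expect_error(globalTTest(c(0.1, NA)), "undefined")

  rm <- makeRespMatrix(49)
  m <- perLineMeans(rm)
  expect_equal(unname(m), (rm$y1 + rm$y2) / 2)
  expect_named(m, rm$line_id)
})

test_that("group means mirror a constructed environment-dependent regime", {
  # large pools: isolates the regime contrast from pooled-fly sampling noise
  des <- experimentDesign(trueS = c(homogeneous = 0.25, heterogeneous = 0),
                          census = 10000L, founders = 10000L,
                          poolSize = 10000L, readDepth = 100000L)
  sim <- simulateExperiment(des, seed = 50)
  lines <- buildLineRecords(PoolSeqCounts(sim$counts), sim$design)
  rm <- responseMatrix(lines, "s_I")
  g <- groupMeans(rm, nBoot = 999, seed = 51)
  expect_equal(nrow(g), 4L)
  het <- g[g$environment == "heterogeneous" & g$sf == "common", ]
  expect_true(het$lower <= 0 && 0 <= het$upper)
  hom <- g[g$environment == "homogeneous", ]
  expect_true(all(hom$lower > 0))
})

test_that("identical regimes give exchangeable group intervals", {
  # noise-free limit: every cell shares the regime, so the four intervals
  # must overlap (here: collapse onto the same per-start-frequency value)
  des <- experimentDesign(trueS = 0.2, deterministic = TRUE,
                          readDepth = 1000000L)
  sim <- simulateExperiment(des, seed = 52)
  lines <- buildLineRecords(PoolSeqCounts(sim$counts), sim$design)
  g <- groupMeans(responseMatrix(lines, "s_I"), nBoot = 999, seed = 53)
  expect_equal(nrow(g), 4L)
  expect_true(max(g$lower) <= min(g$upper) + 1e-6)
  expect_lt(max(g$estimate) - min(g$estimate), 1e-4)
})
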