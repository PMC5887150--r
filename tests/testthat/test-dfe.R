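test_that("neutral SFS at constant size follows the 1/i law", {
  m <- expectedNeutralSFS(demography(1, 0.1, 200L), 4)
  props <- m[2:4] / sum(m[2:4])
  expect_equal(props, c(6, 3, 2) / 11, tolerance = 0.01)
  # with a mutation scale the classes are probabilities summing to 1
  p <- expectedNeutralSFS(demography(1, 0.1, 100L), 10, theta = 0.005)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  expect_true(all(p >= 0))
})

test_that("recent growth skews the neutral SFS toward singletons", {
  pConst <- expectedNeutralSFS(demography(1, 0.1, 200L), 10)
  pGrow <- expectedNeutralSFS(demography(100, 0.02, 200L), 10)
  singleton <- function(p) p[2] / sum(p[2:10])
  expect_gt(singleton(pGrow), singleton(pConst))
})

test_that("selected SFS reduces to neutral at S = 0 and skews under selection", {
  d <- demography(2, 0.2, 100L)
  pNeu <- expectedNeutralSFS(d, 10)
  pSel0 <- expectedSelectedSFS(d, pointDFE(0), 10)
  expect_equal(pSel0 / sum(pSel0), pNeu / sum(pNeu), tolerance = 1e-8)
  pDel <- expectedSelectedSFS(d, gammaDFE(100, 0.5), 10)
  # purifying selection: rare classes dominate more than under neutrality
  expect_gt(pDel[2] / pDel[10], pNeu[2] / pNeu[10])
})

test_that("gamma quadrature matches direct summation on a dense grid", {
  d <- demography(1.5, 0.25, 100L)
  dfe <- gammaDFE(50, 0.4)
  q <- expectedSelectedSFS(d, dfe, 10, nGrid = 32)
  # oracle: direct summation over a 50-point grid built differently
  # (uniform in log |S|, midpoint gamma mass)
  sGrid <- exp(seq(log(1e-4), log(1e5), length.out = 50))
  rate <- dfe$shape / dfe$meanNes
  edges <- c(0, sqrt(sGrid[-50] * sGrid[-1]), Inf)
  w <- diff(pgamma(edges, shape = dfe$shape, rate = rate))
  brute <- Reduce(`+`, lapply(seq_along(sGrid), function(i)
    w[i] * rnaiAdapt:::.sampleSFS(rnaiAdapt:::.wfOccupancy(d, -sGrid[i]), 100L, 10)))
  expect_equal(q / sum(q), brute / sum(brute), tolerance = 0.02)
  # grid-doubling convergence check passes at the default grid
  expect_no_error(expectedSelectedSFS(d, dfe, 10, nGrid = 32, check = TRUE))
})

test_that("relative fixation rate matches closed forms and is continuous at 0", {
  expect_equal(fixationRate(-2), 2 / (exp(2) - 1), tolerance = 1e-9)
  expect_equal(fixationRate(0), 1)
  expect_equal(fixationRate(1e-9), fixationRate(-1e-9), tolerance = 1e-6)
})

test_that("alphaOmega derives alpha and omega_A from closed forms", {
  d0 <- makeSFS(4, c(5, 3, 2), c(5, 3, 2), Dn = 100, Ds = 100, LN = 100, LS = 100)
  # point mass at S = 0: omega_na = 1; omega_obs = 1 -> alpha = 0
  ao <- alphaOmega(pointDFE(0), d0)
  expect_equal(ao$alpha, 0, tolerance = 1e-9)
  expect_equal(ao$omegaA, 0, tolerance = 1e-9)
  # point mass at S = -2 with omega_obs = 0.5
  d1 <- makeSFS(4, c(5, 3, 2), c(5, 3, 2), Dn = 50, Ds = 100, LN = 100, LS = 100)
  ao1 <- alphaOmega(pointDFE(-2), d1)
  expect_equal(ao1$omegaNa, 2 / (exp(2) - 1), tolerance = 1e-9)
  expect_equal(ao1$alpha, 1 - (2 / (exp(2) - 1)) / 0.5, tolerance = 1e-9)
  expect_equal(ao1$omegaA, 0.5 - 2 / (exp(2) - 1), tolerance = 1e-9)
  # omega_obs below omega_na gives a negative omega_A
  d2 <- makeSFS(4, c(5, 3, 2), c(5, 3, 2), Dn = 10, Ds = 100, LN = 100, LS = 100)
  expect_lt(alphaOmega(pointDFE(-2), d2)$omegaA, 0)
  # Ds = 0 is flagged, not fabricated
  d3 <- makeSFS(4, c(5, 3, 2), c(5, 3, 2), Dn = 10, Ds = 0, LN = 100, LS = 100)
  expect_true(alphaOmega(pointDFE(-2), d3)$undefined)
})

test_that("discretized DFE matches the gamma CDF and sums to 1", {
  dfe <- gammaDFE(50, 0.4)
  dd <- discretizeDFE(dfe)
  expect_equal(sum(dd), 1, tolerance = 1e-12)
  rate <- 0.4 / 50
  oracle <- vapply(list(c(0, 1), c(1, 10), c(10, 100), c(100, Inf)), function(b)
    integrate(function(x) dgamma(x, shape = 0.4, rate = rate), b[1], b[2],
              rel.tol = 1e-10)$value, 0)
  expect_equal(unname(dd), oracle, tolerance = 1e-6)
  # near-degenerate gamma with mean 5: almost all mass in [1, 10)
  expect_gt(discretizeDFE(gammaDFE(5, 500))[["[1,10)"]], 0.999)
  expect_equal(sum(discretizeDFE(pointDFE(-5))), 1)
})

test_that("neutral selected data drives fitted DFE mass below |Ne s| = 1", {
  cfg <- simConfig(seed = 5, nHaplotypes = 10, theta = 0.004,
                   demography = demography(1, 0.1, 100L), dfe = pointDFE(0),
                   omegaA = 0)
  sim <- simSFSDataset(cfg, LN = 4e5, LS = 4e5)
  fit <- fitDFE(sim)
  expect_gte(fit@discretized[["[0,1)"]], 0.9)
})

test_that("pooling is consistent: single gene and duplicated genes", {
  cfg <- simConfig(seed = 9, nHaplotypes = 10, theta = 0.004,
                   dfe = gammaDFE(30, 0.5), omegaA = 0.05)
  sim <- simSFSDataset(cfg, LN = 2e5, LS = 8e4)
  single <- fitDFE(sim)
  pooledSame <- poolAndEstimate(list(sim))
  expect_equal(pooledSame@omegaA, single@omegaA, tolerance = 1e-8)
  # duplicating a gene doubles every count: same proportions, same omega_A
  pooledDup <- poolAndEstimate(list(sim, sim))
  expect_lt(abs(pooledDup@omegaA - single@omegaA), 1e-4)
})

test_that("gene-unit bootstrap degenerates to zero width with one gene", {
  cfg <- simConfig(seed = 13, nHaplotypes = 10, theta = 0.004, omegaA = 0.05)
  sim <- simSFSDataset(cfg, LN = 2e5, LS = 8e4)
  suppressWarnings(bc <- bootstrapCI(list(sim), nBoot = 20, unit = "gene",
                                     refitDemography = FALSE))
  expect_equal(diff(bc$ci), 0, tolerance = 1e-10)
  expect_equal(bc$se, 0, tolerance = 1e-10)
})

test_that("gene-unit bootstrap SE shrinks roughly as 1/sqrt(genes)", {
  genes <- lapply(1:32, function(g)
    simSFSDataset(simConfig(seed = 100 + g, nHaplotypes = 10, theta = 0.004,
                            omegaA = 0.05), LN = 3e4, LS = 1.2e4))
  suppressWarnings({
    seSmall <- bootstrapCI(genes[1:8], nBoot = 40, unit = "gene",
                           refitDemography = FALSE, seed = 2)$se
    seLarge <- bootstrapCI(genes, nBoot = 40, unit = "gene",
                           refitDemography = FALSE, seed = 2)$se
  })
  expect_gt(seSmall / seLarge, 1.2)   # expected ratio 2 under homogeneity
  expect_lt(seSmall / seLarge, 3.5)
})

test_that("permutation test is valid under the null and powerful under separation", {
  mk <- function(seed, omegaA) simSFSDataset(
    simConfig(seed = seed, nHaplotypes = 10, theta = 0.004, omegaA = omegaA),
    LN = 5e4, LS = 2e4)
  same <- lapply(1:10, function(g) mk(200 + g, 0.05))
  pNull <- permutationTest(same[1:5], same[6:10], nPerm = 39, seed = 3)
  expect_gte(pNull$p, 1 / 40)
  # label swap flips the statistic's sign exactly (two-sidedness)
  pSwap <- permutationTest(same[6:10], same[1:5], nPerm = 39, seed = 3)
  expect_equal(pNull$statistic, -pSwap$statistic, tolerance = 1e-8)
  mk20 <- function(seed, omegaA) simSFSDataset(
    simConfig(seed = seed, nHaplotypes = 20, theta = 0.004, omegaA = omegaA),
    LN = 2e5, LS = 8e4)
  hi <- lapply(1:5, function(g) mk20(300 + g, 0.25))
  lo <- lapply(1:5, function(g) mk20(400 + g, 0))
  pSep <- permutationTest(hi, lo, nPerm = 39, seed = 3)
  expect_lte(pSep$p, 2 / 40)
})

test_that("shared-vs-separate DFE LRT behaves as a nested comparison", {
  mk <- function(seed, mean, shape) simSFSDataset(
    simConfig(seed = seed, nHaplotypes = 10, theta = 0.004,
              dfe = gammaDFE(mean, shape), omegaA = 0), LN = 2e5, LS = 8e4)
  a <- lapply(1:3, function(g) mk(500 + g, 50, 0.4))
  b <- lapply(1:3, function(g) mk(600 + g, 50, 0.4))
  res <- lrtSharedVsSeparate(a, b)
  expect_gte(res$LR, 0)
  expect_equal(res$df, 2L)
  # identical data in both classes: LR ~ 0
  resSame <- lrtSharedVsSeparate(a, a)
  expect_lt(resSame$LR, 0.05)
  # strongly different DFEs: decisive rejection
  c2 <- lapply(1:3, function(g) mk(700 + g, 2000, 1.5))
  resDiff <- lrtSharedVsSeparate(a, c2)
  expect_lt(resDiff$p, 1e-4)
})

test_that("fit likelihood never decreases when DFE parameters are freed", {
  mk <- function(seed, mean) simSFSDataset(
    simConfig(seed = seed, nHaplotypes = 10, theta = 0.004,
              dfe = gammaDFE(mean, 0.4), omegaA = 0), LN = 1e5, LS = 4e4)
  a <- list(mk(801, 30)); b <- list(mk(802, 300))
  res <- lrtSharedVsSeparate(a, b)
  expect_gte(res$fitA$logLik + res$fitB$logLik, res$sharedLogLik - 1e-6)
})
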