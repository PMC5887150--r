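test_that("hitchhiking transform honors its degenerate limits and normalization", {
  bg <- c(0.5, 0.2, 0.1, 0.08, 0.06, 0.03, 0.03)
  n <- 6
  expect_equal(sweepSpectrum(bg, 1), bg, tolerance = 1e-12)
  s0 <- sweepSpectrum(bg, 0)
  expect_equal(sum(s0[c(1, n + 1)]), 1, tolerance = 1e-12)
  expect_true(all(s0[2:n] == 0))
  set.seed(1)
  for (i in 1:10) {
    b <- runif(n + 1); b <- b / sum(b)
    expect_equal(sum(sweepSpectrum(b, runif(1))), 1, tolerance = 1e-10)
  }
  expect_error(sweepSpectrum(c(-0.1, 0.6, 0.5), 0.5), "negative")
})

test_that("hitchhiking transform matches direct Monte-Carlo simulation", {
  n <- 5
  bg <- rep(1 / 6, 6)  # uniform over classes 0..5
  exact <- sweepSpectrum(bg, 0.5)
  mc <- sweepSpectrumMC(bg, 0.5, n, nDraws = 2e5, seed = 9)
  se <- sqrt(exact * (1 - exact) / 2e5)
  expect_true(all(abs(mc - exact) < 4 * se + 1e-12))
})

test_that("CLR scan is nonnegative and translation invariant", {
  cfg <- simConfig(seed = 17, nHaplotypes = 8, theta = 0.01,
                   regionLengthBp = 4000L)
  reg <- simNeutralRegion(cfg)$sites
  scan <- clrScan(reg, gridSpacingBp = 200)
  expect_true(all(scan@clr >= 0))
  shifted <- regionSites(reg@positions + 5000, reg@counts, reg@n,
                         background = reg@background)
  scan2 <- clrScan(shifted, gridSpacingBp = 200)
  expect_equal(scan@clr, scan2@clr, tolerance = 1e-9)
  expect_error(clrScan(regionSites(numeric(0), integer(0), 8L,
                                   background = rep(1 / 9, 9))), "empty")
})

test_that("CLR scan localizes a strong simulated sweep", {
  n <- 10
  neutral <- expectedNeutralSFS(demography(1, 0.1, 100L), n, theta = 0.008)
  cfg <- simConfig(seed = 23, nHaplotypes = n, regionLengthBp = 10000L,
                   sweep = list(sweepIntensity = 3e-4, sweepPositionBp = 5000L))
  reg <- simSweepRegion(cfg, neutral)
  scan <- clrScan(reg, gridSpacingBp = 500)
  peak <- scan@positions[which.max(scan@clr)]
  expect_lt(abs(peak - 5000), 1000)
  expect_gt(max(scan@clr), 10)
})

test_that("threshold is the type-7 quantile of neutral maxima", {
  expect_equal(sweepThreshold(1:100), 95.05)
  expect_equal(sweepThreshold(1:100, level = 1), 100)
  expect_lte(sweepThreshold(1:100, 0.9), sweepThreshold(1:100, 0.99))
  expect_warning(sweepThreshold(1:50), "100")
})

test_that("peak merging follows the 1-kb rule", {
  mkScan <- function(pos, clr) new("CLRScan", positions = pos, clr = clr,
                                   alphaHat = rep(Inf, length(pos)),
                                   threshold = NA_real_,
                                   intervals = data.frame(start = numeric(0),
                                                          end = numeric(0)))
  none <- callSweepRegions(mkScan(c(0, 500, 1000), c(1, 2, 1)), threshold = 5)
  expect_equal(nrow(none@intervals), 0)
  near <- callSweepRegions(mkScan(c(0, 800), c(10, 10)), threshold = 5)
  expect_equal(nrow(near@intervals), 1)
  far <- callSweepRegions(mkScan(c(0, 1500), c(10, 10)), threshold = 5)
  expect_equal(nrow(far@intervals), 2)
})

test_that("sweep enrichment equals exact binomial enumeration", {
  # genes arranged so that exactly 6 of 10 sweep-positive genes are RNAi and
  # the RNAi length share is 0.2
  mkGenes <- function() {
    starts <- seq(0, by = 20000, length.out = 20)
    isRnai <- rep(c(TRUE, FALSE), 10)
    widths <- ifelse(isRnai, 500, 2000)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(start = starts + 1,
                                                    width = widths),
                           is_rnai = isRnai)
  }
  genes <- mkGenes()
  # sweep intervals overlapping RNAi genes 1,3,5,7,9,11 and control 2,4,6,8
  hit <- c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8)
  ivs <- data.frame(start = GenomicRanges::start(genes)[hit] - 1,
                    end = GenomicRanges::start(genes)[hit] + 10)
  res <- sweepEnrichment(ivs, genes, proximityBp = 0)
  expect_equal(res$kRnai, 6); expect_equal(res$nTotal, 10)
  expect_equal(res$p0, 10 * 500 / (10 * 500 + 10 * 2000))  # = 0.2
  expect_equal(res$binomialP, binomUpperByEnumeration(6, 10, res$p0),
               tolerance = 1e-12)
  # no sweep-positive genes
  empty <- sweepEnrichment(data.frame(start = numeric(0), end = numeric(0)),
                           genes)
  expect_equal(empty$binomialP, 1)
  # p0 = 1 (all genes RNAi): p = 1
  allR <- genes; S4Vectors::mcols(allR)$is_rnai <- TRUE
  expect_equal(sweepEnrichment(ivs, allR)$binomialP, 1)
})

test_that("enrichment p equals enumeration across table sizes up to 25", {
  set.seed(7)
  for (i in 1:30) {
    nTot <- sample(1:25, 1); k <- sample(0:nTot, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(pbinom(k - 1, nTot, p0, lower.tail = FALSE),
                 binomUpperByEnumeration(k, nTot, p0), tolerance = 1e-10)
  }
})

test_that("normalized CLR model recovers null effects and species variance", {
  set.seed(11)
  nG <- 40
  species <- rep(c("spA", "spB", "spC", "spD"), each = nG)
  spEff <- rep(c(-0.5, 0, 0.3, 0.6), each = nG)
  classes <- rep(rep(c("control", "piRNA"), each = nG / 2), 4)
  y <- 1 + spEff + rnorm(length(spEff), 0, 0.3)
  res <- normalizedClrModel(y, thresholds = rep(1, length(y)),
                            classes = classes, species = species,
                            mcmc = list(nChains = 1, nIter = 1500, seed = 4))
  expect_lt(abs(res$effects$estimate[res$effects$class == "piRNA"]), 0.15)
  expect_gt(res$effects$mcmcp[1], 0.05)
  # species variance share: true share = var(spEff)/(var+0.09) ~ 0.65
  expect_gt(res$speciesShare, 0.4)
  expect_lt(res$speciesShare, 0.9)
  expect_warning(
    normalizedClrModel(y[1:nG], rep(1, nG), classes[1:nG], species[1:nG],
                       mcmc = list(nChains = 1, nIter = 500, seed = 4)),
    "single species")
})

test_that("nSL matches the brute-force implementation on random matrices", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:8, 1); m <- sample(5:12, 1)
    mat <- matrix(rbinom(n * m, 1, runif(1, 0.3, 0.7)), n, m)
    d <- colSums(mat)
    if (all(d < 2 | (n - d) < 2)) next
    h <- new("HaplotypeMatrix", mat = mat, positions = as.numeric(seq_len(m)))
    res <- nslScan(h, freqBins = 1)
    oracle <- nslBruteForce(mat)
    keep <- which(!is.na(oracle))
    expect_equal(res$position, as.numeric(keep))
    expect_equal(res$rawNsl, oracle[keep], tolerance = 1e-12)
  }
})

test_that("nSL is zero under mirror symmetry and skips singleton sites", {
  # derived and ancestral carrier groups with mirror-identical structure
  blockA <- matrix(c(1, 1, 0, 0,
                     1, 0, 1, 0), nrow = 2, byrow = TRUE)
  mat <- rbind(cbind(1, blockA), cbind(0, blockA))
  h <- new("HaplotypeMatrix", mat = mat, positions = as.numeric(1:5))
  res <- nslScan(h, freqBins = 1)
  expect_equal(res$rawNsl[res$position == 1], 0, tolerance = 1e-12)
  # a singleton site is skipped under minClassSize = 2
  mat2 <- matrix(c(1, 1, 0, 0,
                   0, 1, 1, 0,
                   0, 0, 1, 1,
                   0, 0, 0, 1), 4, 4, byrow = TRUE)
  h2 <- new("HaplotypeMatrix", mat = mat2, positions = as.numeric(1:4))
  res2 <- nslScan(h2, freqBins = 1)
  expect_false(1 %in% res2$position)
  expect_error(nslScan(new("HaplotypeMatrix",
                           mat = matrix(0, 4, 2), positions = c(1, 2))),
               "monomorphic")
})
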