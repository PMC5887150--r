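fastMeta <- function(seed = 1) list(nChains = 1, nAdapt = 400, nBurn = 200,
                                    nIter = 1500, seed = seed)

simOmegaTable <- function(seed, nPerClass = 40, means = c(0.01, 0.06),
                          sdResid = c(0.01, 0.03), se = 0.01, nSpecies = 4,
                          sdSpecies = 0.005) {
  withSeed(seed, {
    rows <- list()
    for (cl in 1:2) for (sp in 1:nSpecies) {
      nG <- nPerClass / nSpecies
      spEff <- rnorm(1, 0, sdSpecies)
      truth <- means[cl] + spEff + rnorm(nG, 0, sdResid[cl])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%d_%d_%d", cl, sp, seq_len(nG)),
        species_id = paste0("sp", sp),
        homolog_id = sprintf("hom%d_%d", cl, seq_len(nG)),
        omega_a = truth + rnorm(nG, 0, se), se_omega_a = se,
        is_rnai = cl == 2,
        pathway = if (cl == 2) "piRNA" else "control",
        pirna_function = if (cl == 2) "biogenesis" else NA,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

test_that("a noiseless class collapses to its common value", {
  tab <- data.frame(gene_id = paste0("g", 1:12), species_id = "sp1",
                    homolog_id = paste0("h", 1:12),
                    omega_a = 0.05, se_omega_a = 1e-6,
                    is_rnai = TRUE, pathway = "piRNA",
                    pirna_function = NA, stringsAsFactors = FALSE)
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(2))
  cm <- metaClassMeans(fit)
  expect_equal(cm$estimate, 0.05, tolerance = 1e-3)
  expect_lt(mean(fit@draws[, "sdResid_RNAi"]^2), 1e-5)
})

test_that("class means and class-specific variances are recovered", {
  tab <- simOmegaTable(seed = 101)
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(3))
  cm <- metaClassMeans(fit)
  ctrl <- cm[cm$class == "control", ]; rnai <- cm[cm$class == "RNAi", ]
  expect_true(ctrl$ciLow <= 0.01 && 0.01 <= ctrl$ciHigh)
  expect_true(rnai$ciLow <= 0.06 && 0.06 <= rnai$ciHigh)
  # the RNAi residual variance is larger, as generated
  cv <- compareVariances(fit, "RNAi", "control")
  expect_gt(cv$varianceDiff, 0)
})

test_that("variance comparison is calibrated in its degenerate cases", {
  tab <- simOmegaTable(seed = 201, nPerClass = 60, means = c(0.03, 0.03),
                       sdResid = c(0.02, 0.02))
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(5))
  cv <- compareVariances(fit, "RNAi", "control")
  expect_gt(cv$varianceMcmcp, 0.05)
  expect_lt(abs(cv$varianceDiff), 4e-4)
  tab2 <- simOmegaTable(seed = 301, means = c(0.03, 0.03),
                        sdResid = c(0.01, 0.0316) * sqrt(10))
  fit2 <- fitMeta(tab2, "rnai_vs_control", mcmc = fastMeta(7))
  cv2 <- compareVariances(fit2, "RNAi", "control")
  expect_lt(cv2$varianceMcmcp, 0.05)
})

test_that("measurement error is honored: shrinkage limits hold", {
  tab <- simOmegaTable(seed = 401, nPerClass = 20, nSpecies = 1)
  # one gene with an enormous SE, one with a tiny SE
  tab$se_omega_a[1] <- 10; tab$omega_a[1] <- 5
  tab$se_omega_a[2] <- 1e-7
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(9))
  pm <- predictedMeans(fit)
  classMean <- mean(fit@draws[, "mean_control"])
  expect_lt(abs(pm[1] - classMean), 0.02)          # se -> Inf: class mean
  expect_lt(abs(pm[2] - tab$omega_a[2]), 1e-3)     # se -> 0: own estimate
})

test_that("ignoring measurement error inflates the residual variance", {
  tab <- simOmegaTable(seed = 501, sdResid = c(0.01, 0.01), se = 0.03)
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(11))
  tabNoSe <- tab; tabNoSe$se_omega_a <- 1e-6
  fitNoSe <- fitMeta(tabNoSe, "rnai_vs_control", mcmc = fastMeta(11))
  v <- mean(fit@draws[, "sdResid_control"]^2)
  vNo <- mean(fitNoSe@draws[, "sdResid_control"]^2)
  expect_gt(vNo, v)
  expect_lt(abs(v - 0.01^2), 0.0004)
})

test_that("the class mean agrees with an independent meta-analysis fit", {
  skip_if_not_installed("metafor")
  tab <- simOmegaTable(seed = 601, nPerClass = 40, nSpecies = 1)
  one <- tab[!tab$is_rnai, ]
  fit <- fitMeta(tab, "rnai_vs_control", mcmc = fastMeta(13))
  rma <- metafor::rma(yi = one$omega_a, sei = one$se_omega_a, method = "REML")
  est <- metaClassMeans(fit)
  expect_equal(est$estimate[est$class == "control"],
               as.numeric(rma$beta), tolerance = 0.005)
})

test_that("homolog models run and small classes are rejected by name", {
  tab <- simOmegaTable(seed = 701)
  fit <- fitMeta(tab, "homolog", mcmc = fastMeta(15))
  expect_true(any(grepl("^hom_", colnames(fit@draws))))
  fit2 <- fitMeta(tab, "homolog_no_pathway", mcmc = fastMeta(15))
  expect_equal(fit2@classes, "all")
  bad <- tab; bad$pathway[bad$pathway == "piRNA"][-1] <- "control"
  expect_error(fitMeta(bad, "pathway", mcmc = fastMeta(1)), "piRNA")
  neg <- tab; neg$se_omega_a[3] <- -1
  expect_error(fitMeta(neg, "rnai_vs_control"), "nonnegative")
})

test_that("variance partition matches hand-computed sums of squares", {
  # orthogonal two-factor construction: 2 species x 4 homologs, 2 pathways
  tab <- expand.grid(species_id = c("sp1", "sp2"),
                     homolog_id = c("h1", "h2", "h3", "h4"),
                     stringsAsFactors = FALSE)
  tab$pathway <- ifelse(tab$homolog_id %in% c("h1", "h2"), "control", "piRNA")
  spEff <- c(sp1 = -0.01, sp2 = 0.01)
  homEff <- c(h1 = 0, h2 = 0.02, h3 = 0.05, h4 = 0.07)
  tab$gene_id <- paste0(tab$homolog_id, "_", tab$species_id)
  tab$omega_a <- spEff[tab$species_id] + homEff[tab$homolog_id]
  vp <- suppressWarnings(variancePartition(tab))
  ssSp <- 8 * var(rep(spEff, 4)) * 7 / 8 * 8 / 7  # total SS of species factor
  sst <- sum((tab$omega_a - mean(tab$omega_a))^2)
  expect_equal(vp$pctSpecies, 100 * sum((spEff[tab$species_id] -
                                           mean(spEff[tab$species_id]))^2) / sst,
               tolerance = 1e-8)
  expect_equal(vp$pctSpecies + vp$pctGenePlusPathway + vp$pctResidual, 100,
               tolerance = 1e-8)
  expect_equal(vp$pctResidual, 0, tolerance = 1e-6)
  # no species differences by construction
  tab2 <- tab; tab2$omega_a <- homEff[tab2$homolog_id]
  expect_lt(suppressWarnings(variancePartition(tab2))$pctSpecies, 1e-8)
})
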