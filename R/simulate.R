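# Generators for every input the pipeline consumes, with the statistical
# structure the analyses assume. Each generator derives its RNG stream from
# the master seed via opSeed(), so identical seeds give byte-identical
# output and streams are independent across operations.

#' Generative parameters for the synthetic-data module
#'
#' @param seed master integer seed.
#' @param nHaplotypes ingroup sample size.
#' @param theta scaled mutation rate per site (4 Ne u).
#' @param regionLengthBp region length in bp.
#' @param demography a \code{\link{demography}} list.
#' @param dfe a \code{\link{gammaDFE}} or \code{\link{pointDFE}}.
#' @param omegaA true adaptive nonsynonymous substitution excess (per
#'   synonymous substitution per site) added on top of the DFE's nonadaptive
#'   omega when drawing divergence counts.
#' @param divPerSite synonymous divergence per site used for divergence draws.
#' @param sweep optional list with \code{sweepIntensity} (alpha_s > 0; escape
#'   probability at distance d is 1 - exp(-alpha_s d), so larger values mean
#'   weaker hitchhiking) and \code{sweepPositionBp}.
#' @param countsModel optional hierarchical-effect values, see
#'   \code{\link{countsModel}}.
#' @return a SimConfig list.
#' @export
simConfig <- function(seed = 1L, nHaplotypes = 20L, theta = 0.01,
                      regionLengthBp = 20000L, demography = rnaiAdapt::demography(),
                      dfe = gammaDFE(50, 0.4), omegaA = 0, divPerSite = 0.05,
                      sweep = NULL, countsModel = rnaiAdapt::countsModel()) {
  .assertScalarNum(seed, "seed")
  .assertScalarNum(nHaplotypes, "nHaplotypes", lower = 1)
  .assertScalarNum(theta, "theta", lower = 0)
  .assertScalarNum(regionLengthBp, "regionLengthBp", lower = 1)
  .assertScalarNum(divPerSite, "divPerSite", lower = 0)
  if (!is.null(sweep)) {
    .assertScalarNum(sweep$sweepIntensity, "sweepIntensity", lower = 1e-12)
    .assertScalarNum(sweep$sweepPositionBp, "sweepPositionBp", lower = 0)
  }
  list(seed = as.integer(seed), nHaplotypes = as.integer(nHaplotypes),
       theta = theta, regionLengthBp = as.integer(regionLengthBp),
       demography = .checkDemography(demography), dfe = dfe, omegaA = omegaA,
       divPerSite = divPerSite, sweep = sweep, countsModel = countsModel)
}

#' Hierarchical-effect values for the count-table generator
#'
#' Log-linear effects of the generative twin of the cross-species count
#' model. Defaults are realistic for Drosophila-scale data: synonymous
#' polymorphism around exp(mu) per site, a nonsynonymous reduction of
#' exp(betaN), divergence exceeding polymorphism by exp(betaD), and no
#' selection effect (betaND = 0).
#'
#' @param mu intercept (log counts per site for synonymous polymorphism).
#' @param betaN nonsynonymous main effect.
#' @param betaD divergence main effect.
#' @param betaND selection (nonsynonymous x divergence) interaction.
#' @param sdSpecies SD of species effects on each of (1, N, D, ND);
#'   the reference species is fixed at zero.
#' @param sdGene SDs of gene-within-species deviations on (1, N, D, ND).
#' @param sdHomolog SDs of homolog deviations on (N, ND).
#' @param sdObs SD of the observation-level log-normal overdispersion.
#' @param pathwayN,pathwayND named numeric vectors of pathway effects on the
#'   N and ND terms (pathways absent from the vector have effect 0).
#' @return a counts-model list.
#' @export
countsModel <- function(mu = -1.5, betaN = -1.4, betaD = 0.5, betaND = 0,
                        sdSpecies = 0, sdGene = c(0, 0, 0, 0),
                        sdHomolog = c(0, 0), sdObs = 0,
                        pathwayN = numeric(0), pathwayND = numeric(0)) {
  stopifnot(length(sdGene) == 4L, length(sdHomolog) == 2L,
            all(c(sdSpecies, sdGene, sdHomolog, sdObs) >= 0))
  list(mu = mu, betaN = betaN, betaD = betaD, betaND = betaND,
       sdSpecies = sdSpecies, sdGene = sdGene, sdHomolog = sdHomolog,
       sdObs = sdObs, pathwayN = pathwayN, pathwayND = pathwayND)
}

#' Simulate a cross-species MK count table with known effects
#'
#' Generative twin of the hierarchical count model: the four counts per
#' gene x species are Poisson with log mean = offset (log L_N or log L_S)
#' plus the configured fixed, species, pathway, gene and homolog effects and
#' observation-level log-normal overdispersion. True effect values are
#' recorded in the \code{"truth"} attribute.
#'
#' @param config a \code{\link{simConfig}} with a \code{countsModel}.
#' @param nGenes number of homologs.
#' @param nSpecies number of species (species 1 is the reference).
#' @param LN,LS optional per-homolog site totals; drawn if NULL.
#' @param pathways optional per-homolog pathway labels (default "control").
#' @return a data.frame of MK records (one row per gene x species) with a
#'   \code{"truth"} attribute.
#' @export
simMKTable <- function(config, nGenes, nSpecies = 1L, LN = NULL, LS = NULL,
                       pathways = NULL) {
  if (nGenes < 1 || nSpecies < 1) stop("nGenes and nSpecies must be positive")
  cm <- config$countsModel
  if (is.null(cm)) stop("config has no countsModel")
  withSeed(opSeed(config$seed, "simMKTable"), {
    if (is.null(LN)) {
      codons <- round(stats::runif(nGenes, 200, 800))
      LN <- 2.2 * codons; LS <- 0.8 * codons
    }
    stopifnot(length(LN) == nGenes, length(LS) == nGenes, all(LN > 0), all(LS > 0))
    if (is.null(pathways)) pathways <- rep("control", nGenes)
    pwN <- function(p) if (p %in% names(cm$pathwayN)) cm$pathwayN[[p]] else 0
    pwND <- function(p) if (p %in% names(cm$pathwayND)) cm$pathwayND[[p]] else 0
    spEff <- matrix(stats::rnorm(nSpecies * 4, 0, cm$sdSpecies), nSpecies, 4)
    spEff[1, ] <- 0
    homEff <- cbind(stats::rnorm(nGenes, 0, cm$sdHomolog[1]),
                    stats::rnorm(nGenes, 0, cm$sdHomolog[2]))
    rows <- vector("list", nGenes * nSpecies)
    geneEff <- array(0, dim = c(nGenes, nSpecies, 4))
    for (k in 1:4) geneEff[, , k] <- stats::rnorm(nGenes * nSpecies, 0, cm$sdGene[k])
    idx <- 0L
    for (s in seq_len(nSpecies)) for (g in seq_len(nGenes)) {
      idx <- idx + 1L
      draw <- function(IN, ID) {
        eta <- log(if (IN) LN[g] else LS[g]) + cm$mu +
          cm$betaN * IN + cm$betaD * ID + cm$betaND * IN * ID +
          spEff[s, 1] + spEff[s, 2] * IN + spEff[s, 3] * ID + spEff[s, 4] * IN * ID +
          pwN(pathways[g]) * IN + pwND(pathways[g]) * IN * ID +
          geneEff[g, s, 1] + geneEff[g, s, 2] * IN + geneEff[g, s, 3] * ID +
          geneEff[g, s, 4] * IN * ID +
          homEff[g, 1] * IN + homEff[g, 2] * IN * ID +
          (if (cm$sdObs > 0) stats::rnorm(1, 0, cm$sdObs) else 0)
        stats::rpois(1, exp(eta))
      }
      rows[[idx]] <- data.frame(
        gene_id = sprintf("g%04d_sp%d", g, s), species_id = paste0("sp", s),
        homolog_id = sprintf("hom%04d", g), pathway = pathways[g],
        is_rnai = pathways[g] != "control", pirna_function = NA_character_,
        Pn = draw(1, 0), Ps = draw(0, 0), Dn = draw(1, 1), Ds = draw(0, 1),
        L_N = LN[g], L_S = LS[g], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(countsModel = cm, speciesEffects = spEff,
                               homologEffects = homEff, geneEffects = geneEff,
                               LN = LN, LS = LS, pathways = pathways)
    out
  })
}

#' Simulate a paired SFS dataset with known omega_A
#'
#' Neutral SFS sites are multinomial draws from the expected neutral class
#' probabilities, selected sites from the expected spectrum under the
#' configured DFE (same per-site mutation scale theta). Divergence counts are
#' Poisson with synonymous rate \code{divPerSite} and nonsynonymous rate
#' \code{divPerSite * (omega_na + omegaA)}. The generating truth is recorded
#' in the \code{"truth"} attribute.
#'
#' @param config a \code{\link{simConfig}}.
#' @param LN,LS nonsynonymous and synonymous site totals.
#' @return a \linkS4class{PairedSFS} with a \code{"truth"} attribute.
#' @export
simSFSDataset <- function(config, LN = 1e6, LS = LN / 2.75) {
  n <- config$nHaplotypes
  if (n < 2L) stop("nHaplotypes must be at least 2")
  pNeu <- expectedNeutralSFS(config$demography, n, theta = config$theta)
  pSel <- expectedSelectedSFS(config$demography, config$dfe, n, theta = config$theta)
  omegaNa <- .omegaNonadaptive(config$dfe)
  withSeed(opSeed(config$seed, "simSFSDataset"), {
    neu <- as.numeric(stats::rmultinom(1, round(LS), pNeu))
    sel <- as.numeric(stats::rmultinom(1, round(LN), pSel))
    Ds <- stats::rpois(1, config$divPerSite * LS)
    Dn <- stats::rpois(1, config$divPerSite * (omegaNa + config$omegaA) * LN)
    out <- new("PairedSFS", n = n,
               neutralSfs = neu[2:n], selectedSfs = sel[2:n],
               invariantNeutral = neu[1] + neu[n + 1],
               invariantSelected = sel[1] + sel[n + 1],
               Dn = Dn, Ds = Ds, LN = LN, LS = LS)
    attr(out, "truth") <- list(omegaA = config$omegaA, omegaNa = omegaNa,
                               dfe = config$dfe, demography = config$demography,
                               theta = config$theta)
    out
  })
}

#' Simulate a neutral region
#'
#' Either a standard neutral coalescent without recombination (mode
#' "coalescent") or an independent-sites draw from a supplied background
#' spectrum (mode "spectrum", used for threshold calibration). Positions are
#' uniform on the region; every site in the region is reported so invariant
#' sites enter downstream scans.
#'
#' @param config a \code{\link{simConfig}}.
#' @param mode "coalescent" or "spectrum".
#' @param background spectrum over derived counts 0..n (mode "spectrum").
#' @param rep replicate index for the RNG stream.
#' @return list with \code{haplotypes} (a \linkS4class{HaplotypeMatrix},
#'   coalescent mode only) and \code{sites} (a \linkS4class{RegionSites}).
#' @export
simNeutralRegion <- function(config, mode = c("coalescent", "spectrum"),
                             background = NULL, rep = 1L) {
  mode <- match.arg(mode)
  n <- config$nHaplotypes
  L <- config$regionLengthBp
  if (n < 2L) stop("nHaplotypes must be at least 2")
  withSeed(opSeed(config$seed, paste0("simNeutralRegion.", mode), rep), {
    if (mode == "spectrum") {
      stopifnot(length(background) == n + 1L, all(background >= 0))
      background <- background / sum(background)
      counts <- sample(0:n, L, replace = TRUE, prob = background)
      sites <- regionSites(0:(L - 1L), counts, n, background = background)
      return(list(haplotypes = NULL, sites = sites))
    }
    # Hudson coalescent, no recombination
    active <- as.list(seq_len(n))
    blen <- numeric(0); bleaves <- list()
    k <- n
    while (k > 1L) {
      t <- stats::rexp(1, rate = k * (k - 1) / 2)
      for (lineage in active) {
        blen <- c(blen, t); bleaves <- c(bleaves, list(lineage))
      }
      # record accumulated branch below each active lineage by merging later:
      pair <- sample(k, 2)
      merged <- c(active[[pair[1]]], active[[pair[2]]])
      active <- c(active[-pair], list(merged))
      k <- k - 1L
    }
    tbl <- sum(blen)
    nMut <- stats::rpois(1, config$theta / 2 * tbl * L)
    mat <- matrix(0L, n, 0)
    pos <- integer(0)
    if (nMut > 0) {
      branch <- sample(length(blen), nMut, replace = TRUE, prob = blen)
      pos <- sort(sample(0:(L - 1L), min(nMut, L)))
      branch <- branch[seq_along(pos)]
      mat <- matrix(0L, n, length(pos))
      for (j in seq_along(pos)) mat[bleaves[[branch[j]]], j] <- 1L
    }
    counts <- integer(L)
    counts[pos + 1L] <- colSums(mat)
    sites <- regionSites(0:(L - 1L), counts, n)
    hap <- new("HaplotypeMatrix", mat = mat, positions = as.numeric(pos))
    list(haplotypes = hap, sites = sites)
  })
}

#' Construct a RegionSites object
#'
#' @param positions site positions (bp, 0-based).
#' @param counts derived counts 0..n, NA for folded-invariant sites.
#' @param n sample size.
#' @param background optional spectrum over counts 0..n; estimated from the
#'   region when NULL (folded-invariant mass split equally between classes 0
#'   and n).
#' @return a \linkS4class{RegionSites}.
#' @export
regionSites <- function(positions, counts, n, background = NULL) {
  counts <- as.integer(counts)
  if (is.null(background)) {
    tab <- tabulate(counts + 1L, nbins = n + 1L)
    nInv <- sum(is.na(counts))
    tab[1] <- tab[1] + nInv / 2
    tab[n + 1L] <- tab[n + 1L] + nInv / 2
    background <- tab / sum(tab)
  }
  new("RegionSites", positions = as.numeric(positions), counts = counts,
      n = as.integer(n), background = background)
}

#' Simulate a region whose SFS is distorted by a selective sweep
#'
#' Per-site derived counts are drawn from the hitchhiking transform of the
#' background spectrum (\code{\link{sweepSpectrum}}) at each site's distance
#' from the configured sweep position; the true position is recorded in the
#' \code{"truth"} attribute.
#'
#' @param config a \code{\link{simConfig}} with a \code{sweep} component.
#' @param background spectrum over derived counts 0..n.
#' @param rep replicate index for the RNG stream.
#' @return a \linkS4class{RegionSites} with a \code{"truth"} attribute.
#' @export
simSweepRegion <- function(config, background, rep = 1L) {
  if (is.null(config$sweep)) stop("config$sweep must be set")
  n <- config$nHaplotypes
  L <- config$regionLengthBp
  x0 <- config$sweep$sweepPositionBp
  if (x0 < 0 || x0 >= L) stop("sweep position must lie inside the region")
  stopifnot(length(background) == n + 1L)
  if (any(background < 0)) stop("invalid background spectrum: negative mass")
  background <- background / sum(background)
  Q <- .sweepQ(background, n)
  pos <- 0:(L - 1L)
  e <- 1 - exp(-config$sweep$sweepIntensity * abs(pos - x0))
  withSeed(opSeed(config$seed, "simSweepRegion", rep), {
    W <- .binomWeights(e, n)
    P <- W %*% Q
    u <- stats::runif(L)
    cum <- P %*% upper.tri(diag(n + 1L), diag = TRUE)
    counts <- as.integer(rowSums(u > cum))
    out <- regionSites(pos, counts, n, background = background)
    attr(out, "truth") <- list(sweepPositionBp = x0,
                               sweepIntensity = config$sweep$sweepIntensity)
    out
  })
}

#' Simulate a codon alignment with recorded MK truth
#'
#' An ancestral sequence of sense codons receives \code{targetDivergence}
#' mutations on the outgroup lineage only (the ingroup consensus stays
#' ancestral) and \code{targetPolymorphism} segregating mutations in the
#' ingroup, each carried by fewer than half the haplotypes so the consensus
#' equals the ancestral sequence. Stop codons are never introduced. The true
#' counts and SFS are recorded in the \code{"truth"} attribute.
#'
#' @param config a \code{\link{simConfig}}.
#' @param nCodons number of codons.
#' @param targetDivergence number of divergence mutations (at most one per
#'   codon).
#' @param targetPolymorphism number of segregating mutations.
#' @param geneId,speciesId identifiers for the alignment.
#' @return a \linkS4class{CodonAlignment} with a \code{"truth"} attribute.
#' @export
simCodonAlignment <- function(config, nCodons, targetDivergence = 0L,
                              targetPolymorphism = 0L, geneId = "gene",
                              speciesId = "species") {
  stopifnot(nCodons >= 1)
  n <- config$nHaplotypes
  tb <- .codonTables()
  withSeed(opSeed(config$seed, "simCodonAlignment"), {
    anc <- sample(tb$sense, nCodons, replace = TRUE)
    ancSeq <- paste(anc, collapse = "")
    truth <- list(Pn = 0, Ps = 0, Dn = 0, Ds = 0,
                  neutralSfs = numeric(n - 1L), selectedSfs = numeric(n - 1L))
    usedPos <- integer(0)   # nucleotide positions already mutated
    mutate <- function(codon, pos) {
      alts <- setdiff(.BASES, substr(codon, pos, pos))
      to <- vapply(alts, function(b) { x <- codon; substr(x, pos, pos) <- b; x }, "")
      to <- to[tb$aa[to] != "*"]
      if (length(to) == 0L) return(NULL)
      sample(to, 1)
    }
    # divergence on the outgroup lineage, at most one mutation per codon
    og <- anc
    divCodons <- sample(nCodons, min(targetDivergence, nCodons))
    for (ci in divCodons) {
      pos <- sample(3, 1)
      newCodon <- mutate(anc[ci], pos)
      if (is.null(newCodon)) next
      og[ci] <- newCodon
      usedPos <- c(usedPos, 3L * (ci - 1L) + pos)
      if (tb$aa[newCodon] == tb$aa[anc[ci]]) truth$Ds <- truth$Ds + 1
      else truth$Dn <- truth$Dn + 1
    }
    # ingroup polymorphism: derived allele carried by < n/2 haplotypes
    mat <- matrix(rep(strsplit(ancSeq, "")[[1]], n), nrow = n, byrow = TRUE)
    kMax <- max(1L, (n - 1L) %/% 2L)
    kProb <- (1 / seq_len(kMax)); kProb <- kProb / sum(kProb)
    placed <- 0L; tries <- 0L
    while (placed < targetPolymorphism && tries < 50L * targetPolymorphism + 50L) {
      tries <- tries + 1L
      ci <- sample(nCodons, 1); pos <- sample(3, 1)
      ntPos <- 3L * (ci - 1L) + pos
      if (ntPos %in% usedPos) next
      newCodon <- mutate(anc[ci], pos)
      if (is.null(newCodon)) next
      k <- sample.int(kMax, 1, prob = kProb)
      carriers <- sample(n, k)
      mat[carriers, ntPos] <- substr(newCodon, pos, pos)
      usedPos <- c(usedPos, ntPos)
      syn <- tb$aa[newCodon] == tb$aa[anc[ci]]
      if (syn) { truth$Ps <- truth$Ps + 1; truth$neutralSfs[k] <- truth$neutralSfs[k] + 1 }
      else { truth$Pn <- truth$Pn + 1; truth$selectedSfs[k] <- truth$selectedSfs[k] + 1 }
      placed <- placed + 1L
    }
    sites <- vapply(anc, codonSites, c(syn = 0, nonsyn = 0))
    truth$LS <- sum(sites["syn", ]); truth$LN <- sum(sites["nonsyn", ])
    ing <- apply(mat, 1, paste, collapse = "")
    names(ing) <- sprintf("%s|hap%02d", geneId, seq_len(n))
    aln <- codonAlignment(ing, paste(og, collapse = ""), geneId = geneId,
                          speciesId = speciesId)
    attr(aln, "truth") <- truth
    aln
  })
}
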