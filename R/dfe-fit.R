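# Two-stage maximum-likelihood estimation of demography, the deleterious DFE,
# alpha and omega_A from a paired SFS, following the classical approach:
# (1) two-epoch demography from the neutral (synonymous) SFS, (2) gamma DFE
# from the selected (nonsynonymous) SFS conditional on that demography. The
# likelihood is product-multinomial over SFS classes (monomorphic class
# included); each stage is optimized by bounded quasi-Newton from a fixed
# grid of starting points.

# fold class probabilities p[0..n] -> list(mono, poly[1..floor(n/2)])
.foldProbs <- function(p, n, folded) {
  if (!folded) return(list(mono = p[1] + p[n + 1], poly = p[2:n]))
  half <- n %/% 2L
  poly <- numeric(half)
  for (i in seq_len(half)) {
    j <- n - i
    poly[i] <- if (j == i) p[i + 1] else p[i + 1] + p[j + 1]
  }
  list(mono = p[1] + p[n + 1], poly = poly)
}

.foldCounts <- function(x, n, folded) {
  if (!folded) return(x)
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    j <- n - i
    out[i] <- if (j == i) x[i] else x[i] + x[j]
  }
  out
}

# weighted multinomial log likelihood over (mono, poly classes)
.sfsLoglik <- function(polyCounts, monoCount, m, n, folded, theta) {
  p <- .finishSFS(m, n, theta)
  f <- .foldProbs(p, n, folded)
  if (any(f$poly <= 0) || f$mono <= 0) return(-Inf)
  sum(polyCounts * log(f$poly)) + monoCount * log(f$mono)
}

.thetaUpper <- function(m, n) 0.95 / sum(m[2:(n + 1)])

# closed-form ML of the shared per-site mutation scale given the class
# masses m: with p_poly = theta * m_j and folded monomorphic mass
# 1 - theta * sum(m_1..n-1), the maximizer is P / (M' (P + mono)).
.thetaHat <- function(polyTotal, monoCount, m, n) {
  Mp <- sum(m[2:n])
  th <- polyTotal / (Mp * (polyTotal + monoCount))
  min(max(th, 1e-12), .thetaUpper(m, n))
}

# stage 1: demography from the neutral SFS, with the mutation scale theta
# profiled out in closed form. theta is shared with the selected sites
# (equal per-site mutation rate), which is what makes weakly deleterious
# mass identifiable from the relative polymorphism level.
.fitNeutralStage <- function(polyCounts, monoCount, n, folded, nRef,
                             startPar = NULL) {
  P <- sum(polyCounts)
  obj <- function(par) {
    demog <- list(n2OverN1 = exp(par[1]), t2 = exp(par[2]), nRef = nRef)
    m <- .sampleSFS(.wfOccupancy(demog, 0), nRef, n)
    theta <- .thetaHat(P, monoCount, m, n)
    -.sfsLoglik(polyCounts, monoCount, m, n, folded, theta)
  }
  lower <- c(log(0.02), log(1e-3))
  upper <- c(log(50), log(5))
  finish <- function(fit) {
    demog <- list(n2OverN1 = exp(fit$par[1]), t2 = exp(fit$par[2]), nRef = nRef)
    m <- .sampleSFS(.wfOccupancy(demog, 0), nRef, n)
    list(demography = demog, theta = .thetaHat(P, monoCount, m, n),
         logLik = -fit$value, neutralMass = m, par = fit$par)
  }
  if (!is.null(startPar)) {
    # warm restart from a previous fit (used by resampling procedures)
    fit <- stats::optim(startPar[1:2], obj, method = "L-BFGS-B", lower = lower,
                        upper = upper, control = list(factr = 1e5))
    return(finish(fit))
  }
  starts <- expand.grid(lr = log(c(0.3, 1, 3, 10)), lt2 = log(c(0.05, 0.5)))
  fits <- list()
  fails <- character(0)
  for (k in seq_len(nrow(starts))) {
    p0 <- c(starts$lr[k], starts$lt2[k])
    fit <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                                 upper = upper, control = list(factr = 1e4)),
                    error = function(e) NULL)
    if (is.null(fit)) { fails <- c(fails, paste(round(p0, 2), collapse = ",")); next }
    fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L)
    stop("neutral-stage optimizer failed on all starts: ", paste(fails, collapse = "; "))
  vals <- vapply(fits, `[[`, 0, "value")
  best <- finish(fits[[which.min(vals)]])
  # the neutral SFS can leave (r, t2) on a near-flat ridge (e.g. a constant-
  # size truth); keep the near-tied optima so the joint (neutral + selected)
  # likelihood can arbitrate between them
  keep <- which(vals - min(vals) < 4)
  keep <- keep[order(vals[keep])]
  cand <- list(); seen <- character(0)
  for (k in keep) {
    key <- paste(round(fits[[k]]$par, 2), collapse = "|")
    if (key %in% seen || length(cand) >= 4L) next
    seen <- c(seen, key)
    cand[[length(cand) + 1L]] <- finish(fits[[k]])
  }
  best$candidates <- cand
  best
}

# stage 2: gamma DFE from the selected SFS, conditional on the demography and
# the shared mutation scale, with per-S spectra precomputed
.fitGammaStage <- function(polyCounts, monoCount, n, folded, gridS, gridSpectra,
                           theta) {
  absS <- -gridS
  obj <- function(par) {
    w <- .gammaWeights(absS, exp(par[1]), exp(par[2]))
    m <- as.numeric(w %*% gridSpectra)
    -.sfsLoglik(polyCounts, monoCount, m, n, folded,
                min(theta, .thetaUpper(m, n)))
  }
  starts <- expand.grid(lm = log(c(0.5, 5, 50, 500)), lb = log(c(0.2, 1)))
  lower <- c(log(1e-3), log(0.02))
  upper <- c(log(1e5), log(50))
  best <- NULL
  fails <- character(0)
  for (k in seq_len(nrow(starts))) {
    p0 <- c(starts$lm[k], starts$lb[k])
    fit <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                                 upper = upper, control = list(factr = 1e4)),
                    error = function(e) NULL)
    if (is.null(fit)) { fails <- c(fails, paste(round(p0, 2), collapse = ",")); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("gamma-stage optimizer failed on all starts: ", paste(fails, collapse = "; "))
  list(dfe = gammaDFE(exp(best$par[1]), exp(best$par[2])),
       theta = theta, logLik = -best$value)
}

.sfsCounts <- function(data, which, folded) {
  poly <- if (which == "neutral") data@neutralSfs else data@selectedSfs
  mono <- if (which == "neutral") data@invariantNeutral else data@invariantSelected
  list(poly = .foldCounts(poly, data@n, folded), mono = mono)
}

#' Fit demography, gamma DFE, alpha and omega_A to a paired SFS
#'
#' Two-stage maximum likelihood: the two-epoch demography (plus a per-site
#' mutation-scale nuisance, profiled in closed form) is fitted to the neutral
#' SFS, then the gamma DFE to the selected SFS conditional on the demography,
#' reusing the neutral-stage mutation scale (a shared scale keeps weakly
#' deleterious mass identifiable). Near-tied stage-1 demographies are
#' arbitrated by the joint (neutral + selected) likelihood with a parsimony
#' preference for constant size. The product-multinomial likelihood includes
#' the monomorphic class. alpha and omega_A are derived via
#' \code{\link{alphaOmega}}.
#'
#' @param data a \linkS4class{PairedSFS}.
#' @param folded fold the SFS before fitting (default TRUE; robust to
#'   mispolarization).
#' @param nRef Wright-Fisher discretization size (default 100).
#' @param nGridS number of deleterious S quadrature points (default 32).
#' @param demog optional fixed demography (plus \code{theta} attribute) to
#'   skip stage 1 (used by resampling procedures where the demography is a
#'   species-level property shared across gene classes).
#' @return a \linkS4class{DFEFit}.
#' @export
fitDFE <- function(data, folded = TRUE, nRef = 100L, nGridS = 32L, demog = NULL) {
  stopifnot(is(data, "PairedSFS"))
  n <- data@n
  if (sum(data@neutralSfs) < 1) stop("neutral SFS has no polymorphic sites")
  neu <- .sfsCounts(data, "neutral", folded)
  sel <- .sfsCounts(data, "selected", folded)
  if (is.null(demog)) {
    s1 <- .fitNeutralStage(neu$poly, neu$mono, n, folded, as.integer(nRef))
    # Arbitrate near-tied demographies by the joint (neutral + selected)
    # likelihood, with a parsimony tie-break: a constant-size history is
    # always offered as a candidate, and among joint-likelihood ties (within
    # 2 log units) the smallest size change wins. Without this, a neutral-
    # flat (r, t2) ridge lets the gamma DFE rescale arbitrarily.
    cands <- s1$candidates
    const <- .fitNeutralStage(neu$poly, neu$mono, n, folded, as.integer(nRef),
                              startPar = c(0, log(0.01)))
    const$demography$n2OverN1 <- 1
    m1 <- .sampleSFS(.wfOccupancy(const$demography, 0), as.integer(nRef), n)
    const$theta <- .thetaHat(sum(neu$poly), neu$mono, m1, n)
    const$logLik <- .sfsLoglik(neu$poly, neu$mono, m1, n, folded, const$theta)
    const$neutralMass <- m1
    cands <- c(cands, list(const))
    gridS0 <- .defaultSGrid(nGridS)[-1]
    scored <- list()
    for (cd in cands) {
      spectra <- .sfsGrid(cd$demography, n, gridS0)
      g <- tryCatch(.fitGammaStage(sel$poly, sel$mono, n, folded, gridS0,
                                   spectra, theta = cd$theta),
                    error = function(e) NULL)
      if (is.null(g)) next
      cd$joint <- cd$logLik + g$logLik
      scored[[length(scored) + 1L]] <- cd
    }
    if (length(scored) > 0L) {
      joints <- vapply(scored, `[[`, 0, "joint")
      tied <- which(joints > max(joints) - 2)
      devs <- vapply(scored[tied], function(cd) abs(log(cd$demography$n2OverN1)),
                     0)
      s1 <- scored[[tied[which.min(devs)]]]
    }
  } else {
    demog <- .checkDemography(demog)
    m <- .sampleSFS(.wfOccupancy(demog, 0), demog$nRef, n)
    theta <- attr(demog, "theta")
    if (is.null(theta)) theta <- min(sum(neu$poly) / (sum(neu$poly) + neu$mono) /
                                       sum(m[2:(n + 1)]), .thetaUpper(m, n))
    s1 <- list(demography = demog, theta = theta,
               logLik = .sfsLoglik(neu$poly, neu$mono, m, n, folded, theta),
               neutralMass = m)
  }
  gridS <- .defaultSGrid(nGridS)[-1]
  gridSpectra <- .sfsGrid(s1$demography, n, gridS)
  s2 <- .fitGammaStage(sel$poly, sel$mono, n, folded, gridS, gridSpectra,
                       theta = s1$theta)
  fit <- new("DFEFit", demography = s1$demography, dfe = s2$dfe,
             logLik = s1$logLik + s2$logLik, alpha = NA_real_, omegaA = NA_real_,
             seOmegaA = NA_real_, discretized = numeric(0),
             thetaNeutral = s1$theta, thetaSelected = s2$theta,
             gridS = gridS, gridSpectra = gridSpectra,
             n = as.integer(n), folded = folded)
  ao <- alphaOmega(fit, data)
  fit@alpha <- ao$alpha
  fit@omegaA <- ao$omegaA
  fit@discretized <- discretizeDFE(fit)
  fit
}

#' Derive alpha and omega_A from a DFE fit and divergence data
#'
#' The nonadaptive omega is the expectation of the relative fixation rate
#' r(S) = S/(1 - exp(-S)) over the fitted deleterious DFE; the observed
#' omega is (Dn/L_N)/(Ds/L_S). Then alpha = 1 - omega_na/omega_obs and
#' omega_A = omega_obs - omega_na (negative values allowed and reported
#' as-is).
#'
#' @param fit a \linkS4class{DFEFit} (only the DFE slot is used).
#' @param data a \linkS4class{PairedSFS} with divergence counts.
#' @return list with \code{alpha}, \code{omegaA}, \code{omegaNa},
#'   \code{omegaObs} and \code{undefined}.
#' @export
alphaOmega <- function(fit, data) {
  dfe <- if (is(fit, "DFEFit")) fit@dfe else fit
  omegaNa <- .omegaNonadaptive(dfe)
  if (data@Ds <= 0 || data@LN <= 0 || data@LS <= 0)
    return(list(alpha = NA_real_, omegaA = NA_real_, omegaNa = omegaNa,
                omegaObs = NA_real_, undefined = TRUE))
  omegaObs <- (data@Dn / data@LN) / (data@Ds / data@LS)
  list(alpha = 1 - omegaNa / omegaObs, omegaA = omegaObs - omegaNa,
       omegaNa = omegaNa, omegaObs = omegaObs, undefined = FALSE)
}

#' Discretize the fitted deleterious DFE into |Ne s| bins
#'
#' @param fit a \linkS4class{DFEFit} or a DFE list.
#' @param bins bin boundaries on the |Ne s| scale.
#' @return named proportions summing to 1.
#' @export
discretizeDFE <- function(fit, bins = c(0, 1, 10, 100, Inf)) {
  dfe <- if (is(fit, "DFEFit")) fit@dfe else fit
  labs <- paste0("[", head(bins, -1), ",", tail(bins, -1), ")")
  if (identical(dfe$type, "point")) {
    x <- abs(dfe$s)
    out <- as.numeric(x >= head(bins, -1) & x < tail(bins, -1))
  } else {
    cdf <- stats::pgamma(bins, shape = dfe$shape, rate = dfe$shape / dfe$meanNes)
    out <- diff(cdf)
  }
  stats::setNames(out, labs)
}

#' Pool paired SFS across genes of a class and fit
#'
#' Element-wise sum of SFS and divergence across the supplied genes, then
#' \code{\link{fitDFE}}.
#'
#' @param sfsList list of \linkS4class{PairedSFS} (one per gene).
#' @param ... passed to \code{\link{fitDFE}}.
#' @return a \linkS4class{DFEFit}.
#' @export
poolAndEstimate <- function(sfsList, ...) {
  fitDFE(poolSFS(sfsList), ...)
}

#' Element-wise pooling of paired SFS
#'
#' @param sfsList list of \linkS4class{PairedSFS} with equal n.
#' @return a single pooled \linkS4class{PairedSFS}.
#' @export
poolSFS <- function(sfsList) {
  if (length(sfsList) == 0L) stop("cannot pool an empty class")
  n <- unique(vapply(sfsList, function(s) s@n, 1L))
  if (length(n) != 1L) stop("all spectra must share the sample size n")
  add <- function(f) sum(vapply(sfsList, f, 0))
  new("PairedSFS", n = n,
      neutralSfs = Reduce(`+`, lapply(sfsList, function(s) s@neutralSfs)),
      selectedSfs = Reduce(`+`, lapply(sfsList, function(s) s@selectedSfs)),
      invariantNeutral = add(function(s) s@invariantNeutral),
      invariantSelected = add(function(s) s@invariantSelected),
      Dn = add(function(s) s@Dn), Ds = add(function(s) s@Ds),
      LN = add(function(s) s@LN), LS = add(function(s) s@LS))
}

# fast omega_A for a pooled SFS given a fixed demography and cached grid;
# the shared mutation scale is re-estimated in closed form from the class's
# neutral SFS
.omegaAGivenDemog <- function(pooled, folded, gridS, gridSpectra, neutralMass) {
  neu <- .sfsCounts(pooled, "neutral", folded)
  theta <- .thetaHat(sum(neu$poly), neu$mono, neutralMass, pooled@n)
  sel <- .sfsCounts(pooled, "selected", folded)
  s2 <- .fitGammaStage(sel$poly, sel$mono, pooled@n, folded, gridS, gridSpectra,
                       theta = theta)
  ao <- alphaOmega(s2$dfe, pooled)
  list(omegaA = ao$omegaA, alpha = ao$alpha, dfe = s2$dfe, logLik = s2$logLik,
       theta = theta)
}

#' Bootstrap confidence interval for class-level omega_A
#'
#' Resamples units with replacement, re-estimates omega_A, and reports the
#' percentile interval and SE. \code{unit = "gene"} resamples genes;
#' \code{unit = "codon"} resamples sites within the pooled spectra
#' (multinomial over SFS classes, Poisson for divergence counts), which is
#' the per-gene SE variant. The demography is fitted once to the observed
#' pooled data and held fixed across resamples (a species-level property).
#'
#' @param sfsList list of \linkS4class{PairedSFS}.
#' @param nBoot number of bootstrap resamples (warned below 50).
#' @param level confidence level (default 0.95).
#' @param unit resampling unit, \code{"gene"} or \code{"codon"}.
#' @param seed integer seed for the resampling stream.
#' @param refitDemography refit the demography stage on every resample
#'   (default TRUE), warm-started from the point fit; per-S spectra grids
#'   are memoized on a rounded demography lattice to keep this tractable.
#' @param folded,nRef,nGridS as in \code{\link{fitDFE}}.
#' @return list with \code{omegaA}, \code{ci}, \code{se} and the bootstrap
#'   replicates.
#' @export
bootstrapCI <- function(sfsList, nBoot = 200L, level = 0.95,
                        unit = c("gene", "codon"), seed = 1L,
                        refitDemography = TRUE,
                        folded = TRUE, nRef = 100L, nGridS = 32L) {
  unit <- match.arg(unit)
  if (nBoot < 50L) warning("nBoot < 50: bootstrap interval will be unstable")
  if (is(sfsList, "PairedSFS")) sfsList <- list(sfsList)
  pooled <- poolSFS(sfsList)
  fit <- fitDFE(pooled, folded = folded, nRef = nRef, nGridS = nGridS)
  startPar <- c(log(fit@demography$n2OverN1), log(fit@demography$t2),
                log(fit@thetaNeutral))
  gridMemo <- new.env(parent = emptyenv())
  gridFor <- function(demog) {
    # round the demography to a coarse lattice so nearby resampled fits share
    # one spectra grid
    key <- sprintf("%.2f|%.2f", log(demog$n2OverN1) / 0.05,
                   demog$t2 / 0.02)
    hit <- gridMemo[[key]]
    if (is.null(hit)) {
      dR <- list(n2OverN1 = exp(round(log(demog$n2OverN1) / 0.05) * 0.05),
                 t2 = round(demog$t2 / 0.02) * 0.02, nRef = demog$nRef)
      if (dR$t2 <= 0) dR$t2 <- 0.01
      hit <- .sfsGrid(dR, pooled@n, fit@gridS)
      gridMemo[[key]] <- hit
    }
    hit
  }
  pointMass <- .sampleSFS(.wfOccupancy(fit@demography, 0), as.integer(nRef),
                          pooled@n)
  constDemog <- list(n2OverN1 = 1, t2 = 0.01, nRef = as.integer(nRef))
  constMass <- .sampleSFS(.wfOccupancy(constDemog, 0), as.integer(nRef),
                          pooled@n)
  bootOnce <- function(pb) {
    if (!refitDemography)
      return(.omegaAGivenDemog(pb, folded, fit@gridS, fit@gridSpectra,
                               pointMass))
    # mirror the point estimator: warm-started refit plus a constant-size
    # candidate, arbitrated by the joint likelihood with a parsimony
    # tie-break (otherwise resamples drift along the neutral-flat ridge and
    # shift the bootstrap distribution relative to the point estimate)
    neu <- .sfsCounts(pb, "neutral", folded)
    s1 <- .fitNeutralStage(neu$poly, neu$mono, pb@n, folded, as.integer(nRef),
                           startPar = startPar)
    neutLl <- function(nm) {
      th <- .thetaHat(sum(neu$poly), neu$mono, nm, pb@n)
      .sfsLoglik(neu$poly, neu$mono, nm, pb@n, folded, th)
    }
    gWarm <- .omegaAGivenDemog(pb, folded, fit@gridS, gridFor(s1$demography),
                               s1$neutralMass)
    gConst <- .omegaAGivenDemog(pb, folded, fit@gridS, gridFor(constDemog),
                                constMass)
    jointWarm <- s1$logLik + gWarm$logLik
    jointConst <- neutLl(constMass) + gConst$logLik
    if (jointConst > jointWarm - 2 ||
        abs(log(s1$demography$n2OverN1)) < 1e-6) gConst else gWarm
  }
  resampleSites <- function(s) {
    rs <- function(poly, mono) {
      tot <- round(sum(poly) + mono)
      p <- c(poly, mono) / (sum(poly) + mono)
      draw <- as.numeric(stats::rmultinom(1, tot, p))
      list(poly = draw[seq_along(poly)], mono = draw[length(draw)])
    }
    a <- rs(s@neutralSfs, s@invariantNeutral)
    b <- rs(s@selectedSfs, s@invariantSelected)
    new("PairedSFS", n = s@n, neutralSfs = a$poly, selectedSfs = b$poly,
        invariantNeutral = a$mono, invariantSelected = b$mono,
        Dn = stats::rpois(1, s@Dn), Ds = stats::rpois(1, s@Ds),
        LN = s@LN, LS = s@LS)
  }
  reps <- withSeed(opSeed(seed, "bootstrapCI"), {
    t(vapply(seq_len(nBoot), function(b) {
      pb <- if (unit == "gene") {
        idx <- sample(length(sfsList), replace = TRUE)
        poolSFS(sfsList[idx])
      } else resampleSites(pooled)
      if (pb@Ds <= 0 || sum(pb@neutralSfs) < 1)
        return(c(omegaA = NA_real_, meanNes = NA_real_, shape = NA_real_))
      r <- bootOnce(pb)
      c(omegaA = r$omegaA, meanNes = r$dfe$meanNes, shape = r$dfe$shape)
    }, c(omegaA = 0, meanNes = 0, shape = 0)))
  })
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  a <- (1 - level) / 2
  ciOf <- function(x) c(.quantile7(x, a), .quantile7(x, 1 - a))
  list(omegaA = fit@omegaA,
       ci = ciOf(reps[, "omegaA"]),
       ciMeanNes = ciOf(reps[, "meanNes"]), ciShape = ciOf(reps[, "shape"]),
       se = stats::sd(reps[, "omegaA"]), replicates = reps, fit = fit)
}

#' Permutation test for an omega_A difference between two gene classes
#'
#' Class labels are permuted across genes; the statistic is pooled
#' omega_A(a) - omega_A(b). The demography is fitted once to the combined
#' data and shared across permutations (demography is a property of the
#' species, not of the gene class). Two-sided p with the add-one rule.
#'
#' @param genesA,genesB lists of \linkS4class{PairedSFS}.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param folded,nRef,nGridS as in \code{\link{fitDFE}}.
#' @return list with \code{statistic}, \code{p}, and permutation statistics.
#' @export
permutationTest <- function(genesA, genesB, nPerm = 199L, seed = 1L,
                            folded = TRUE, nRef = 100L, nGridS = 32L) {
  if (length(genesA) == 0L || length(genesB) == 0L)
    stop("both classes must be non-empty")
  all <- c(genesA, genesB)
  nA <- length(genesA)
  comb <- fitDFE(poolSFS(all), folded = folded, nRef = nRef, nGridS = nGridS)
  nm <- .sampleSFS(.wfOccupancy(comb@demography, 0), as.integer(nRef), comb@n)
  statOf <- function(idxA) {
    a <- .omegaAGivenDemog(poolSFS(all[idxA]), folded, comb@gridS,
                           comb@gridSpectra, nm)
    b <- .omegaAGivenDemog(poolSFS(all[-idxA]), folded, comb@gridS,
                           comb@gridSpectra, nm)
    a$omegaA - b$omegaA
  }
  obs <- statOf(seq_len(nA))
  perms <- withSeed(opSeed(seed, "permutationTest"), {
    vapply(seq_len(nPerm), function(k) statOf(sample(length(all), nA)), 0)
  })
  p <- (1 + sum(abs(perms) >= abs(obs))) / (nPerm + 1)
  list(statistic = obs, p = p, permStats = perms)
}

#' Likelihood-ratio test: shared vs separate DFE between two classes
#'
#' The demography is fitted to the combined neutral SFS and shared. Under the
#' separate model each class has its own gamma DFE; under the shared model a
#' single gamma is fitted jointly (each class keeps its own mutation-scale
#' nuisance in both models, so it cancels from the comparison). LR =
#' 2 (ll_a + ll_b - ll_shared), df = 2 (gamma mean and shape duplicated),
#' chi-square p.
#'
#' @param genesA,genesB lists of \linkS4class{PairedSFS}.
#' @param folded,nRef,nGridS as in \code{\link{fitDFE}}.
#' @return list with \code{LR}, \code{df}, \code{p}, and the three fits.
#' @export
lrtSharedVsSeparate <- function(genesA, genesB, folded = TRUE, nRef = 100L,
                                nGridS = 32L) {
  poolA <- poolSFS(genesA); poolB <- poolSFS(genesB)
  comb <- fitDFE(poolSFS(c(genesA, genesB)), folded = folded, nRef = nRef,
                 nGridS = nGridS)
  gridS <- comb@gridS; spectra <- comb@gridSpectra
  nm <- .sampleSFS(.wfOccupancy(comb@demography, 0), as.integer(nRef), comb@n)
  thetaOf <- function(pool) {
    neu <- .sfsCounts(pool, "neutral", folded)
    .thetaHat(sum(neu$poly), neu$mono, nm, pool@n)
  }
  thA <- thetaOf(poolA); thB <- thetaOf(poolB)
  neuA <- .sfsCounts(poolA, "neutral", folded)
  neuB <- .sfsCounts(poolB, "neutral", folded)
  selA <- .sfsCounts(poolA, "selected", folded)
  selB <- .sfsCounts(poolB, "selected", folded)
  fitA <- .fitGammaStage(selA$poly, selA$mono, poolA@n, folded, gridS, spectra,
                         theta = thA)
  fitB <- .fitGammaStage(selB$poly, selB$mono, poolB@n, folded, gridS, spectra,
                         theta = thB)
  absS <- -gridS
  # shared gamma; each class keeps its own (closed-form) mutation scale
  obj <- function(par) {
    w <- .gammaWeights(absS, exp(par[1]), exp(par[2]))
    m <- as.numeric(w %*% spectra)
    -(.sfsLoglik(selA$poly, selA$mono, m, poolA@n, folded,
                 min(thA, .thetaUpper(m, poolA@n))) +
      .sfsLoglik(selB$poly, selB$mono, m, poolB@n, folded,
                 min(thB, .thetaUpper(m, poolB@n))))
  }
  p0 <- c(log(mean(c(fitA$dfe$meanNes, fitB$dfe$meanNes))),
          log(mean(c(fitA$dfe$shape, fitB$dfe$shape))))
  shared <- stats::optim(p0, obj, method = "L-BFGS-B",
                         lower = c(log(1e-3), log(0.02)),
                         upper = c(log(1e5), log(50)),
                         control = list(factr = 1e4))
  LR <- max(0, 2 * (fitA$logLik + fitB$logLik - (-shared$value)))
  df <- 2L
  list(LR = LR, df = df, p = stats::pchisq(LR, df, lower.tail = FALSE),
       fitA = fitA, fitB = fitB, sharedLogLik = -shared$value)
}
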