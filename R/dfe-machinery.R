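# Wright-Fisher transition-matrix machinery for expected site frequency
# spectra under a two-epoch demography with genic selection.
#
# The population is discretized to nRef gene copies. Selection uses the
# exponential fitness map x' = x e^s / (x e^s + 1 - x) with s = S / (2 nRef),
# so the scaled coefficient S matches the diffusion convention in which the
# relative fixation rate is r(S) = S / (1 - exp(-S)). The ancestral epoch is
# at mutation-drift-selection equilibrium; at the size change the chain is
# evolved for t2 * nRef rescaled generations (one grid generation of size
# nRef reproduces the drift of N2/nRef actual generations of size N2, so
# t2 is time in units of the current population size). Mutational influx is
# proportional to population size per generation, hence to (N2/N1)^2 per
# rescaled generation.
#
# S is scaled by the ANCESTRAL population size: the ancestral-epoch matrix
# uses S and the post-change epoch uses S * (N2/N1). This keeps the DFE
# identifiable when the neutral SFS leaves (N2/N1, t2) on a flat ridge (a
# constant-size history fits equally with any size ratio at t2 -> 0, and
# current-size scaling would let the gamma rescale along that ridge), and it
# matches the fixation-rate integral: interspecies divergence accumulates
# over the long ancestral epoch, so omega_na = E[r(S)] on the same scale.

# transition matrix among segregating states 1..N-1 (columns: destination
# can also be 0 or N, which are dropped -> mass absorbs)
.wfSegMatrix <- function(N, S) {
  s <- S / (2 * N)
  x <- (1:(N - 1)) / N
  w <- exp(s)
  xsel <- x * w / (x * w + 1 - x)
  # rows = from, cols = to (1..N-1)
  t(vapply(xsel, function(p) stats::dbinom(1:(N - 1), N, p), numeric(N - 1)))
}

# Eigendecompositions of the (transposed) segregating-state transition
# matrices are cached per (N, S): the equilibrium occupancy and the
# G-generation evolution are then closed forms in the eigenvalues, which
# makes repeated likelihood evaluations cheap.
.wfCacheEnv <- new.env(parent = emptyenv())

.wfEig <- function(N, S) {
  key <- sprintf("%d|%.12g", N, S)
  hit <- .wfCacheEnv[[key]]
  if (!is.null(hit)) return(if (isFALSE(hit)) NULL else hit)
  if (length(ls(.wfCacheEnv)) > 600L) rm(list = ls(.wfCacheEnv), envir = .wfCacheEnv)
  tM <- t(.wfSegMatrix(N, S))
  e1 <- numeric(N - 1L); e1[1] <- 1
  out <- tryCatch({
    e <- eigen(tM)
    vinv <- solve(e$vectors)
    if (max(abs(Re(e$vectors %*% (vinv %*% e1)) - e1)) > 1e-8) stop("defective")
    list(values = e$values, vectors = e$vectors, vinvE1 = as.vector(vinv %*% e1),
         vinv = vinv, tM = tM)
  }, error = function(err) FALSE)
  .wfCacheEnv[[key]] <- if (is.logical(out)) FALSE else out
  if (isFALSE(out)) NULL else out
}

.wfTm <- function(N, S) {
  key <- sprintf("M%d|%.12g", N, S)
  hit <- .wfCacheEnv[[key]]
  if (is.null(hit)) {
    hit <- t(.wfSegMatrix(N, S))
    .wfCacheEnv[[key]] <- hit
  }
  hit
}

# full two-epoch occupancy for one selection coefficient. Uses the cached
# eigendecomposition where the matrix is cleanly diagonalizable (neutral and
# weak selection, the optimizer's hot path) and direct solves/iteration for
# near-defective strong-selection matrices.
.wfOccupancy <- function(demog, S) {
  N <- demog$nRef
  r <- demog$n2OverN1
  e1 <- numeric(N - 1L); e1[1] <- 1
  eig1 <- .wfEig(N, S)
  Feq <- if (!is.null(eig1)) {
    Re(eig1$vectors %*% (eig1$vinvE1 / (1 - eig1$values)))
  } else {
    solve(diag(N - 1L) - .wfTm(N, S), e1)
  }
  Feq <- pmax(as.numeric(Feq), 0)
  # linear interpolation between adjacent integer generation counts keeps the
  # likelihood continuous in t2 (a requirement for quasi-Newton optimization)
  Gx <- max(0, demog$t2 * N)
  G0 <- floor(Gx)
  frac <- Gx - G0
  if (Gx == 0) return(Feq)
  eig2 <- .wfEig(N, S * r)
  stepTo <- function(G) {
    if (G == 0) return(Feq)
    if (!is.null(eig2)) {
      lam <- eig2$values
      lamG <- lam^G
      a <- eig2$vinv %*% Feq
      Re(eig2$vectors %*% (lamG * a + r^2 * ((1 - lamG) / (1 - lam)) * eig2$vinvE1))
    } else {
      tM2 <- .wfTm(N, S * r)
      influx <- r^2 * e1
      Fv <- Feq
      for (g in seq_len(G)) Fv <- as.numeric(tM2 %*% Fv) + influx
      Fv
    }
  }
  F0 <- stepTo(G0)
  Fv <- if (frac == 0) F0 else (1 - frac) * F0 + frac * stepTo(G0 + 1L)
  pmax(as.numeric(Fv), 0)
}

# hypergeometric downsampling of a population occupancy to sample size n;
# returns expected relative class masses for sample classes 0..n
.hyperMat <- function(N, n) {
  key <- sprintf("H%d|%d", N, n)
  hit <- .wfCacheEnv[[key]]
  if (!is.null(hit)) return(hit)
  H <- t(vapply(seq_len(N - 1L), function(i) stats::dhyper(0:n, i, N - i, n),
                numeric(n + 1L)))
  .wfCacheEnv[[key]] <- H
  H
}

.sampleSFS <- function(Fv, N, n) {
  if (n > N) stop("sample size n exceeds the discretization nRef")
  as.numeric(Fv %*% .hyperMat(N, n))
}

.checkDemography <- function(demog) {
  stopifnot(is.list(demog))
  for (f in c("n2OverN1", "t2", "nRef"))
    if (is.null(demog[[f]]) || demog[[f]] <= 0)
      stop("demography must have positive ", f)
  demog$nRef <- as.integer(demog$nRef)
  demog
}

#' Two-epoch demography description
#'
#' @param n2OverN1 population size ratio after the step change.
#' @param t2 time since the change, in generations scaled by the current
#'   population size.
#' @param nRef discretization size (gene copies) for the Wright-Fisher
#'   transition matrix; must be at least the sample size.
#' @return a demography list.
#' @export
demography <- function(n2OverN1 = 1, t2 = 0.1, nRef = 100L) {
  .checkDemography(list(n2OverN1 = n2OverN1, t2 = t2, nRef = as.integer(nRef)))
}

#' Gamma distribution of deleterious fitness effects
#'
#' @param meanNes mean of -S where S = 4 Ne s, with Ne the ancestral-epoch
#'   effective size (positive, deleterious scale).
#' @param shape gamma shape parameter.
#' @return a DFE list of type "gamma".
#' @export
gammaDFE <- function(meanNes, shape) {
  .assertScalarNum(meanNes, "meanNes", lower = 1e-12)
  .assertScalarNum(shape, "shape", lower = 1e-12)
  list(type = "gamma", meanNes = meanNes, shape = shape)
}

#' Point-mass distribution of fitness effects
#'
#' @param s the scaled selection coefficient S = 4 Ne s (<= 0 for
#'   deleterious, 0 for neutral).
#' @return a DFE list of type "point".
#' @export
pointDFE <- function(s) {
  .assertScalarNum(s, "s", upper = 0)
  list(type = "point", s = s)
}

#' Expected neutral sample SFS under a two-epoch demography
#'
#' Wright-Fisher transition-matrix forward iteration with mutational influx,
#' evolved past the size step, then hypergeometric downsampling to sample
#' size n. With \code{theta} supplied, per-site class probabilities over
#' derived counts 0..n are returned (non-segregating mass is assigned to
#' class 0); otherwise the relative occupancy-sampled masses.
#'
#' @param demog a \code{\link{demography}} list.
#' @param n haplotype sample size (>= 2).
#' @param theta optional per-site mutation scale; when supplied the result
#'   is a probability vector summing to 1.
#' @return numeric vector of length n + 1 (classes 0..n).
#' @export
expectedNeutralSFS <- function(demog, n, theta = NULL) {
  demog <- .checkDemography(demog)
  stopifnot(n >= 2)
  if (demog$nRef < n) stop("nRef must be at least the sample size n")
  m <- .sampleSFS(.wfOccupancy(demog, 0), demog$nRef, n)
  .finishSFS(m, n, theta)
}

.finishSFS <- function(m, n, theta) {
  if (is.null(theta)) return(m)
  .assertScalarNum(theta, "theta", lower = 0)
  p <- theta * m
  tot <- sum(p[2:(n + 1)])
  if (tot >= 1) stop("theta too large: polymorphic mass exceeds 1")
  p[1] <- p[1] + (1 - tot - p[1])  # residual monomorphic-ancestral mass
  p
}

# expected sample SFS grid over fixed selection coefficients; rows = S values,
# cols = classes 0..n. This is the expensive piece; it is computed once per
# demography and reused across gamma-DFE likelihood evaluations.
.sfsGrid <- function(demog, n, gridS) {
  demog <- .checkDemography(demog)
  t(vapply(gridS, function(S) .sampleSFS(.wfOccupancy(demog, S), demog$nRef, n),
           numeric(n + 1L)))
}

# default log-spaced grid of deleterious S values (negative), plus S = 0
.defaultSGrid <- function(nGrid = 32L, sMin = 1e-4, sMax = 1e5) {
  -c(0, exp(seq(log(sMin), log(sMax), length.out = nGrid)))
}

# gamma quadrature weights on a log-spaced |S| grid: probability mass between
# geometric midpoints, tails assigned to the end points
.gammaWeights <- function(absS, meanNes, shape) {
  rate <- shape / meanNes
  k <- length(absS)
  mid <- sqrt(absS[-k] * absS[-1])
  bounds <- c(0, mid, Inf)
  diff(stats::pgamma(bounds, shape = shape, rate = rate))
}

#' Expected selected sample SFS under a gamma (or point-mass) DFE
#'
#' Fixed-S expected spectra from the same Wright-Fisher machinery, integrated
#' over the DFE by quadrature on a log-spaced S grid. Convergence is checked
#' by doubling the grid; non-convergence is an error with diagnostics.
#'
#' @inheritParams expectedNeutralSFS
#' @param dfe a \code{\link{gammaDFE}} or \code{\link{pointDFE}}.
#' @param nGrid quadrature grid size (gamma DFE only).
#' @param tol relative tolerance for the grid-doubling check.
#' @param check verify quadrature convergence (default TRUE).
#' @return numeric vector of length n + 1 (classes 0..n).
#' @export
expectedSelectedSFS <- function(demog, dfe, n, theta = NULL, nGrid = 32L,
                                tol = 5e-3, check = FALSE) {
  demog <- .checkDemography(demog)
  if (demog$nRef < n) stop("nRef must be at least the sample size n")
  if (identical(dfe$type, "point")) {
    m <- .sampleSFS(.wfOccupancy(demog, dfe$s), demog$nRef, n)
    return(.finishSFS(m, n, theta))
  }
  stopifnot(identical(dfe$type, "gamma"))
  mix <- function(ng) {
    gridS <- .defaultSGrid(ng)[-1]   # deleterious points only
    spectra <- .sfsGrid(demog, n, gridS)
    w <- .gammaWeights(-gridS, dfe$meanNes, dfe$shape)
    as.numeric(w %*% spectra)
  }
  m <- mix(nGrid)
  if (check) {
    m2 <- mix(2L * nGrid)
    rel <- max(abs(m - m2) / (abs(m2) + 1e-12))
    if (rel > tol)
      stop(sprintf("quadrature did not converge: relative change %.3g > %.3g when grid doubled from %d to %d points",
                   rel, tol, nGrid, 2L * nGrid))
    m <- m2
  }
  .finishSFS(m, n, theta)
}

#' Relative fixation rate under genic selection
#'
#' r(S) = S / (1 - exp(-S)), continuous at 0 with r(0) = 1.
#'
#' @param S scaled selection coefficient(s).
#' @return numeric vector of relative fixation rates.
#' @export
fixationRate <- function(S) {
  out <- ifelse(abs(S) < 1e-8, 1 + S / 2, S / (1 - exp(-S)))
  as.numeric(out)
}

# nonadaptive omega: E[r(S)] over the deleterious DFE. Adaptive quadrature
# with a quantile-grid fallback for spiked gammas where the adaptive rule's
# extrapolation breaks down.
.omegaNonadaptive <- function(dfe) {
  if (identical(dfe$type, "point")) return(fixationRate(dfe$s))
  rate <- dfe$shape / dfe$meanNes
  f <- function(x) stats::dgamma(x, shape = dfe$shape, rate = rate) * fixationRate(-x)
  val <- tryCatch(stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value,
                  error = function(e) NA_real_)
  if (is.na(val)) {
    K <- 4096L
    xs <- stats::qgamma((seq_len(K) - 0.5) / K, shape = dfe$shape, rate = rate)
    val <- mean(fixationRate(-xs))
  }
  val
}
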