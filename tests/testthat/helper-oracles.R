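# Independent oracles used across tests. These deliberately re-derive
# quantities by enumeration or direct simulation, separate from the package's
# implementation paths.

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisherByEnumeration <- function(Pn, Ps, Dn, Ds) {
  m <- Pn + Ps        # row 1 total (polymorphism)
  n2 <- Dn + Ds       # row 2 total (divergence)
  k <- Pn + Dn        # column total (nonsynonymous)
  x <- 0:k
  probs <- dhyper(x, m, n2, k)
  pObs <- dhyper(Pn, m, n2, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact upper-tail binomial p by summation
binomUpperByEnumeration <- function(k, n, p0) {
  if (n == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0))
}

# direct Monte-Carlo simulation of the hitchhiking process
sweepSpectrumMC <- function(background, escapeP, n, nDraws, seed = 1) {
  set.seed(seed)
  counts <- integer(nDraws)
  for (d in seq_len(nDraws)) {
    k <- rbinom(1, n, escapeP)
    if (k == n) {
      c0 <- sample(0:n, 1, prob = background)
      counts[d] <- c0
      next
    }
    c0 <- sample(0:n, 1, prob = background)
    # sample k+1 lineage states without replacement from c0 derived among n
    states <- sample(c(rep(1L, c0), rep(0L, n - c0)), k + 1L)
    merged <- states[1]
    counts[d] <- sum(states[-1]) + merged * (n - k)
  }
  tabulate(counts + 1L, nbins = n + 1L) / nDraws
}

# brute-force nSL: O(n^2 m^2) pairwise run expansion
nslBruteForce <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  runLen <- function(a, b, i) {
    if (mat[a, i] != mat[b, i]) return(0L)
    l <- i; r <- i
    while (l > 1L && mat[a, l - 1L] == mat[b, l - 1L]) l <- l - 1L
    while (r < m && mat[a, r + 1L] == mat[b, r + 1L]) r <- r + 1L
    r - l + 1L
  }
  raw <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    der <- which(mat[, i] == 1); anc <- which(mat[, i] == 0)
    if (length(der) < 2L || length(anc) < 2L) next
    pairMean <- function(set) {
      tot <- 0; cnt <- 0
      for (a in seq_along(set)) for (b in seq_along(set)) if (a < b) {
        tot <- tot + runLen(set[a], set[b], i); cnt <- cnt + 1
      }
      tot / cnt
    }
    raw[i] <- log(pairMean(anc) / pairMean(der))
  }
  raw
}

# convenience: quick paired-SFS fixture
makeSFS <- function(n, neu, sel, invNeu = 1000, invSel = 3000,
                    Dn = 100, Ds = 100, LN = 1e4, LS = 4e3) {
  new("PairedSFS", n = as.integer(n), neutralSfs = neu, selectedSfs = sel,
      invariantNeutral = invNeu, invariantSelected = invSel,
      Dn = Dn, Ds = Ds, LN = LN, LS = LS)
}

# vectorized Monte-Carlo hitchhiking oracle (for large draw counts)
sweepSpectrumMCVec <- function(background, escapeP, n, nDraws, seed = 1) {
  set.seed(seed)
  k <- rbinom(nDraws, n, escapeP)
  c0 <- sample(0:n, nDraws, replace = TRUE, prob = background)
  out <- integer(nDraws)
  full <- k == n
  out[full] <- c0[full]
  idx <- which(!full)
  j <- rhyper(length(idx), m = c0[idx], n = n - c0[idx], k = k[idx] + 1L)
  merged <- runif(length(idx)) < j / (k[idx] + 1L)
  out[idx] <- (j - merged) + merged * (n - k[idx])
  tabulate(out + 1L, nbins = n + 1L) / nDraws
}
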