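# Composite-likelihood sweep scan: a generative hitchhiking transform of the
# background spectrum gives the per-site class probabilities under a sweep
# centered at a grid point; the CLR compares the maximized sweep model with
# the background model, with significance thresholds from neutral replicate
# regions.

# Q matrix of the hitchhiking transform: row k+1 = distribution of the final
# derived count given exactly k of the n lineages escaped the sweep. The k
# escapees plus one merged lineage draw their derived states by
# hypergeometric downsampling of the background spectrum to k+1 lineages;
# the merged lineage's state is replicated to its n-k descendants.
.sweepQ <- function(background, n) {
  Q <- matrix(0, n + 1L, n + 1L)
  Q[n + 1L, ] <- background
  cls <- 0:n
  for (k in 0:(n - 1L)) {
    m <- k + 1L
    # downsampled spectrum over j derived among m lineages
    q <- vapply(0:m, function(j)
      sum(background * stats::dhyper(j, cls, n - cls, m)), 0)
    for (j in 0:m) {
      pMerged <- j / m
      if (pMerged > 0) {
        cnt <- (j - 1L) + (n - k)
        Q[k + 1L, cnt + 1L] <- Q[k + 1L, cnt + 1L] + q[j + 1L] * pMerged
      }
      if (pMerged < 1) Q[k + 1L, j + 1L] <- Q[k + 1L, j + 1L] + q[j + 1L] * (1 - pMerged)
    }
  }
  Q
}

.binomWeights <- function(e, n) {
  vapply(0:n, function(k) stats::dbinom(k, n, e), numeric(length(e)))
}

#' Hitchhiking transform of a background spectrum
#'
#' Each of n lineages escapes the sweep independently with probability
#' \code{escapeP}; all non-escapers descend from a single lineage. The
#' escaped lineages plus the merged lineage draw derived states by
#' hypergeometric downsampling of the background spectrum, and the merged
#' lineage's state is replicated to its descendants. Computed exactly by
#' enumeration.
#'
#' @param background probabilities over derived counts 0..n.
#' @param escapeP escape probability in [0, 1].
#' @return probabilities over derived counts 0..n (sums to 1).
#' @export
sweepSpectrum <- function(background, escapeP) {
  if (any(background < 0)) stop("invalid background spectrum: negative mass")
  .assertScalarNum(escapeP, "escapeP", lower = 0, upper = 1)
  background <- background / sum(background)
  n <- length(background) - 1L
  as.numeric(stats::dbinom(0:n, n, escapeP) %*% .sweepQ(background, n))
}

# per-site likelihood columns: row s = Q[, class_s] as a function of k;
# folded-invariant sites sum classes 0 and n
.classColumns <- function(Q, counts, n) {
  tQ <- t(Q)  # rows = class, cols = k
  M <- matrix(0, length(counts), n + 1L)
  folded <- is.na(counts)
  if (any(!folded)) M[!folded, ] <- tQ[counts[!folded] + 1L, , drop = FALSE]
  if (any(folded)) M[folded, ] <- rep(tQ[1L, ] + tQ[n + 1L, ], each = sum(folded))
  M
}

#' Composite-likelihood-ratio scan for selective sweeps
#'
#' At each grid point, each site's escape probability is
#' 1 - exp(-alpha_s * d) with d the distance in bp; the per-site likelihood
#' is the hitchhiking-transform probability of the observed class (folded
#' classes sum their members). CLR = 2 (max over alpha_s of the summed log
#' likelihood - summed log likelihood under the background). The intensity
#' grid always includes the neutral limit, so CLR >= 0 everywhere.
#'
#' @param region a \linkS4class{RegionSites}.
#' @param gridSpacingBp spacing of scan grid points (default: region
#'   length / 1000).
#' @param alphaGrid log-spaced grid of sweep intensities; Inf (neutrality)
#'   is appended automatically.
#' @return a \linkS4class{CLRScan}.
#' @export
clrScan <- function(region, gridSpacingBp = NULL,
                    alphaGrid = 10^seq(-5, -1, length.out = 13)) {
  stopifnot(is(region, "RegionSites"))
  pos <- region@positions
  if (length(pos) == 0L) stop("empty region")
  n <- region@n
  span <- max(pos) - min(pos)
  if (is.null(gridSpacingBp)) gridSpacingBp <- max(1, span / 1000)
  grid <- seq(min(pos), max(pos), by = gridSpacingBp)
  alphaGrid <- sort(unique(c(alphaGrid, Inf)))
  Q <- .sweepQ(region@background, n)
  M <- .classColumns(Q, region@counts, n)
  bgCol <- ifelse(is.na(region@counts),
                  region@background[1] + region@background[n + 1L],
                  region@background[region@counts + 1L])
  bgScore <- sum(log(pmax(bgCol, 1e-300)))
  clr <- numeric(length(grid)); aHat <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    d <- abs(pos - grid[gi])
    best <- -Inf; bestA <- Inf
    for (a in alphaGrid) {
      e <- if (is.finite(a)) 1 - exp(-a * d) else rep(1, length(d))
      W <- .binomWeights(e, n)
      sc <- sum(log(pmax(rowSums(W * M), 1e-300)))
      if (sc > best) { best <- sc; bestA <- a }
    }
    clr[gi] <- 2 * (best - bgScore)
    aHat[gi] <- bestA
  }
  new("CLRScan", positions = grid, clr = pmax(clr, 0), alphaHat = aHat,
      threshold = NA_real_, intervals = data.frame(start = numeric(0),
                                                   end = numeric(0)))
}

#' Significance threshold for the CLR scan from neutral replicates
#'
#' The type-7 95th percentile (by default) of maximum CLR values over neutral
#' replicate regions matched for length, sample size and site density.
#'
#' @param neutralMaxClrs numeric vector of per-replicate maximum CLR values.
#' @param level quantile level (default 0.95).
#' @return the threshold.
#' @export
sweepThreshold <- function(neutralMaxClrs, level = 0.95) {
  if (length(neutralMaxClrs) < 100L)
    warning("fewer than 100 neutral replicates: threshold will be noisy")
  .quantile7(neutralMaxClrs, level)
}

#' Merge significant CLR peaks into sweep-positive intervals
#'
#' Grid points above the threshold are grouped into runs of consecutive
#' points; runs separated by at most \code{mergeGapBp} are merged into a
#' single broad peak, splitting the contig into sweep-positive and
#' sweep-negative areas.
#'
#' @param scan a \linkS4class{CLRScan}.
#' @param threshold CLR significance threshold.
#' @param mergeGapBp peaks closer than this are merged (default 1000).
#' @return the scan with its \code{threshold} and \code{intervals}
#'   (0-based half-open) filled in.
#' @export
callSweepRegions <- function(scan, threshold, mergeGapBp = 1000) {
  stopifnot(is(scan, "CLRScan"))
  sig <- which(scan@clr > threshold)
  ivs <- data.frame(start = numeric(0), end = numeric(0))
  if (length(sig) > 0L) {
    pos <- scan@positions[sig]
    runStart <- pos[1]; prev <- pos[1]
    starts <- numeric(0); ends <- numeric(0)
    for (p in pos[-1]) {
      if (p - prev > mergeGapBp) {
        starts <- c(starts, runStart); ends <- c(ends, prev)
        runStart <- p
      }
      prev <- p
    }
    starts <- c(starts, runStart); ends <- c(ends, prev)
    ivs <- data.frame(start = starts, end = ends + 1)
  }
  methods::initialize(scan, threshold = threshold, intervals = ivs)
}

#' Length-weighted binomial enrichment of sweep-positive genes
#'
#' A gene is sweep-positive when it lies within \code{proximityBp} of a
#' sweep-positive interval. With k sweep-positive RNAi genes among nTotal
#' sweep-positive genes, and p0 the RNAi share of the summed gene length,
#' the one-sided exact binomial upper-tail p-value tests whether RNAi genes
#' carry more sweeps than expected given their length.
#'
#' @param intervals data.frame with \code{start}/\code{end} (0-based
#'   half-open), or a \linkS4class{CLRScan} with intervals called.
#' @param genes a \link[GenomicRanges]{GRanges} with an \code{is_rnai}
#'   metadata column.
#' @param proximityBp proximity in bp (default 1000).
#' @return list with \code{kRnai}, \code{nTotal}, \code{p0} and
#'   \code{binomialP}.
#' @export
sweepEnrichment <- function(intervals, genes, proximityBp = 1000) {
  if (is(intervals, "CLRScan")) intervals <- intervals@intervals
  stopifnot(is(genes, "GRanges"))
  isRnai <- S4Vectors::mcols(genes)$is_rnai
  if (is.null(isRnai)) stop("genes must carry an 'is_rnai' metadata column")
  lens <- GenomicRanges::width(genes)
  if (sum(lens) == 0) stop("zero total gene length")
  p0 <- sum(lens[isRnai]) / sum(lens)
  positive <- rep(FALSE, length(genes))
  if (nrow(intervals) > 0L) {
    sw <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(genes))[1],
      ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
    dd <- GenomicRanges::distanceToNearest(genes, sw)
    positive[S4Vectors::queryHits(dd)] <-
      S4Vectors::mcols(dd)$distance <= proximityBp
  }
  k <- sum(positive & isRnai); nTot <- sum(positive)
  p <- if (nTot == 0L) 1 else stats::pbinom(k - 1, nTot, p0, lower.tail = FALSE)
  list(kRnai = k, nTotal = nTot, p0 = p0, binomialP = p)
}

#' Mixed model of threshold-normalized per-gene maximum CLR
#'
#' The per-gene maximum CLR is normalized by the expected significance
#' threshold of its region (CLR~ = maxCLR / threshold) and modeled with a
#' pathway fixed effect and a species random effect; posterior effects with
#' MCMCp and the species share of variance are reported. With a single
#' species the random effect is dropped with a warning.
#'
#' @param maxClr per-gene maximum CLR values.
#' @param thresholds per-gene (or per-region) significance thresholds.
#' @param classes per-gene pathway labels; the reference level is
#'   \code{"control"} when present, otherwise the first level.
#' @param species per-gene species labels.
#' @param mcmc list of MCMC settings (nChains, nAdapt, nBurn, nIter, seed).
#' @return list with \code{effects} (data.frame of estimate, CI, MCMCp per
#'   class), \code{speciesShare} and the posterior \code{draws}.
#' @export
normalizedClrModel <- function(maxClr, thresholds, classes, species,
                               mcmc = list()) {
  y <- maxClr / thresholds
  stopifnot(length(y) == length(classes), length(y) == length(species))
  cls <- factor(classes)
  if ("control" %in% levels(cls)) cls <- stats::relevel(cls, "control")
  sp <- factor(species)
  useRE <- nlevels(sp) > 1L
  if (!useRE) warning("single species: species random effect dropped")
  mc <- .mcmcDefaults(mcmc, nAdapt = 500L, nBurn = 500L, nIter = 2000L)
  model <- paste0(
    "model{\n",
    " for(i in 1:N){ y[i] ~ dnorm(b0 + bClass[cls[i]]",
    if (useRE) " + u[sp[i]]" else "", ", tauE) }\n",
    " b0 ~ dnorm(0, 0.0001)\n bClass[1] <- 0\n",
    " for(c in 2:C){ bClass[c] ~ dnorm(0, 0.0001) }\n",
    if (useRE) " for(s in 1:S){ u[s] ~ dnorm(0, tauU) }\n sdU ~ dt(0, 1, 1) T(0,)\n tauU <- pow(sdU, -2)\n" else "",
    " sdE ~ dt(0, 1, 1) T(0,)\n tauE <- pow(sdE, -2)\n}")
  dat <- list(y = y, N = length(y), cls = as.integer(cls), C = nlevels(cls))
  if (useRE) { dat$sp <- as.integer(sp); dat$S <- nlevels(sp) }
  monitors <- c("b0", if (nlevels(cls) > 1L) "bClass", "sdE", if (useRE) "sdU")
  draws <- .runJags(model, dat, monitors, mc)
  eff <- lapply(seq_len(nlevels(cls))[-1], function(c) {
    dcol <- draws[, sprintf("bClass[%d]", c)]
    data.frame(class = levels(cls)[c], estimate = mean(dcol),
               ciLow = .quantile7(dcol, 0.025), ciHigh = .quantile7(dcol, 0.975),
               mcmcp = mcmcP(dcol))
  })
  share <- if (useRE) {
    vU <- draws[, "sdU"]^2; vE <- draws[, "sdE"]^2
    mean(vU / (vU + vE))
  } else NA_real_
  list(effects = do.call(rbind, eff), speciesShare = share, draws = draws)
}
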