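#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats dbinom dhyper dpois rpois rbinom rmultinom runif rnorm rexp
#'   rgamma pgamma dgamma qgamma optim fisher.test dhyper phyper pbinom
#'   integrate sd var quantile rnbinom aggregate anova lm as.formula
#'   complete.cases setNames pchisq
#' @importFrom utils read.delim write.table head tail
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Codon alignment of an ingroup sample plus one outgroup
#'
#' The product of upstream amino-acid-guided alignment: equal-length,
#' in-frame nucleotide sequences for an ingroup population sample and a
#' single outgroup, with a per-codon mask. Masked codons are excluded
#' from every downstream count.
#'
#' @slot geneId,speciesId character identifiers.
#' @slot ingroup a \link[Biostrings]{DNAStringSet} of ingroup haplotypes.
#' @slot outgroup a single-sequence \link[Biostrings]{DNAStringSet}.
#' @slot mask logical, one entry per codon; \code{TRUE} = masked.
#' @export
setClass("CodonAlignment",
  representation(geneId = "character", speciesId = "character",
                 ingroup = "DNAStringSet", outgroup = "DNAStringSet",
                 mask = "logical"),
  validity = function(object) {
    w <- Biostrings::width(object@ingroup)
    wo <- Biostrings::width(object@outgroup)
    if (length(object@ingroup) < 1L) return("at least one ingroup sequence required")
    if (length(object@outgroup) != 1L) return("exactly one outgroup sequence required")
    if (length(unique(c(w, wo))) != 1L) return("all sequences must have equal length")
    if (w[1] %% 3L != 0L) return("alignment length must be divisible by 3")
    if (length(object@mask) != w[1] %/% 3L) return("mask must have one entry per codon")
    TRUE
  })

#' Paired neutral/selected site frequency spectra with divergence
#'
#' Sample SFS for synonymous (neutral) and nonsynonymous (selected) sites,
#' indexed by derived-allele count 1..n-1, plus folded invariant classes
#' (sites monomorphic in the ingroup, unpolarized), divergence counts and
#' NG86 fractional site totals.
#'
#' @slot n integer haplotype sample size.
#' @slot neutralSfs,selectedSfs numeric vectors of length \code{n - 1}.
#' @slot invariantNeutral,invariantSelected numeric; monomorphic site mass
#'   (fractional, from per-position synonymous/nonsynonymous site weights).
#' @slot Dn,Ds numeric divergence counts; \code{LN},\code{LS} site totals.
#' @export
setClass("PairedSFS",
  representation(n = "integer", neutralSfs = "numeric", selectedSfs = "numeric",
                 invariantNeutral = "numeric", invariantSelected = "numeric",
                 Dn = "numeric", Ds = "numeric", LN = "numeric", LS = "numeric"),
  validity = function(object) {
    if (object@n < 2L) return("sample size n must be >= 2")
    if (length(object@neutralSfs) != object@n - 1L ||
        length(object@selectedSfs) != object@n - 1L)
      return("SFS vectors must have length n - 1")
    if (any(c(object@neutralSfs, object@selectedSfs, object@invariantNeutral,
              object@invariantSelected, object@Dn, object@Ds) < 0))
      return("all counts must be nonnegative")
    TRUE
  })

#' Two-epoch demography plus gamma DFE fit with derived alpha and omega_A
#'
#' @slot demography list with \code{n2OverN1}, \code{t2}, \code{nRef}.
#' @slot dfe list: \code{type} ("gamma" or "point"), and \code{meanNes},
#'   \code{shape} or \code{s}. \code{meanNes} is the mean of -S, S = 4*Ne*s,
#'   on the deleterious scale.
#' @slot logLik joint maximized log likelihood (neutral + selected stages).
#' @slot alpha proportion of adaptive nonsynonymous substitutions (may be
#'   negative). \slot omegaA adaptive nonsynonymous substitutions per
#'   synonymous substitution per site (may be negative).
#' @slot seOmegaA bootstrap SE (NA until \code{bootstrapCI} is run).
#' @slot discretized proportions of deleterious mutations per |Ne s| bin.
#' @slot thetaNeutral,thetaSelected fitted per-site mutation-scale nuisances.
#' @slot gridS,gridSpectra internal S grid and per-S expected sample spectra
#'   for the fitted demography (kept for reuse by downstream operations).
#' @slot n sample size; \slot folded whether the SFS was folded for fitting.
#' @export
setClass("DFEFit",
  representation(demography = "list", dfe = "list", logLik = "numeric",
                 alpha = "numeric", omegaA = "numeric", seOmegaA = "numeric",
                 discretized = "numeric", thetaNeutral = "numeric",
                 thetaSelected = "numeric", gridS = "numeric",
                 gridSpectra = "matrix", n = "integer", folded = "logical"))

#' Posterior fit of the cross-species hierarchical count model
#'
#' @slot draws matrix of posterior draws (one column per monitored quantity).
#' @slot diagnostics data.frame of R-hat and effective sizes per parameter.
#' @slot records the input count table (one row per gene x species).
#' @slot spec the model specification used.
#' @slot levels list of factor level vectors (species, pathway, gene, homolog).
#' @export
setClass("SnipreFit",
  representation(draws = "matrix", diagnostics = "data.frame",
                 records = "data.frame", spec = "list", levels = "list"))

#' Posterior fit of the measurement-error meta-analysis of per-gene omega_A
#'
#' @slot draws matrix of posterior draws.
#' @slot model model label (rnai_vs_control, pathway, pirna_function,
#'   homolog, homolog_no_pathway).
#' @slot table the input omega table.
#' @slot classes fixed-effect class levels (first = reference where relevant).
#' @export
setClass("MetaFit",
  representation(draws = "matrix", model = "character", table = "data.frame",
                 classes = "character"))

#' Composite-likelihood-ratio sweep scan over a region
#'
#' @slot positions grid positions (bp, 0-based).
#' @slot clr CLR value at each grid point.
#' @slot alphaHat maximizing sweep intensity at each grid point.
#' @slot threshold significance threshold (NA until set).
#' @slot intervals data.frame of merged sweep-positive intervals
#'   (0-based half-open start/end).
#' @export
setClass("CLRScan",
  representation(positions = "numeric", clr = "numeric", alphaHat = "numeric",
                 threshold = "numeric", intervals = "data.frame"),
  validity = function(object) {
    if (length(object@clr) != length(object@positions) ||
        length(object@alphaHat) != length(object@positions))
      return("positions, clr and alphaHat must have equal length")
    if (any(object@clr < -1e-8)) return("CLR must be nonnegative up to tolerance")
    TRUE
  })

#' Binary haplotype matrix over segregating sites
#'
#' @slot mat n x m 0/1 matrix (rows = haplotypes, 1 = derived allele).
#' @slot positions site positions in bp (0-based), strictly increasing.
#' @export
setClass("HaplotypeMatrix",
  representation(mat = "matrix", positions = "numeric"),
  validity = function(object) {
    if (ncol(object@mat) != length(object@positions))
      return("one position per column required")
    if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    if (!all(object@mat %in% c(0, 1))) return("matrix entries must be 0/1")
    TRUE
  })

#' Region of sites with derived-allele counts and a background spectrum
#'
#' Per-site derived counts (0..n) or a folded-invariant flag, plus the
#' background spectrum used by the sweep composite likelihood.
#'
#' @slot positions site positions (bp, 0-based).
#' @slot counts integer derived counts; NA marks folded-invariant sites
#'   (monomorphic in the ingroup, unpolarized).
#' @slot n haplotype sample size.
#' @slot background probabilities over derived counts 0..n (sums to 1).
#' @export
setClass("RegionSites",
  representation(positions = "numeric", counts = "integer", n = "integer",
                 background = "numeric"),
  validity = function(object) {
    if (length(object@positions) != length(object@counts))
      return("one count per position required")
    ok <- is.na(object@counts) | (object@counts >= 0L & object@counts <= object@n)
    if (!all(ok)) return("counts must lie in 0..n or be NA (folded invariant)")
    if (length(object@background) != object@n + 1L)
      return("background must have n + 1 classes")
    if (any(object@background < 0)) return("background has negative mass")
    if (abs(sum(object@background) - 1) > 1e-8) return("background must sum to 1")
    TRUE
  })

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment %s / %s: %d ingroup haplotypes, %d codons (%d masked)\n",
              object@geneId, object@speciesId, length(object@ingroup),
              length(object@mask), sum(object@mask)))
})

setMethod("show", "PairedSFS", function(object) {
  cat(sprintf("PairedSFS n=%d: %d selected / %d neutral polymorphic sites; Dn=%g Ds=%g; LN=%.1f LS=%.1f\n",
              object@n, round(sum(object@selectedSfs)), round(sum(object@neutralSfs)),
              object@Dn, object@Ds, object@LN, object@LS))
})

setMethod("show", "DFEFit", function(object) {
  cat("DFEFit\n")
  cat(sprintf("  demography: n2/n1=%.3g, t2=%.3g (nRef=%d)\n",
              object@demography$n2OverN1, object@demography$t2, object@demography$nRef))
  if (identical(object@dfe$type, "gamma"))
    cat(sprintf("  gamma DFE: mean |Ne s| = %.3g, shape = %.3g\n",
                object@dfe$meanNes, object@dfe$shape))
  else cat(sprintf("  point-mass DFE at S = %.3g\n", object@dfe$s))
  cat(sprintf("  alpha = %.4g, omega_A = %.4g (SE %.3g), logLik = %.2f\n",
              object@alpha, object@omegaA, object@seOmegaA, object@logLik))
})

setMethod("show", "CLRScan", function(object) {
  cat(sprintf("CLRScan: %d grid points, max CLR = %.2f at %d bp",
              length(object@positions), max(object@clr),
              round(object@positions[which.max(object@clr)])))
  if (!is.na(object@threshold))
    cat(sprintf("; threshold = %.2f, %d sweep-positive interval(s)",
                object@threshold, nrow(object@intervals)))
  cat("\n")
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d segregating sites\n",
              nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "RegionSites", function(object) {
  cat(sprintf("RegionSites: %d sites (%d polymorphic), n=%d\n",
              length(object@positions),
              sum(!is.na(object@counts) & object@counts > 0L & object@counts < object@n),
              object@n))
})

setMethod("show", "SnipreFit", function(object) {
  cat(sprintf("SnipreFit: %d draws x %d monitored quantities; %d gene-species records\n",
              nrow(object@draws), ncol(object@draws), nrow(object@records)))
  bad <- object@diagnostics$rhat > 1.05
  if (any(bad, na.rm = TRUE))
    cat(sprintf("  WARNING: %d parameter(s) with R-hat > 1.05\n", sum(bad, na.rm = TRUE)))
})

setMethod("show", "MetaFit", function(object) {
  cat(sprintf("MetaFit (%s): %d draws, classes: %s\n", object@model,
              nrow(object@draws), paste(object@classes, collapse = ", ")))
})

# ---- accessors ----

#' @rdname CLRScan-class
#' @param x a CLRScan
#' @export
clrValues <- function(x) x@clr

#' @rdname CLRScan-class
#' @export
gridPositions <- function(x) x@positions

#' @rdname HaplotypeMatrix-class
#' @param x a HaplotypeMatrix or RegionSites
#' @export
sitePositions <- function(x) x@positions

#' @rdname HaplotypeMatrix-class
#' @export
haplotypes <- function(x) x@mat

#' @rdname SnipreFit-class
#' @param x a SnipreFit or MetaFit
#' @export
posteriorDraws <- function(x) x@draws
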