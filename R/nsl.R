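#' Standardized nSL haplotype scan
#'
#' For site i and a haplotype pair, L is the number of consecutive
#' segregating sites in the maximal run containing i over which the pair is
#' identical. SL_der(i) and SL_anc(i) average L over pairs sharing the
#' derived and ancestral allele at i; raw nSL = ln(SL_anc / SL_der), and
#' values are standardized within derived-allele-frequency bins of equal
#' occupancy (subtract the bin mean, divide by the bin SD). Runs stop at the
#' matrix edges without extrapolation. Sites with fewer than
#' \code{minClassSize} carriers in either allele class are skipped.
#'
#' @param h a \linkS4class{HaplotypeMatrix}.
#' @param freqBins number of derived-frequency bins for standardization.
#' @param minClassSize minimum carriers per allele class (default 2).
#' @return data.frame with position, derivedCount, rawNsl and standardized
#'   nsl per retained site.
#' @export
nslScan <- function(h, freqBins = 20L, minClassSize = 2L) {
  stopifnot(is(h, "HaplotypeMatrix"))
  mat <- h@mat
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) stop("nSL requires at least 4 haplotypes")
  d <- colSums(mat)
  if (all(d == 0 | d == n)) stop("monomorphic input: no segregating sites")
  keep <- which(d >= minClassSize & (n - d) >= minClassSize)
  if (length(keep) == 0L)
    return(data.frame(position = numeric(0), derivedCount = integer(0),
                      rawNsl = numeric(0), nsl = numeric(0)))
  pairs <- utils::combn(n, 2)
  pa <- pairs[1, ]; pb <- pairs[2, ]
  matA <- mat[pa, , drop = FALSE]; matB <- mat[pb, , drop = FALSE]
  eq <- matA == matB
  runLen <- matrix(0, nrow(eq), m)
  for (p in seq_len(nrow(eq))) {
    r <- rle(eq[p, ])
    runLen[p, ] <- rep(ifelse(r$values, r$lengths, 0), r$lengths)
  }
  bothDer <- (matA == 1) & (matB == 1)
  bothAnc <- (matA == 0) & (matB == 0)
  slDer <- colSums(runLen * bothDer) / colSums(bothDer)
  slAnc <- colSums(runLen * bothAnc) / colSums(bothAnc)
  raw <- log(slAnc / slDer)
  out <- data.frame(position = h@positions[keep], derivedCount = d[keep],
                    rawNsl = raw[keep], nsl = NA_real_)
  # equal-occupancy derived-count bins
  nb <- max(1L, min(freqBins, length(keep)))
  qs <- .quantile7(out$derivedCount, seq(0, 1, length.out = nb + 1L))
  bins <- cut(out$derivedCount, breaks = unique(qs), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- which(bins == b)
    mu <- mean(out$rawNsl[idx]); sdv <- stats::sd(out$rawNsl[idx])
    out$nsl[idx] <- if (is.na(sdv) || sdv == 0) 0 else (out$rawNsl[idx] - mu) / sdv
  }
  out
}
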