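#' Construct a CodonAlignment
#'
#' @param ingroup character vector or DNAStringSet of ingroup haplotypes.
#' @param outgroup single character string or DNAStringSet of length 1.
#' @param geneId,speciesId identifiers.
#' @param mask optional logical per-codon mask (TRUE = masked).
#' @return a \linkS4class{CodonAlignment}.
#' @export
codonAlignment <- function(ingroup, outgroup, geneId = "gene", speciesId = "species",
                           mask = NULL) {
  if (is.character(ingroup)) ingroup <- Biostrings::DNAStringSet(ingroup)
  if (is.character(outgroup)) outgroup <- Biostrings::DNAStringSet(outgroup)
  if (is.null(mask)) mask <- rep(FALSE, Biostrings::width(ingroup)[1] %/% 3L)
  new("CodonAlignment", geneId = geneId, speciesId = speciesId,
      ingroup = ingroup, outgroup = outgroup, mask = mask)
}

.alnMatrix <- function(aln) {
  t(vapply(as.character(aln@ingroup), function(s) strsplit(s, "")[[1]],
           character(Biostrings::width(aln@ingroup)[1]), USE.NAMES = FALSE))
}

#' Majority-rule consensus of the ingroup alignment
#'
#' Per-column majority base; ties are broken in favor of the base carried by
#' the first-listed sequence among the tied candidates; gap characters are
#' outvoted by any base.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @return a single nucleotide character string.
#' @export
buildConsensus <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- .alnMatrix(aln)
  apply2 <- function(col) {
    bases <- col[col %in% .BASES]
    if (length(bases) == 0L) return(col[1])
    tab <- table(bases)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) == 1L) return(cand)
    # tie: earliest-listed sequence carrying a tied base wins
    col[which(col %in% cand)[1]]
  }
  paste(apply(m, 2, apply2), collapse = "")
}

#' Mask sliding windows of anomalously high divergence
#'
#' Non-overlapping windows of \code{windowBp} sites are compared between two
#' aligned sequences; windows whose divergence (mismatches over compared
#' ACGT-ACGT sites) exceeds mean + \code{sdThreshold} * SD are masked. Windows
#' with no comparable sites are excluded from the mean/SD and left unmasked.
#'
#' @param seqA,seqB equal-length aligned sequences (character).
#' @param windowBp window size in bp.
#' @param sdThreshold number of SDs above the mean divergence (default 6).
#' @return logical vector, one entry per window (TRUE = masked), with the
#'   per-window divergence attached as attribute \code{"divergence"}.
#' @export
maskDivergentWindows <- function(seqA, seqB, windowBp, sdThreshold = 6) {
  stopifnot(nchar(seqA) == nchar(seqB), windowBp >= 1)
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  L <- length(a)
  starts <- seq(1L, L, by = windowBp)
  div <- vapply(starts, function(s) {
    idx <- s:min(s + windowBp - 1L, L)
    ok <- a[idx] %in% .BASES & b[idx] %in% .BASES
    if (!any(ok)) return(NA_real_)
    mean(a[idx][ok] != b[idx][ok])
  }, 0)
  usable <- !is.na(div)
  mu <- mean(div[usable]); sdv <- sd(div[usable])
  if (is.na(sdv)) sdv <- 0
  cut <- if (is.infinite(sdThreshold)) Inf else mu + sdThreshold * sdv
  masked <- usable & div > cut
  attr(masked, "divergence") <- div
  masked
}

#' Mask codon blocks with low amino-acid identity to the consensus
#'
#' Automated surrogate for manual removal of misaligned blocks: the alignment
#' is cut into blocks of \code{blockCodons} codons and a block is masked when
#' the amino-acid identity of any sequence (ingroup or outgroup) to the
#' consensus, over comparable codons, falls below \code{minIdentity}.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param minIdentity minimum tolerated amino-acid identity in [0, 1].
#' @param blockCodons block size in codons.
#' @param verbose log masking decisions to stderr.
#' @return the alignment with an updated mask.
#' @export
trimMisalignedBlocks <- function(aln, minIdentity = 0.3, blockCodons = 15L,
                                 verbose = FALSE) {
  stopifnot(is(aln, "CodonAlignment"))
  if (minIdentity <= 0) return(aln)
  cons <- buildConsensus(aln)
  nc <- nchar(cons) %/% 3L
  seqs <- c(as.character(aln@ingroup), as.character(aln@outgroup))
  aaOf <- function(s, i) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", codon)) NA_character_ else unname(.codonTables()$aa[codon])
  }
  consAA <- vapply(seq_len(nc), function(i) aaOf(cons, i), "")
  mask <- aln@mask
  starts <- seq(1L, nc, by = blockCodons)
  for (s in starts) {
    idx <- s:min(s + blockCodons - 1L, nc)
    for (sq in seqs) {
      aas <- vapply(idx, function(i) aaOf(sq, i), "")
      comp <- !is.na(aas) & !is.na(consAA[idx])
      if (!any(comp)) next
      ident <- mean(aas[comp] == consAA[idx][comp])
      if (ident < minIdentity) {
        mask[idx] <- TRUE
        if (verbose)
          message(sprintf("masking codons %d-%d (identity %.2f < %.2f)",
                          min(idx), max(idx), ident, minIdentity))
        break
      }
    }
  }
  methods::initialize(aln, mask = mask)
}

# shared per-codon pass: consensus, per-codon validity, divergence and sites
.codonPass <- function(aln) {
  m <- .alnMatrix(aln)
  og <- strsplit(as.character(aln@outgroup)[1], "")[[1]]
  nc <- ncol(m) %/% 3L
  cons <- strsplit(buildConsensus(aln), "")[[1]]
  valid <- !aln@mask
  nonACGT <- 0L
  for (i in seq_len(nc)) {
    if (!valid[i]) next
    cols <- (3L * i - 2L):(3L * i)
    if (any(!m[, cols] %in% .BASES) || any(!og[cols] %in% .BASES) ||
        .isStop(paste(cons[cols], collapse = ""))) {
      valid[i] <- FALSE
      nonACGT <- nonACGT + 1L
    }
  }
  list(m = m, og = og, cons = cons, nc = nc, valid = valid, nonACGT = nonACGT)
}

#' Tabulate McDonald-Kreitman counts from a codon alignment
#'
#' Polymorphism is counted within the ingroup sample: each segregating
#' position is classified synonymous or nonsynonymous against the codon
#' consensus background. Divergence is counted between the ingroup consensus
#' and the outgroup; codons differing at more than one position are scored by
#' averaging over minimal mutational pathways, excluding pathways through
#' stop codons. Fractional site totals L_N and L_S come from NG86-style
#' enumeration of single-nucleotide neighbors of the consensus codons.
#' Codons containing non-ACGT characters are masked and logged.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param isRnai,pathway,pirnaFunction,homologId optional class labels
#'   attached to the record.
#' @return a one-row data.frame (MK record) with columns gene_id, species_id,
#'   Pn, Ps, Dn, Ds, L_N, L_S and class labels.
#' @export
tabulateMK <- function(aln, isRnai = NA, pathway = NA_character_,
                       pirnaFunction = NA_character_, homologId = NA_character_) {
  stopifnot(is(aln, "CodonAlignment"))
  cp <- .codonPass(aln)
  Pn <- 0; Ps <- 0; Dn <- 0; Ds <- 0; LN <- 0; LS <- 0
  for (i in seq_len(cp$nc)) {
    if (!cp$valid[i]) next
    cols <- (3L * i - 2L):(3L * i)
    consCodon <- paste(cp$cons[cols], collapse = "")
    st <- codonSites(consCodon)
    LS <- LS + st["syn"]; LN <- LN + st["nonsyn"]
    ogCodon <- paste(cp$og[cols], collapse = "")
    if (ogCodon != consCodon) {
      pc <- .codonPathCounts(consCodon, ogCodon)
      Ds <- Ds + pc["syn"]; Dn <- Dn + pc["nonsyn"]
    }
    for (p in 1:3) {
      col <- cp$m[, cols[p]]
      alleles <- unique(col)
      if (length(alleles) < 2L) next
      for (alt in setdiff(alleles, cp$cons[cols[p]])) {
        toCodon <- consCodon
        substr(toCodon, p, p) <- alt
        if (.isSynChange(consCodon, toCodon)) Ps <- Ps + 1 else Pn <- Pn + 1
      }
    }
  }
  data.frame(gene_id = aln@geneId, species_id = aln@speciesId,
             Pn = Pn, Ps = Ps, Dn = unname(Dn), Ds = unname(Ds),
             L_N = unname(LN), L_S = unname(LS),
             is_rnai = isRnai, pathway = pathway,
             pirna_function = pirnaFunction, homolog_id = homologId,
             masked_codons = sum(!cp$valid), stringsAsFactors = FALSE)
}

#' Classical McDonald-Kreitman test
#'
#' alpha_MK = 1 - (Ds * Pn) / (Dn * Ps), with a two-sided Fisher exact test on
#' the 2x2 table of (Pn, Ps) vs (Dn, Ds). Undefined ratios (Dn = 0 or Ps = 0)
#' are flagged, not fabricated.
#'
#' @param record a one-row MK record as returned by \code{\link{tabulateMK}},
#'   or NULL if counts are given directly.
#' @param Pn,Ps,Dn,Ds counts (used when \code{record} is NULL).
#' @return list with \code{alphaMk}, \code{oddsRatio}, \code{fisherP} and
#'   \code{undefined}.
#' @export
mkTest <- function(record = NULL, Pn, Ps, Dn, Ds) {
  if (!is.null(record)) {
    Pn <- record$Pn; Ps <- record$Ps; Dn <- record$Dn; Ds <- record$Ds
  }
  stopifnot(all(c(Pn, Ps, Dn, Ds) >= 0))
  undefined <- (Dn == 0 || Ps == 0)
  alpha <- if (undefined) NA_real_ else 1 - (Ds * Pn) / (Dn * Ps)
  or <- if (undefined || Ds == 0) NA_real_ else (Pn * Ds) / (Ps * Dn)
  p <- stats::fisher.test(matrix(c(Pn, Ps, Dn, Ds), nrow = 2))$p.value
  list(alphaMk = alpha, oddsRatio = or, fisherP = p, undefined = undefined)
}

#' Extract the paired site frequency spectrum from a codon alignment
#'
#' For each segregating site the derived allele is identified by parsimony
#' against the outgroup and its carrier count is recorded into the synonymous
#' (neutral) or nonsynonymous (selected) SFS. Sites where the outgroup
#' matches neither ingroup allele are folded (assigned the minor count,
#' merging class i with n - i). Ingroup-invariant sites enter the folded
#' invariant classes with fractional synonymous/nonsynonymous weights from
#' the per-position NG86 site counts. Sites with more than two ingroup
#' alleles are excluded and logged.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @return a \linkS4class{PairedSFS}.
#' @export
extractSFS <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  cp <- .codonPass(aln)
  n <- nrow(cp$m)
  if (n < 2L) stop("extractSFS needs at least two ingroup haplotypes")
  neu <- numeric(n - 1L); sel <- numeric(n - 1L)
  invNeu <- 0; invSel <- 0; Dn <- 0; Ds <- 0; LN <- 0; LS <- 0
  triallelic <- 0L
  tb <- .codonTables()
  for (i in seq_len(cp$nc)) {
    if (!cp$valid[i]) next
    cols <- (3L * i - 2L):(3L * i)
    consCodon <- paste(cp$cons[cols], collapse = "")
    st <- codonSites(consCodon)
    LS <- LS + st["syn"]; LN <- LN + st["nonsyn"]
    ogCodon <- paste(cp$og[cols], collapse = "")
    if (ogCodon != consCodon) {
      pc <- .codonPathCounts(consCodon, ogCodon)
      Ds <- Ds + pc["syn"]; Dn <- Dn + pc["nonsyn"]
    }
    for (p in 1:3) {
      col <- cp$m[, cols[p]]
      alleles <- unique(col)
      if (length(alleles) == 1L) {
        f <- tb$synFrac[consCodon, p]
        invNeu <- invNeu + f; invSel <- invSel + (1 - f)
      } else if (length(alleles) == 2L) {
        ogBase <- cp$og[cols[p]]
        cnt <- c(sum(col == alleles[1]), sum(col == alleles[2]))
        if (ogBase %in% alleles) {
          derived <- setdiff(alleles, ogBase)
          k <- cnt[match(derived, alleles)]
        } else {
          k <- min(cnt)  # unpolarizable: folded
        }
        alt <- setdiff(alleles, cp$cons[cols[p]])[1]
        toCodon <- consCodon; substr(toCodon, p, p) <- alt
        if (.isSynChange(consCodon, toCodon)) neu[k] <- neu[k] + 1
        else sel[k] <- sel[k] + 1
      } else {
        triallelic <- triallelic + 1L
      }
    }
  }
  out <- new("PairedSFS", n = as.integer(n), neutralSfs = neu, selectedSfs = sel,
             invariantNeutral = unname(invNeu), invariantSelected = unname(invSel),
             Dn = unname(Dn), Ds = unname(Ds), LN = unname(LN), LS = unname(LS))
  attr(out, "excluded_triallelic") <- triallelic
  out
}
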