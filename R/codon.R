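# Genetic-code machinery shared by the MK tabulator and the alignment
# simulator. All lookups are built once from Biostrings::GENETIC_CODE
# (standard code) and cached.

.codonEnv <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.codonTables <- function() {
  if (!is.null(.codonEnv$aa)) return(.codonEnv)
  gc <- Biostrings::GENETIC_CODE
  .codonEnv$aa <- gc
  .codonEnv$sense <- names(gc)[gc != "*"]
  # NG86-style fractional sites: at each codon position, the synonymous
  # fraction is (#synonymous one-step changes) / (#changes not creating a
  # stop); changes to stop codons are excluded from both numerator and
  # denominator so every position contributes exactly one site.
  syn <- matrix(0, nrow = 64, ncol = 3, dimnames = list(names(gc), NULL))
  for (codon in names(gc)) {
    if (gc[codon] == "*") next
    for (pos in 1:3) {
      alts <- setdiff(.BASES, substr(codon, pos, pos))
      to <- vapply(alts, function(b) { x <- codon; substr(x, pos, pos) <- b; x }, "")
      aas <- gc[to]
      nonstop <- aas != "*"
      syn[codon, pos] <- if (any(nonstop)) sum(aas[nonstop] == gc[codon]) / sum(nonstop) else 0
    }
  }
  .codonEnv$synFrac <- syn
  .codonEnv
}

.isStop <- function(codon) .codonTables()$aa[codon] == "*"

# synonymous/nonsynonymous status of a single-nucleotide codon change;
# changes to a stop codon count as nonsynonymous
.isSynChange <- function(from, to) {
  aa <- .codonTables()$aa
  !is.na(aa[from]) && !is.na(aa[to]) && aa[to] != "*" && aa[from] == aa[to]
}

#' Fractional synonymous/nonsynonymous site counts for a codon
#'
#' NG86-style enumeration of the nine single-nucleotide neighbors: at each
#' position the synonymous fraction is the number of synonymous one-step
#' changes divided by the number of changes not creating a stop codon, so
#' each position contributes exactly one site and the totals sum to 3.
#'
#' @param codon a sense codon, e.g. \code{"ATG"}.
#' @return named numeric vector \code{c(syn =, nonsyn =)}.
#' @export
codonSites <- function(codon) {
  tb <- .codonTables()
  if (is.na(tb$aa[codon]) || tb$aa[codon] == "*")
    stop("codonSites requires a sense codon, got ", codon)
  s <- sum(tb$synFrac[codon, ])
  c(syn = s, nonsyn = 3 - s)
}

# average synonymous/nonsynonymous substitution counts between two codons
# over minimal mutational pathways, excluding pathways through stop codons;
# if every pathway is blocked, all pathways are used with steps into stops
# counted as nonsynonymous.
.codonPathCounts <- function(from, to) {
  tb <- .codonTables()
  diffPos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  d <- length(diffPos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(diffPos) else {
    idx <- if (d == 2L) list(diffPos, rev(diffPos)) else {
      p <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) p[[length(p) + 1L]] <- diffPos[c(i, j, setdiff(1:3, c(i, j)))]
      p
    }
    idx
  }
  walk <- function(order, allowStop) {
    cur <- from; syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      if (!allowStop && tb$aa[nxt] == "*" && nxt != to) return(NULL)
      if (tb$aa[nxt] != "*" && tb$aa[cur] != "*" && tb$aa[nxt] == tb$aa[cur]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allowStop = FALSE))
  if (length(paths) == 0L) paths <- lapply(perms, walk, allowStop = TRUE)
  colMeans(do.call(rbind, paths))
}
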