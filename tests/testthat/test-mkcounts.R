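test_that("consensus is majority rule with first-sequence tie-breaking", {
  aln1 <- codonAlignment("ATGAAA", "ATGAAA")
  expect_identical(buildConsensus(aln1), "ATGAAA")
  aln2 <- codonAlignment(c("ATGAAA", "ATGAAA", "GTGAAA"), "ATGAAA")
  expect_identical(buildConsensus(aln2), "ATGAAA")
  # two-sequence tie at position 1: first sequence wins
  aln3 <- codonAlignment(c("GTGAAA", "ATGAAA"), "ATGAAA")
  expect_identical(substr(buildConsensus(aln3), 1, 1), "G")
  # gaps are outvoted by bases
  aln4 <- codonAlignment(c("-TGAAA", "-TGAAA", "CTGAAA"), "ATGAAA")
  expect_identical(substr(buildConsensus(aln4), 1, 1), "C")
})

test_that("divergent-window masking flags only extreme windows", {
  base <- strrep("A", 100)
  flip <- function(s, k) {  # make k mismatches in a 100bp window
    v <- strsplit(s, "")[[1]]; v[seq_len(k)] <- "T"; paste(v, collapse = "")
  }
  a <- strrep(base, 100)
  bParts <- c(replicate(99, flip(base, 1)), flip(base, 90))
  b <- paste(bParts, collapse = "")
  m <- maskDivergentWindows(a, b, windowBp = 100)
  expect_identical(which(m), 100L)
  expect_false(any(maskDivergentWindows(a, a, windowBp = 100)))
  expect_false(any(maskDivergentWindows(a, b, windowBp = 100, sdThreshold = Inf)))
})

test_that("misaligned-block trimming masks junk blocks and nothing else", {
  cfg <- simConfig(seed = 11, nHaplotypes = 4)
  aln <- simCodonAlignment(cfg, 60, 0, 0)
  expect_identical(trimMisalignedBlocks(aln)@mask, aln@mask)
  expect_identical(trimMisalignedBlocks(aln, minIdentity = 0)@mask, aln@mask)
  # replace the last 15 codons of one ingroup sequence with a frame-shifted
  # junk block: amino-acid identity to the consensus collapses
  seqs <- as.character(aln@ingroup)
  junk <- paste(rep("CGT", 15), collapse = "")
  substr(seqs[2], 3 * 45 + 1, 3 * 60) <- junk
  aln2 <- codonAlignment(seqs, as.character(aln@outgroup), mask = aln@mask)
  m2 <- trimMisalignedBlocks(aln2, minIdentity = 0.3, blockCodons = 15)@mask
  expect_true(all(m2[46:60]))
  expect_false(any(m2[1:45]))
})

test_that("NG86 site counts match genetic-code enumeration", {
  # ATG (Met): all nine neighbors are nonsynonymous
  expect_equal(unname(codonSites("ATG")["syn"]), 0)
  # TTT (Phe): only TTC is synonymous, all third-position changes non-stop
  expect_equal(unname(codonSites("TTT")["syn"]), 1 / 3)
  # every sense codon contributes exactly 3 sites
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  tot <- vapply(sense, function(cd) sum(codonSites(cd)), 0)
  expect_true(all(abs(tot - 3) < 1e-12))
})

test_that("tabulateMK classifies divergence and polymorphism correctly", {
  # Lys AAA vs Lys AAG: one synonymous substitution
  aln <- codonAlignment(c("AAA", "AAA"), "AAG")
  rec <- tabulateMK(aln)
  expect_equal(rec$Ds, 1); expect_equal(rec$Dn, 0)
  # identical alignment: all counts zero
  rec0 <- tabulateMK(codonAlignment(c("ATG", "ATG"), "ATG"))
  expect_equal(unlist(rec0[c("Pn", "Ps", "Dn", "Ds")]), c(Pn = 0, Ps = 0, Dn = 0, Ds = 0))
  # polymorphism: TTT/TTC segregating is synonymous
  recP <- tabulateMK(codonAlignment(c("TTT", "TTT", "TTC"), "TTT"))
  expect_equal(recP$Ps, 1); expect_equal(recP$Pn, 0)
  # non-ACGT codon is masked
  recN <- tabulateMK(codonAlignment(c("TTN", "TTT"), "TTT"))
  expect_equal(recN$masked_codons, 1)
  expect_equal(recN$L_N + recN$L_S, 0)
})

test_that("fractional sites sum to 3 per unmasked codon", {
  cfg <- simConfig(seed = 21, nHaplotypes = 6)
  aln <- simCodonAlignment(cfg, 150, 10, 20)
  rec <- tabulateMK(aln)
  expect_equal(rec$L_N + rec$L_S, 3 * (150 - rec$masked_codons), tolerance = 1e-9)
})

test_that("multi-hit codons average over minimal stop-free pathways", {
  # ATG -> CTA differs at positions 1 and 3; both orders avoid stops:
  # ATG(M)->CTG(L) nonsyn ->CTA(L) syn; ATG->ATA(I) nonsyn ->CTA(L) nonsyn
  pc <- rnaiAdapt:::.codonPathCounts("ATG", "CTA")
  expect_equal(unname(pc["syn"]), 0.5)
  expect_equal(unname(pc["nonsyn"]), 1.5)
  # TGT -> TGG would pass through TGA (stop) on no path (single diff)
  pc2 <- rnaiAdapt:::.codonPathCounts("TGT", "TGG")
  expect_equal(sum(pc2), 1)
})

test_that("mkTest matches closed forms and flags degenerate tables", {
  sym <- mkTest(Pn = 10, Ps = 10, Dn = 10, Ds = 10)
  expect_equal(sym$alphaMk, 0)
  expect_equal(sym$fisherP, 1)
  ex <- mkTest(Pn = 10, Ps = 20, Dn = 40, Ds = 20)
  expect_equal(ex$alphaMk, 0.75)
  deg <- mkTest(Pn = 5, Ps = 5, Dn = 0, Ds = 5)
  expect_true(deg$undefined)
  expect_true(is.na(deg$alphaMk))
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(42)
  for (i in 1:80) {
    tab <- rmultinom(1, sample(5:30, 1), rep(0.25, 4))
    p1 <- mkTest(Pn = tab[1], Ps = tab[2], Dn = tab[3], Ds = tab[4])$fisherP
    p2 <- fisherByEnumeration(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("extractSFS records derived counts, folding, and invariant mass", {
  # n = 4, two haplotypes carry derived TTC at a synonymous site
  aln <- codonAlignment(c("TTT", "TTT", "TTC", "TTC"), "TTT")
  sfs <- extractSFS(aln)
  expect_equal(sfs@neutralSfs[2], 1)
  expect_equal(sum(sfs@selectedSfs), 0)
  # invariant site mass: fractional syn/nonsyn weights summing to 3 per codon
  alnInv <- codonAlignment(c("ATG", "ATG"), "ATG")
  s2 <- extractSFS(alnInv)
  expect_equal(s2@invariantNeutral + s2@invariantSelected, 3)
  # outgroup matching neither allele: site folded to the minor count
  alnF <- codonAlignment(c("TTT", "TTT", "TTT", "TTC"), "TTA")
  s3 <- extractSFS(alnF)
  expect_equal(s3@neutralSfs[1], 1)
  # triallelic sites excluded
  alnT <- codonAlignment(c("TTT", "TTC", "TTA"), "TTT")
  s4 <- extractSFS(alnT)
  expect_equal(attr(s4, "excluded_triallelic"), 1)
})

test_that("SFS site total equals the unmasked alignment length", {
  cfg <- simConfig(seed = 31, nHaplotypes = 8)
  aln <- simCodonAlignment(cfg, 120, 8, 15)
  sfs <- extractSFS(aln)
  tot <- sum(sfs@neutralSfs) + sum(sfs@selectedSfs) +
    sfs@invariantNeutral + sfs@invariantSelected
  expect_equal(tot, 3 * 120, tolerance = 1e-9)
})

test_that("counts are invariant to reversing the codon order", {
  cfg <- simConfig(seed = 41, nHaplotypes = 6)
  aln <- simCodonAlignment(cfg, 90, 10, 12)
  revCodons <- function(s) {
    cds <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(rev(cds), collapse = "")
  }
  alnR <- codonAlignment(vapply(as.character(aln@ingroup), revCodons, ""),
                         revCodons(as.character(aln@outgroup)))
  r1 <- tabulateMK(aln); r2 <- tabulateMK(alnR)
  expect_equal(r1[c("Pn", "Ps", "Dn", "Ds", "L_N", "L_S")],
               r2[c("Pn", "Ps", "Dn", "Ds", "L_N", "L_S")])
})

test_that("generator truth equals tabulator output (round-trip oracle)", {
  for (seed in c(7, 19, 53)) {
    cfg <- simConfig(seed = seed, nHaplotypes = 8)
    aln <- simCodonAlignment(cfg, 200, 15, 25)
    tr <- attr(aln, "truth")
    rec <- tabulateMK(aln)
    expect_equal(rec$Pn, tr$Pn); expect_equal(rec$Ps, tr$Ps)
    expect_equal(rec$Dn, tr$Dn); expect_equal(rec$Ds, tr$Ds)
    expect_equal(rec$L_N, tr$LN, tolerance = 1e-9)
    sfs <- extractSFS(aln)
    expect_equal(sfs@neutralSfs, tr$neutralSfs)
    expect_equal(sfs@selectedSfs, tr$selectedSfs)
  }
})
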