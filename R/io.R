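# Readers and writers for the tabular and sequence formats used by the
# pipeline. Count tables use the four-line-per-gene schema (one row per
# mutation type PN/PS/DN/DS); omega tables are one row per gene x species.
# All writers emit a provenance header comment that the paired readers skip.

.provHeader <- function() {
  sprintf("# rnaiAdapt %s", as.character(utils::packageVersion("rnaiAdapt")))
}

#' Write MK records in the four-line count-table schema
#'
#' One row per gene x species x mutation type (PN, PS, DN, DS) with site
#' totals and class labels.
#'
#' @param records MK record data.frame (one row per gene x species).
#' @param path output TSV path.
#' @export
writeCountsTable <- function(records, path) {
  long <- do.call(rbind, lapply(c("PN", "PS", "DN", "DS"), function(mt) {
    cnt <- switch(mt, PN = records$Pn, PS = records$Ps, DN = records$Dn,
                  DS = records$Ds)
    data.frame(gene = records$gene_id, species = records$species_id,
               mutation_type = mt, count = cnt,
               L_N = records$L_N, L_S = records$L_S,
               pathway = if (is.null(records$pathway)) NA else records$pathway,
               is_rnai = if (is.null(records$is_rnai)) NA else records$is_rnai,
               pirna_function = if (is.null(records$pirna_function)) NA else records$pirna_function,
               homolog_id = if (is.null(records$homolog_id)) NA else records$homolog_id,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$species, long$gene), ]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provHeader(), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a four-line-per-gene count table into MK records
#'
#' @param path TSV path.
#' @return MK record data.frame (one row per gene x species).
#' @export
readCountsTable <- function(path) {
  long <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("gene", "species", "mutation_type", "count", "L_N", "L_S")
  if (!all(req %in% names(long)))
    stop("count table must have columns: ", paste(req, collapse = ", "))
  key <- paste(long$gene, long$species, sep = "/")
  bad <- names(which(table(key) != 4L))
  if (length(bad) > 0L)
    stop("gene-species combinations without exactly four mutation-type rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- do.call(rbind, lapply(split(long, key), function(g) {
    cnt <- function(mt) {
      r <- g[g$mutation_type == mt, ]
      if (nrow(r) != 1L) stop("gene ", g$gene[1], ": missing or duplicated ", mt, " row")
      r$count
    }
    data.frame(gene_id = g$gene[1], species_id = g$species[1],
               Pn = cnt("PN"), Ps = cnt("PS"), Dn = cnt("DN"), Ds = cnt("DS"),
               L_N = g$L_N[1], L_S = g$L_S[1],
               pathway = if ("pathway" %in% names(g)) g$pathway[1] else NA,
               is_rnai = if ("is_rnai" %in% names(g)) as.logical(g$is_rnai[1]) else NA,
               pirna_function = if ("pirna_function" %in% names(g)) g$pirna_function[1] else NA,
               homolog_id = if ("homolog_id" %in% names(g)) g$homolog_id[1] else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out[, c("Pn", "Ps", "Dn", "Ds")] < 0)) stop("negative counts in table")
  out
}

#' Write a per-gene omega_A table
#'
#' @param table omega table data.frame.
#' @param path output TSV path.
#' @export
writeOmegaTable <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provHeader(), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-gene omega_A table
#'
#' @param path TSV path.
#' @return omega table data.frame.
#' @export
readOmegaTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("gene_id", "species_id", "omega_a", "se_omega_a")
  if (!all(req %in% names(tab)))
    stop("omega table must have columns: ", paste(req, collapse = ", "))
  if (any(!is.na(tab$se_omega_a) & tab$se_omega_a < 0))
    stop("negative se_omega_a in table")
  if ("is_rnai" %in% names(tab)) tab$is_rnai <- as.logical(tab$is_rnai)
  tab
}

#' Write a paired SFS in DFE-alpha-style text format
#'
#' Line 1: sample size n; line 2: selected SFS over classes 0..n (class 0
#' carries the folded invariant mass); line 3: neutral SFS likewise; line 4:
#' Dn Ds L_N L_S.
#'
#' @param sfs a \linkS4class{PairedSFS}.
#' @param path output path.
#' @export
writeSFS <- function(sfs, path) {
  n <- sfs@n
  lines <- c(.provHeader(),
             as.character(n),
             paste(c(sfs@invariantSelected, sfs@selectedSfs, 0), collapse = " "),
             paste(c(sfs@invariantNeutral, sfs@neutralSfs, 0), collapse = " "),
             paste(c(sfs@Dn, sfs@Ds, sfs@LN, sfs@LS), collapse = " "))
  writeLines(lines, path)
}

#' Read a paired SFS written by \code{\link{writeSFS}}
#'
#' @param path input path.
#' @return a \linkS4class{PairedSFS}.
#' @export
readSFS <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  n <- as.integer(lines[1])
  sel <- as.numeric(strsplit(lines[2], "\\s+")[[1]])
  neu <- as.numeric(strsplit(lines[3], "\\s+")[[1]])
  if (length(sel) != n + 1L || length(neu) != n + 1L)
    stop("SFS lines must have n + 1 entries")
  div <- if (length(lines) >= 4L) as.numeric(strsplit(lines[4], "\\s+")[[1]])
         else c(0, 0, 0, 0)
  new("PairedSFS", n = n, neutralSfs = neu[2:n], selectedSfs = sel[2:n],
      invariantNeutral = neu[1] + neu[n + 1L],
      invariantSelected = sel[1] + sel[n + 1L],
      Dn = div[1], Ds = div[2], LN = div[3], LS = div[4])
}

#' Write a codon alignment as FASTA
#'
#' The outgroup record is flagged by the ID prefix \code{outgroup|}.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param path output FASTA path.
#' @export
writeCodonAlignment <- function(aln, path) {
  seqs <- c(aln@ingroup, aln@outgroup)
  nm <- names(aln@ingroup)
  if (is.null(nm)) nm <- sprintf("%s|hap%02d", aln@geneId, seq_along(aln@ingroup))
  names(seqs) <- c(nm, paste0("outgroup|", aln@geneId))
  Biostrings::writeXStringSet(seqs, path)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA path with one \code{outgroup|}-prefixed record.
#' @param geneId,speciesId identifiers (default from the file).
#' @return a \linkS4class{CodonAlignment}.
#' @export
readCodonAlignment <- function(path, geneId = NULL, speciesId = "species") {
  seqs <- Biostrings::readDNAStringSet(path)
  isOut <- startsWith(names(seqs), "outgroup|")
  if (sum(isOut) != 1L) stop("FASTA must contain exactly one 'outgroup|' record")
  if (is.null(geneId)) geneId <- sub("^outgroup\\|", "", names(seqs)[isOut])
  codonAlignment(seqs[!isOut], seqs[isOut], geneId = geneId, speciesId = speciesId)
}

#' Read phased/pseudohaplotype VCF genotypes into a haplotype matrix
#'
#' Biallelic SNPs only; genotypes are split into haplotypes (phased or
#' pseudohaplotype separators both accepted, haploid calls passed through).
#' Derived coding uses the \code{AA} INFO tag: sites where the ancestral
#' allele equals the ALT are flipped, and sites whose ancestral state is
#' missing or matches neither allele are dropped (count logged).
#'
#' @param path VCF path.
#' @param ancestral "AA" (INFO tag, default) or "ref" (assume REF ancestral).
#' @return a \linkS4class{HaplotypeMatrix}; the number of dropped sites is
#'   attached as attribute \code{"dropped"}.
#' @export
vcfToHaplotypes <- function(path, ancestral = c("AA", "ref")) {
  ancestral <- match.arg(ancestral)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  hapOf <- function(g) strsplit(g, "[|/]")[[1]]
  ploidy <- unique(lengths(lapply(gt[1, ], hapOf)))
  if (length(ploidy) != 1L) stop("mixed ploidy in VCF")
  nHap <- ncol(gt) * ploidy
  rows <- which(biallelic)
  mat <- matrix(NA_integer_, nHap, length(rows))
  for (j in seq_along(rows)) {
    alleles <- unlist(lapply(gt[rows[j], ], hapOf), use.names = FALSE)
    mat[, j] <- as.integer(alleles)
  }
  pos <- as.numeric(fix[rows, "POS"]) - 1  # 0-based internally
  aa <- if (ancestral == "AA") {
    info <- fix[rows, "INFO"]
    m <- regmatches(info, regexpr("AA=[ACGTacgt.]+", info))
    vapply(seq_along(rows), function(j) {
      hit <- regmatches(info[j], regexpr("AA=[ACGTacgt.]", info[j]))
      if (length(hit) == 0L) NA_character_ else toupper(sub("AA=", "", hit))
    }, "")
  } else fix[rows, "REF"]
  ref <- fix[rows, "REF"]; alt <- fix[rows, "ALT"]
  keep <- !is.na(aa) & (aa == ref | aa == alt) & !apply(mat, 2, anyNA)
  dropped <- sum(!keep)
  if (dropped > 0L) message(dropped, " site(s) dropped (unpolarizable or missing calls)")
  mat <- mat[, keep, drop = FALSE]
  flip <- aa[keep] == alt[keep]
  mat[, flip] <- 1L - mat[, flip]
  ord <- order(pos[keep])
  out <- new("HaplotypeMatrix", mat = mat[, ord, drop = FALSE],
             positions = pos[keep][ord])
  attr(out, "dropped") <- dropped
  out
}

#' Write a haplotype matrix as a minimal VCF
#'
#' Haploid samples, REF = ancestral allele (also emitted as the \code{AA}
#' INFO tag), ALT = derived.
#'
#' @param h a \linkS4class{HaplotypeMatrix}.
#' @param path output VCF path.
#' @param contig contig name.
#' @export
writeHaplotypesVCF <- function(h, path, contig = "chr1") {
  n <- nrow(h@mat)
  samples <- sprintf("hap%03d", seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=rnaiAdapt-%s",
                      as.character(utils::packageVersion("rnaiAdapt"))),
              sprintf("##contig=<ID=%s>", contig),
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(h@positions), function(j) {
    paste(c(contig, h@positions[j] + 1, ".", "A", "G", ".", "PASS", "AA=A",
            "GT", as.character(h@mat[, j])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

#' Read gene intervals with class labels from BED
#'
#' BED6+2 (name = gene id; extra columns is_rnai and pathway), 0-based
#' half-open on disk, returned as a GRanges (1-based).
#'
#' @param path BED path.
#' @return a \link[GenomicRanges]{GRanges} with gene_id, is_rnai and pathway
#'   metadata columns.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(is_rnai = "character", pathway = "character"))
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr)$is_rnai <- as.logical(S4Vectors::mcols(gr)$is_rnai)
  gr
}

#' Write gene intervals to BED6+2
#'
#' @param genes a GRanges with gene_id, is_rnai and pathway metadata.
#' @param path output BED path.
#' @export
writeGeneBed <- function(genes, path) {
  mc <- S4Vectors::mcols(genes)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = GenomicRanges::start(genes) - 1L,
                   end = GenomicRanges::end(genes),
                   name = mc$gene_id, score = 0L, strand = ".",
                   is_rnai = tolower(as.character(mc$is_rnai)),
                   pathway = mc$pathway)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
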