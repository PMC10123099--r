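#' Indexed genome sequence access
#'
#' Strand-aware sequence extraction over an indexed FASTA, with
#' chromosome-name normalization between the "chr1" and "1" dialects
#' (plus the chrM/MT synonym pair).
#'
#' @name genome
NULL

chrom_aliases <- function(name) {
  out <- c(name)
  if (startsWith(name, "chr")) out <- c(out, sub("^chr", "", name))
  else out <- c(out, paste0("chr", name))
  if (name %in% c("chrM", "MT", "M", "chrMT"))
    out <- unique(c(out, "chrM", "MT", "M", "chrMT"))
  unique(out)
}

#' Open a genome FASTA
#'
#' Builds the `.fai` index on first use and a chromosome-name
#' normalization table covering the common naming dialects.
#'
#' @param path path to a FASTA file.
#' @return object of class `genome_seq`.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  info <- Rsamtools::seqinfo(fa)
  lens <- GenomeInfoDb::seqlengths(info)
  map <- character(0)
  for (nm in names(lens)) {
    for (alias in chrom_aliases(nm)) map[alias] <- nm
  }
  g <- list(fa = fa, map = map, lengths = lens)
  class(g) <- "genome_seq"
  g
}

normalize_chrom <- function(genome, chrom) {
  nm <- unname(genome$map[chrom])
  if (is.na(nm))
    stop_fmt("unknown chromosome '%s' (also tried '%s')", chrom,
             paste(setdiff(chrom_aliases(chrom), chrom), collapse = "', '"))
  nm
}

#' Fetch a genomic sequence
#'
#' @param genome a `genome_seq` from [load_genome()].
#' @param chrom chromosome in either naming dialect.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` returns the uppercased slice, `"-"` its reverse
#'   complement (ambiguity codes preserved).
#' @return a character string of exactly `end - start` bases.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  nm <- normalize_chrom(genome, chrom)
  len <- unname(genome$lengths[nm])
  if (start < 0 || end > len || start >= end)
    stop_fmt("range [%s,%s) out of bounds for %s (length %d)",
             format(start, scientific = FALSE),
             format(end, scientific = FALSE), nm, len)
  gr <- GenomicRanges::GRanges(nm, IRanges::IRanges(start + 1, end))
  s <- Rsamtools::scanFa(genome$fa, gr)[[1L]]
  s <- Biostrings::DNAString(toupper(as.character(s)))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
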