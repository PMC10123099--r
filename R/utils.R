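# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# reverse complement of a plain character vector of DNA strings,
# preserving IUPAC ambiguity codes
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stable numeric formatting used by all TSV writers: full precision,
# no scientific-notation surprises between write/read cycles
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = NA, trim = TRUE)
  }, character(1))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# intron identity key used by the junction index and host matching
intron_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = "|")
}
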