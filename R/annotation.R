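#' Transcript annotation (BED12)
#'
#' The toolkit takes its transcript models from a BED12 file whose name
#' column holds `"<transcript ID>_<gene symbol>"`. Exon blocks are
#' reconstructed from blockSizes/blockStarts; thickStart/thickEnd give
#' the CDS span (equal values mean a non-coding transcript). All
#' coordinates are 0-based half-open on the genomic axis.
#'
#' @name annotation
NULL

#' Read a BED12 annotation
#'
#' @param path path to a 12-column BED file.
#' @return list of transcript models (class `transcript_set`). Each model
#'   is a list with `transcript_id`, `gene_symbol`, `chrom`, `strand`,
#'   `exons` (two-column matrix of 0-based half-open intervals in
#'   ascending genomic order) and `cds` (length-2 vector or `NULL` for
#'   non-coding transcripts).
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  no_split <- character(0)
  txs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12L)
      stop_fmt("%s: line %d has %d columns; BED12 requires 12", path, i,
               length(f))
    chrom <- f[1L]
    start <- as.numeric(f[2L]); end <- as.numeric(f[3L])
    name <- f[4L]; strand <- f[6L]
    thick_s <- as.numeric(f[7L]); thick_e <- as.numeric(f[8L])
    n_blocks <- as.integer(f[10L])
    sizes <- as.numeric(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
    offs <- as.numeric(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks)
      stop_fmt("%s: line %d: blockCount %d does not match blockSizes/blockStarts",
               path, i, n_blocks)
    if (!strand %in% c("+", "-"))
      stop_fmt("%s: line %d: strand must be '+' or '-'", path, i)
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (is.unsorted(ex_start, strictly = TRUE) ||
        any(ex_start[-1L] < ex_end[-n_blocks]))
      stop_fmt("%s: line %d: exon blocks overlap or are unsorted", path, i)
    if (grepl("_", name, fixed = TRUE)) {
      # split at the LAST underscore: transcript IDs never contain one
      tx_id <- sub("_[^_]*$", "", name)
      symbol <- sub("^.*_", "", name)
    } else {
      no_split <- c(no_split, name)
      tx_id <- name
      symbol <- name
    }
    cds <- if (thick_s == thick_e) NULL else c(thick_s, thick_e)
    txs[[i]] <- list(transcript_id = tx_id, gene_symbol = symbol,
                     chrom = chrom, strand = strand,
                     exons = cbind(start = ex_start, end = ex_end),
                     cds = cds)
  }
  if (length(no_split))
    warn_fmt("%d transcript name(s) without '_' kept verbatim (e.g. %s)",
             length(no_split), no_split[1L])
  class(txs) <- "transcript_set"
  txs
}

tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(NULL)
  cbind(start = tx$exons[-n, "end"], end = tx$exons[-1L, "start"])
}

#' Index annotated junctions and exons
#'
#' Builds the lookup structures shared by the structural analyses: the
#' set of annotated introns (as the gap between consecutive exons of any
#' transcript) and an interval-searchable collection of annotated exons.
#'
#' @param transcripts a `transcript_set` from [read_bed12()].
#' @return list of class `junction_index` with `introns` (character key
#'   set), `exon_gr` (a [GenomicRanges::GRanges] of unique annotated
#'   exons) and `n_transcripts`.
#' @export
build_junction_index <- function(transcripts) {
  keys <- character(0)
  chroms <- character(0); strands <- character(0)
  ex_s <- numeric(0); ex_e <- numeric(0)
  for (tx in transcripts) {
    intr <- tx_introns(tx)
    if (!is.null(intr))
      keys <- c(keys, intron_key(tx$chrom, tx$strand,
                                 intr[, "start"], intr[, "end"]))
    chroms <- c(chroms, rep(tx$chrom, nrow(tx$exons)))
    strands <- c(strands, rep(tx$strand, nrow(tx$exons)))
    ex_s <- c(ex_s, tx$exons[, "start"])
    ex_e <- c(ex_e, tx$exons[, "end"])
  }
  exon_gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start = ex_s + 1, end = ex_e), strand = strands)
  exon_gr <- unique(exon_gr)
  idx <- list(introns = unique(keys), exon_gr = exon_gr,
              n_transcripts = length(transcripts))
  class(idx) <- "junction_index"
  idx
}

#' Annotated exons fully inside a genomic interval
#'
#' @param index a `junction_index`.
#' @param chrom,strand location (strand-matched lookup).
#' @param start,end 0-based half-open query interval.
#' @return GRanges of unique annotated exons contained in the interval.
#' @export
exons_within <- function(index, chrom, strand, start, end) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = start + 1, end = end),
                              strand = strand)
  hits <- GenomicRanges::findOverlaps(index$exon_gr, q, type = "within")
  index$exon_gr[S4Vectors::queryHits(hits)]
}

#' Enumerate annotated skipped-exon configurations
#'
#' For every internal exon of every multi-exon transcript, emits the
#' (upstream exon, exon, downstream exon) triple that a potential
#' skipping event would span. Duplicated triples across isoforms are
#' collapsed. Used as the annotated-transcriptome baseline for the size
#' and splice-site-score analyses.
#'
#' @param transcripts a `transcript_set`.
#' @return data frame with the same geometry columns as [se_view()].
#' @export
annotated_se_triples <- function(transcripts) {
  out <- list()
  k <- 0L
  for (tx in transcripts) {
    n <- nrow(tx$exons)
    if (n < 3L) next
    for (i in seq.int(2L, n - 1L)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = tx$chrom, strand = tx$strand,
        exon_start = tx$exons[i, "start"], exon_end = tx$exons[i, "end"],
        left_es = tx$exons[i - 1L, "start"], left_ee = tx$exons[i - 1L, "end"],
        right_es = tx$exons[i + 1L, "start"], right_ee = tx$exons[i + 1L, "end"],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      exon_start = numeric(0), exon_end = numeric(0),
                      left_es = numeric(0), left_ee = numeric(0),
                      right_es = numeric(0), right_ee = numeric(0)))
  v <- do.call(rbind, out)
  v <- v[!duplicated(v), , drop = FALSE]
  rownames(v) <- NULL
  minus <- v$strand == "-"
  v$up_es <- ifelse(minus, v$right_es, v$left_es)
  v$up_ee <- ifelse(minus, v$right_ee, v$left_ee)
  v$down_es <- ifelse(minus, v$left_es, v$right_es)
  v$down_ee <- ifelse(minus, v$left_ee, v$right_ee)
  v
}

#' Enumerate annotated introns with their flanking exons
#'
#' One record per unique (flanking exon, intron, flanking exon)
#' configuration; the annotated baseline for the retained-intron
#' analyses.
#'
#' @param transcripts a `transcript_set`.
#' @return data frame with the same geometry columns as [ri_view()].
#' @export
annotated_introns <- function(transcripts) {
  out <- list(); k <- 0L
  for (tx in transcripts) {
    n <- nrow(tx$exons)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = tx$chrom, strand = tx$strand,
        left_es = tx$exons[i, "start"], left_ee = tx$exons[i, "end"],
        right_es = tx$exons[i + 1L, "start"], right_ee = tx$exons[i + 1L, "end"],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      left_es = numeric(0), left_ee = numeric(0),
                      right_es = numeric(0), right_ee = numeric(0),
                      intron_start = numeric(0), intron_end = numeric(0)))
  v <- do.call(rbind, out)
  v <- v[!duplicated(v), , drop = FALSE]
  rownames(v) <- NULL
  v$intron_start <- v$left_ee
  v$intron_end <- v$right_es
  v
}

#' Write transcript models as BED12
#'
#' @param transcripts a `transcript_set` or list of transcript models.
#' @param path output path.
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- vapply(transcripts, function(tx) {
    start <- tx$exons[1L, "start"]; end <- tx$exons[nrow(tx$exons), "end"]
    cds <- tx$cds %||% c(start, start)
    sizes <- tx$exons[, "end"] - tx$exons[, "start"]
    offs <- tx$exons[, "start"] - start
    paste(tx$chrom, format(start, scientific = FALSE),
          format(end, scientific = FALSE),
          paste0(tx$transcript_id, "_", tx$gene_symbol), 0, tx$strand,
          format(cds[1L], scientific = FALSE),
          format(cds[2L], scientific = FALSE), "0",
          nrow(tx$exons),
          paste0(paste(format(sizes, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(offs, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
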