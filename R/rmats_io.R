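#' rMATS JCEC event tables
#'
#' Readers, writers and filters for rMATS "JCEC" differential-splicing
#' output. Five event types are supported: skipped exon (SE), retained
#' intron (RI), alternative 5'/3' splice site (A5SS/A3SS) and mutually
#' exclusive exons (MXE). The column contract is positional (1-based):
#' gene symbol in column 3, chromosome in 4, strand in 5, 0-based
#' half-open coordinates in columns 6-11 (6-13 for MXE), FDR in column 20
#' (22 for MXE) and inclusion-level difference in column 23 (25 for MXE).
#' All other columns are carried as opaque text and may be blank.
#'
#' @name rmats_io
NULL

AS_TYPES <- c("SE", "RI", "A5SS", "A3SS", "MXE")

as_type_layout <- function(as_type) {
  as_type <- match.arg(as_type, AS_TYPES)
  if (as_type == "MXE") {
    list(n_coords = 8L, coord_cols = 6:13, fdr_col = 22L, inc_col = 25L,
         min_cols = 25L)
  } else {
    list(n_coords = 6L, coord_cols = 6:11, fdr_col = 20L, inc_col = 23L,
         min_cols = 23L)
  }
}

coord_headers <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  MXE  = c("X1stExonStart_0base", "X1stExonEnd", "X2ndExonStart_0base",
           "X2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
           "downstreamEE")
)

rmats_header <- function(as_type) {
  tail_cols <- c("ID.1", "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                 "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen", "PValue",
                 "FDR", "IncLevel1", "IncLevel2", "IncLevelDifference")
  c("ID", "GeneID", "geneSymbol", "chr", "strand",
    coord_headers[[as_type]], tail_cols)
}

#' Read an rMATS JCEC file
#'
#' Parses one rMATS JCEC table into a `splice_events` data frame with one
#' row per event. Line 1 must be a header. Data lines whose required
#' fields do not parse as numbers are dropped with a warning naming the
#' line numbers; structural problems (missing header, too few columns)
#' are errors. Duplicate events (same type/chrom/strand/coordinates) are
#' collapsed to the record with the smallest FDR, with a warning.
#'
#' @param path path to a tab-separated JCEC file.
#' @param as_type one of `"SE"`, `"RI"`, `"A5SS"`, `"A3SS"`, `"MXE"`.
#' @param lenient pad missing trailing columns with blanks instead of
#'   erroring, to accept tables hand-assembled from other callers.
#' @param flip_sign negate the inclusion-level difference, for runs where
#'   the rMATS sample order was reversed (sample 1 is assumed to be the
#'   test condition, so negative values on SE mean increased skipping).
#' @return a data frame of class `splice_events` with columns `as_type`,
#'   `gene_id`, `gene_symbol`, `chrom`, `strand`, `c1`..`c8` (0-based
#'   half-open coordinates in file order; `c7`/`c8` are `NA` except for
#'   MXE), `fdr`, `inc_diff` and `source_line`.
#' @export
read_rmats <- function(path, as_type, lenient = FALSE, flip_sign = FALSE) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  layout <- as_type_layout(as_type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_fmt("%s: empty file (header required)", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  head1 <- fields[[1L]]
  if (length(head1) >= 6L &&
      !is.na(suppressWarnings(as.numeric(head1[6L])))) {
    stop_fmt("%s: line 1 looks like data; a header line is required", path)
  }
  if (length(fields) == 1L) return(empty_events(as_type))

  rows <- vector("list", length(fields) - 1L)
  bad_lines <- integer(0)
  for (i in seq.int(2L, length(fields))) {
    f <- fields[[i]]
    if (length(f) < layout$min_cols) {
      if (lenient) {
        f <- c(f, rep("", layout$min_cols - length(f)))
      } else {
        stop_fmt("%s: line %d has %d columns; %d required for %s",
                 path, i, length(f), layout$min_cols, as_type)
      }
    }
    coords <- suppressWarnings(as.numeric(f[layout$coord_cols]))
    fdr <- suppressWarnings(as.numeric(f[layout$fdr_col]))
    inc <- suppressWarnings(as.numeric(f[layout$inc_col]))
    if (anyNA(coords) || is.na(fdr) || is.na(inc)) {
      bad_lines <- c(bad_lines, i)
      next
    }
    strand <- f[5L]
    if (!strand %in% c("+", "-"))
      stop_fmt("%s: line %d: strand must be '+' or '-', got '%s'",
               path, i, strand)
    if (any(coords < 0))
      stop_fmt("%s: line %d: negative coordinate", path, i)
    starts <- coords[seq(1L, layout$n_coords, by = 2L)]
    ends <- coords[seq(2L, layout$n_coords, by = 2L)]
    if (any(starts >= ends))
      stop_fmt("%s: line %d: exon start >= end", path, i)
    if (fdr < 0 || fdr > 1)
      stop_fmt("%s: line %d: FDR %s outside [0,1]", path, i, f[layout$fdr_col])
    if (inc < -1 || inc > 1)
      stop_fmt("%s: line %d: inclusion difference %s outside [-1,1]",
               path, i, f[layout$inc_col])
    rows[[i - 1L]] <- list(gene_id = f[2L], gene_symbol = f[3L],
                           chrom = f[4L], strand = strand,
                           coords = coords, fdr = fdr, inc = inc,
                           line = i)
  }
  if (length(bad_lines))
    warn_fmt("%s: dropped %d line(s) with unparseable required fields: %s",
             path, length(bad_lines), paste(bad_lines, collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_events(as_type))

  cmat <- matrix(NA_real_, nrow = length(rows), ncol = 8L)
  for (j in seq_along(rows))
    cmat[j, seq_len(layout$n_coords)] <- rows[[j]]$coords
  ev <- data.frame(
    as_type = as_type,
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    gene_symbol = vapply(rows, `[[`, character(1), "gene_symbol"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  colnames(cmat) <- paste0("c", 1:8)
  ev <- cbind(ev, as.data.frame(cmat))
  ev$fdr <- vapply(rows, `[[`, numeric(1), "fdr")
  ev$inc_diff <- vapply(rows, `[[`, numeric(1), "inc")
  if (flip_sign) ev$inc_diff <- -ev$inc_diff
  ev$source_line <- vapply(rows, `[[`, numeric(1), "line")

  keys <- event_key(ev)
  if (anyDuplicated(keys)) {
    ord <- order(ev$fdr)              # keep smallest FDR per key
    keep <- ord[!duplicated(keys[ord])]
    keep <- sort(keep)                # preserve file order
    warn_fmt("%s: %d duplicate event(s) collapsed (smallest FDR kept)",
             path, nrow(ev) - length(keep))
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  class(ev) <- c("splice_events", "data.frame")
  ev
}

empty_events <- function(as_type) {
  ev <- data.frame(as_type = character(0), gene_id = character(0),
                   gene_symbol = character(0), chrom = character(0),
                   strand = character(0), c1 = numeric(0), c2 = numeric(0),
                   c3 = numeric(0), c4 = numeric(0), c5 = numeric(0),
                   c6 = numeric(0), c7 = numeric(0), c8 = numeric(0),
                   fdr = numeric(0), inc_diff = numeric(0),
                   source_line = numeric(0), stringsAsFactors = FALSE)
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Write events back in rMATS JCEC layout
#'
#' Emits the positional JCEC dialect (header plus data lines) so that
#' re-parsing with [read_rmats()] reproduces the event table field-wise,
#' and a write/parse/write cycle is byte-stable. Columns the toolkit does
#' not model (read counts, p-values, inclusion levels) are written blank.
#'
#' @param events a `splice_events` data frame.
#' @param path output path.
#' @export
write_rmats <- function(events, path) {
  stopifnot(inherits(events, "splice_events"))
  as_type <- if (nrow(events)) events$as_type[1L] else "SE"
  layout <- as_type_layout(as_type)
  hdr <- rmats_header(as_type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(events) == 0L) return(invisible(path))
  nc <- layout$n_coords
  cmat <- as.matrix(events[, paste0("c", seq_len(nc)), drop = FALSE])
  coord_txt <- apply(cmat, 1L, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  blanks <- paste(rep("", 8L), collapse = "\t")  # ID.1 .. PValue
  lines <- paste(seq_len(nrow(events)), events$gene_id, events$gene_symbol,
                 events$chrom, events$strand, coord_txt, blanks,
                 num_chr(events$fdr), "", "", num_chr(events$inc_diff),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Canonical event identity key
#'
#' Deterministic key built from type, chromosome, strand and the full
#' coordinate tuple. Statistics (FDR, inclusion difference), gene labels
#' and file order do not enter the key, so the same physical event
#' observed in different experiments compares equal.
#'
#' @param events a `splice_events` data frame.
#' @return character vector of keys, one per event.
#' @export
event_key <- function(events) {
  cmat <- as.matrix(events[, paste0("c", 1:8), drop = FALSE])
  coord_txt <- apply(cmat, 1L, function(r)
    paste(format(r[!is.na(r)], scientific = FALSE, trim = TRUE),
          collapse = ":"))
  if (nrow(events) == 0L) return(character(0))
  paste(events$as_type, events$chrom, events$strand, coord_txt, sep = ":")
}

#' Filter events by significance and sign
#'
#' Keeps events with FDR strictly below the threshold whose
#' inclusion-level difference matches the requested sign. For SE events a
#' negative inclusion difference means increased skipping under the test
#' condition; for RI a positive difference means increased retention.
#' Events with an inclusion difference of exactly zero belong to neither
#' sign class.
#'
#' @param events a `splice_events` data frame.
#' @param fdr_threshold significance threshold, strict `<` (default
#'   0.0005).
#' @param sign `"both"`, `"negative"` or `"positive"`.
#' @export
filter_significant <- function(events, fdr_threshold = 0.0005,
                               sign = c("both", "negative", "positive")) {
  sign <- match.arg(sign)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  keep <- events$fdr < fdr_threshold
  if (sign == "negative") keep <- keep & events$inc_diff < 0
  if (sign == "positive") keep <- keep & events$inc_diff > 0
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("splice_events", "data.frame")
  out
}

#' Orientation-normalized view of SE events
#'
#' Expands SE events into skipped-exon and flanking-exon coordinates on
#' both the genomic axis (`left_*`/`right_*`, ascending) and in
#' transcript orientation (`up_*`/`down_*`; on the minus strand the
#' transcript-upstream exon is the genomic-right one). The flanking pair
#' emitted by rMATS is re-ordered onto the genomic axis first, so the
#' view is valid whichever convention the producing tool used.
#'
#' @param events SE `splice_events`.
#' @return data frame with `event_key`, `gene_symbol`, `chrom`, `strand`,
#'   `fdr`, `inc_diff`, `exon_start`, `exon_end`, `left_es`, `left_ee`,
#'   `right_es`, `right_ee`, `up_es`, `up_ee`, `down_es`, `down_ee`.
#' @export
se_view <- function(events) {
  stopifnot(all(events$as_type == "SE"))
  a_s <- events$c3; a_e <- events$c4   # first flanking exon, file order
  b_s <- events$c5; b_e <- events$c6   # second flanking exon
  swap <- a_s > b_s
  left_es <- ifelse(swap, b_s, a_s); left_ee <- ifelse(swap, b_e, a_e)
  right_es <- ifelse(swap, a_s, b_s); right_ee <- ifelse(swap, a_e, b_e)
  v <- data.frame(
    event_key = event_key(events),
    gene_symbol = events$gene_symbol,
    chrom = events$chrom, strand = events$strand,
    fdr = events$fdr, inc_diff = events$inc_diff,
    exon_start = events$c1, exon_end = events$c2,
    left_es = left_es, left_ee = left_ee,
    right_es = right_es, right_ee = right_ee,
    stringsAsFactors = FALSE
  )
  bad <- !(v$left_ee <= v$exon_start & v$exon_start < v$exon_end &
             v$exon_end <= v$right_es)
  if (any(bad))
    stop_fmt("%d SE event(s) violate flank<exon<flank ordering (e.g. %s)",
             sum(bad), v$event_key[which(bad)[1L]])
  minus <- v$strand == "-"
  v$up_es <- ifelse(minus, v$right_es, v$left_es)
  v$up_ee <- ifelse(minus, v$right_ee, v$left_ee)
  v$down_es <- ifelse(minus, v$left_es, v$right_es)
  v$down_ee <- ifelse(minus, v$left_ee, v$right_ee)
  v
}

#' Orientation-normalized view of RI events
#'
#' The retained intron is the gap between the two flanking exons on the
#' genomic axis; transcript-oriented upstream/downstream exon labels
#' follow the strand.
#'
#' @param events RI `splice_events`.
#' @export
ri_view <- function(events) {
  stopifnot(all(events$as_type == "RI"))
  a_s <- events$c3; a_e <- events$c4
  b_s <- events$c5; b_e <- events$c6
  swap <- a_s > b_s
  left_es <- ifelse(swap, b_s, a_s); left_ee <- ifelse(swap, b_e, a_e)
  right_es <- ifelse(swap, a_s, b_s); right_ee <- ifelse(swap, a_e, b_e)
  v <- data.frame(
    event_key = event_key(events),
    gene_symbol = events$gene_symbol,
    chrom = events$chrom, strand = events$strand,
    fdr = events$fdr, inc_diff = events$inc_diff,
    left_es = left_es, left_ee = left_ee,
    right_es = right_es, right_ee = right_ee,
    intron_start = left_ee, intron_end = right_es,
    stringsAsFactors = FALSE
  )
  bad <- v$intron_start >= v$intron_end
  if (any(bad))
    stop_fmt("%d RI event(s) with degenerate intron (e.g. %s)",
             sum(bad), v$event_key[which(bad)[1L]])
  v
}
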