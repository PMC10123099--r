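#' Annotation-referenced event structure
#'
#' Structural characterization of significant skipped-exon and
#' retained-intron events against a transcript annotation: which skip
#' junctions are unannotated, how many annotated exons a skip junction
#' jumps over, and the sizes of the exons and introns involved, with the
#' annotated transcriptome as baseline.
#'
#' @name structure_stats
NULL

sign_class <- function(inc_diff) {
  ifelse(inc_diff < 0, "negative", ifelse(inc_diff > 0, "positive", "zero"))
}

#' Classify SE skip junctions as annotated or novel
#'
#' A skip junction is annotated when the genomic interval it splices out
#' (upstream-exon end to downstream-exon start) is exactly an annotated
#' intron of some transcript on the same chromosome and strand.
#'
#' @param events significant SE `splice_events`.
#' @param index a `junction_index`.
#' @param fuzz allow a +/- `fuzz` nt mismatch at each junction end for
#'   annotations in an off-by-one dialect (default 0, exact).
#' @return list of class `annotation_status`: `status` (per-event data
#'   frame with `annotated` flag), `summary` (per sign class: total,
#'   unannotated count, fraction unannotated), `unannotated` (listing of
#'   novel junctions).
#' @export
classify_annotation <- function(events, index, fuzz = 0L) {
  v <- se_view(events)
  junc_s <- v$left_ee
  junc_e <- v$right_es
  annotated <- logical(nrow(v))
  offsets <- seq.int(-fuzz, fuzz)
  for (i in seq_len(nrow(v))) {
    keys <- as.vector(outer(junc_s[i] + offsets, junc_e[i] + offsets,
                            function(a, b) intron_key(v$chrom[i], v$strand[i], a, b)))
    annotated[i] <- any(keys %in% index$introns)
  }
  status <- data.frame(
    event_key = v$event_key, gene_symbol = v$gene_symbol,
    chrom = v$chrom, strand = v$strand,
    junction_start = junc_s, junction_end = junc_e,
    fdr = v$fdr, inc_diff = v$inc_diff, sign = sign_class(v$inc_diff),
    annotated = annotated, stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(c("negative", "positive"), function(s) {
    sub <- status[status$sign == s, , drop = FALSE]
    data.frame(sign = s, total = nrow(sub),
               unannotated = sum(!sub$annotated),
               fraction_unannotated = if (nrow(sub)) mean(!sub$annotated)
                                      else NA_real_)
  }))
  out <- list(status = status, summary = summary,
              unannotated = status[!status$annotated, , drop = FALSE])
  class(out) <- "annotation_status"
  out
}

#' Count annotated exon loci inside a skip junction
#'
#' Counts overlap-clusters of annotated exons fully contained in the
#' spliced-out interval, so that isoform-to-isoform variation of one
#' exon's boundaries still counts as a single skipped locus. Identical
#' intervals shared by transcripts are counted once by construction.
#'
#' @param index a `junction_index`.
#' @param chrom,strand location of the junction.
#' @param junction_start,junction_end the skip junction (0-based
#'   half-open spliced-out interval).
#' @param per_interval count distinct contained intervals instead of
#'   overlap clusters.
#' @return non-negative integer.
#' @export
count_intervening_exons <- function(index, chrom, strand, junction_start,
                                    junction_end, per_interval = FALSE) {
  if (junction_end <= junction_start)
    stop_fmt("degenerate skip junction [%s,%s)",
             format(junction_start, scientific = FALSE),
             format(junction_end, scientific = FALSE))
  hits <- exons_within(index, chrom, strand, junction_start, junction_end)
  if (length(hits) == 0L) return(0L)
  if (per_interval) return(length(hits))
  length(GenomicRanges::reduce(hits, ignore.strand = FALSE))
}

#' Multi-exon skipping distribution
#'
#' Tabulates, for each significant SE event, the number of annotated
#' intervening exon loci inside its skip junction, and summarizes the
#' distribution in bins 0 / 1 / 2 / 3 / >=4 (a typical single-exon event
#' falls in bin 1: the skipped exon itself is an annotated locus).
#'
#' @param events significant SE `splice_events`.
#' @param index a `junction_index`.
#' @param sign restrict to one inclusion-difference sign (default
#'   `"negative"`, increased skipping).
#' @inheritParams count_intervening_exons
#' @return list of class `skip_summary` with `records` (per event) and
#'   `histogram` (named counts summing to the event count).
#' @export
number_skipped_summary <- function(events, index,
                                   sign = c("negative", "positive", "both"),
                                   per_interval = FALSE) {
  sign <- match.arg(sign)
  v <- se_view(events)
  if (sign != "both")
    v <- v[sign_class(v$inc_diff) == sign, , drop = FALSE]
  n <- vapply(seq_len(nrow(v)), function(i)
    count_intervening_exons(index, v$chrom[i], v$strand[i],
                            v$left_ee[i], v$right_es[i],
                            per_interval = per_interval), integer(1))
  records <- data.frame(event_key = v$event_key,
                        gene_symbol = v$gene_symbol,
                        sign = sign_class(v$inc_diff),
                        n_intervening = if (nrow(v)) n else integer(0),
                        stringsAsFactors = FALSE)
  bins <- c("0" = sum(n == 0), "1" = sum(n == 1), "2" = sum(n == 2),
            "3" = sum(n == 3), ">=4" = sum(n >= 4))
  out <- list(records = records, histogram = bins)
  class(out) <- "skip_summary"
  out
}

se_sizes_of <- function(v) {
  minus <- v$strand == "-"
  left_exon <- v$left_ee - v$left_es
  right_exon <- v$right_ee - v$right_es
  left_intron <- v$exon_start - v$left_ee
  right_intron <- v$right_es - v$exon_end
  data.frame(
    upstream_exon_len = ifelse(minus, right_exon, left_exon),
    upstream_intron_len = ifelse(minus, right_intron, left_intron),
    skipped_exon_len = v$exon_end - v$exon_start,
    downstream_intron_len = ifelse(minus, left_intron, right_intron),
    downstream_exon_len = ifelse(minus, left_exon, right_exon))
}

size_means <- function(sz) {
  if (nrow(sz) == 0L)
    return(stats::setNames(rep(NA_real_, ncol(sz)), colnames(sz)))
  colMeans(sz)
}

#' Intron and exon sizes of SE events
#'
#' Per-event sizes (in nt, transcript-oriented labels: on the minus
#' strand the genomic-left flank is the downstream exon) of the upstream
#' exon, upstream intron, skipped exon, downstream intron and downstream
#' exon, with per-sign means and the annotated-transcriptome baseline.
#'
#' @param events significant SE `splice_events`.
#' @param baseline_triples output of [annotated_se_triples()], or `NULL`
#'   to skip the baseline.
#' @return list of class `size_summary` with `records`, `summary`
#'   (per-sign means) and `baseline` (annotated means or `NULL`).
#' @export
se_intron_exon_sizes <- function(events, baseline_triples = NULL) {
  v <- se_view(events)
  sz <- se_sizes_of(v)
  records <- cbind(data.frame(event_key = v$event_key,
                              gene_symbol = v$gene_symbol,
                              sign = sign_class(v$inc_diff),
                              stringsAsFactors = FALSE), sz)
  summary <- do.call(rbind, lapply(c("negative", "positive"), function(s) {
    m <- size_means(sz[records$sign == s, , drop = FALSE])
    cbind(data.frame(sign = s, n_events = sum(records$sign == s)),
          as.data.frame(as.list(m)))
  }))
  baseline <- NULL
  if (!is.null(baseline_triples) && nrow(baseline_triples)) {
    bsz <- se_sizes_of(baseline_triples)
    baseline <- cbind(data.frame(sign = "annotated",
                                 n_events = nrow(bsz)),
                      as.data.frame(as.list(size_means(bsz))))
  }
  out <- list(records = records, summary = summary, baseline = baseline)
  class(out) <- "size_summary"
  out
}

ri_sizes_of <- function(v) {
  minus <- v$strand == "-"
  left_exon <- v$left_ee - v$left_es
  right_exon <- v$right_ee - v$right_es
  data.frame(
    upstream_exon_len = ifelse(minus, right_exon, left_exon),
    retained_intron_len = v$intron_end - v$intron_start,
    downstream_exon_len = ifelse(minus, left_exon, right_exon))
}

#' Intron and exon sizes of RI events
#'
#' @param events significant RI `splice_events`.
#' @param baseline_introns output of [annotated_introns()], or `NULL`.
#' @return list of class `size_summary` (upstream exon, retained intron,
#'   downstream exon lengths).
#' @export
ri_intron_exon_sizes <- function(events, baseline_introns = NULL) {
  v <- ri_view(events)
  sz <- ri_sizes_of(v)
  records <- cbind(data.frame(event_key = v$event_key,
                              gene_symbol = v$gene_symbol,
                              sign = sign_class(v$inc_diff),
                              stringsAsFactors = FALSE), sz)
  summary <- do.call(rbind, lapply(c("negative", "positive"), function(s) {
    m <- size_means(sz[records$sign == s, , drop = FALSE])
    cbind(data.frame(sign = s, n_events = sum(records$sign == s)),
          as.data.frame(as.list(m)))
  }))
  baseline <- NULL
  if (!is.null(baseline_introns) && nrow(baseline_introns)) {
    bsz <- ri_sizes_of(baseline_introns)
    baseline <- cbind(data.frame(sign = "annotated", n_events = nrow(bsz)),
                      as.data.frame(as.list(size_means(bsz))))
  }
  out <- list(records = records, summary = summary, baseline = baseline)
  class(out) <- "size_summary"
  out
}

# BED6 of unannotated junctions; score = -10*log10(FDR) capped at 3000
write_unannotated_bed <- function(status, path) {
  un <- status$unannotated
  score <- pmin(round(-10 * log10(pmax(un$fdr, 1e-300))), 3000)
  lines <- paste(un$chrom,
                 format(un$junction_start, scientific = FALSE, trim = TRUE),
                 format(un$junction_end, scientific = FALSE, trim = TRUE),
                 un$gene_symbol, score, un$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
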