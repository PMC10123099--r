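#' Skipped-isoform translation and NMD prediction
#'
#' For every significant skipped-exon event, finds annotated transcripts
#' that express the inclusion isoform (both flanking introns present in
#' the transcript's intron chain), deletes the skipped exon from the
#' representative host, translates the resulting isoform, classifies the
#' reading-frame effect, and applies the 50-nt rule: an isoform whose
#' translation terminates more than 50 nt upstream of its final
#' exon-exon junction is a nonsense-mediated decay (NMD) candidate.
#' Frameshifted isoforms additionally yield the novel C-terminal peptide
#' ("neopeptide") read in the shifted frame; in-frame events yield the
#' excised peptide encoded by the removed coding interval.
#'
#' @name translate_nmd
NULL

tx_oriented_exons <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

tx_length <- function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"])

#' Spliced transcript sequence
#'
#' Concatenated exon sequence in transcript (5' to 3') orientation.
#'
#' @param tx a transcript model.
#' @param genome a `genome_seq`.
#' @export
transcript_sequence <- function(tx, genome) {
  ex <- tx_oriented_exons(tx)
  parts <- vapply(seq_len(nrow(ex)), function(i)
    fetch_sequence(genome, tx$chrom, ex[i, "start"], ex[i, "end"],
                   tx$strand), character(1))
  paste(parts, collapse = "")
}

# 0-based transcript coordinate of a 0-based genomic base, or NA when
# the base is not exonic
genomic_to_tx <- function(tx, gpos) {
  ex <- tx_oriented_exons(tx)
  off <- 0
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, "end"] - ex[i, "start"]
    if (gpos >= ex[i, "start"] && gpos < ex[i, "end"]) {
      within <- if (tx$strand == "+") gpos - ex[i, "start"]
                else ex[i, "end"] - 1 - gpos
      return(off + within)
    }
    off <- off + w
  }
  NA_real_
}

cds_start_gpos <- function(tx) {
  if (is.null(tx$cds)) return(NA_real_)
  if (tx$strand == "+") tx$cds[1L] else tx$cds[2L] - 1
}

tx_cds_len <- function(tx) {
  if (is.null(tx$cds)) return(0)
  sum(pmax(0, pmin(tx$exons[, "end"], tx$cds[2L]) -
             pmax(tx$exons[, "start"], tx$cds[1L])))
}

build_host_index <- function(transcripts) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(transcripts)) {
    intr <- tx_introns(transcripts[[i]])
    if (is.null(intr)) next
    keys <- intron_key(transcripts[[i]]$chrom, transcripts[[i]]$strand,
                       intr[, "start"], intr[, "end"])
    for (k in keys) assign(k, c(env[[k]], i), envir = env)
  }
  env
}

#' Find host transcripts for SE events
#'
#' A transcript hosts an event when its intron chain contains both
#' flanking introns of the inclusion isoform (upstream-exon end to
#' skipped-exon start, and skipped-exon end to downstream-exon start).
#'
#' @param events SE `splice_events`.
#' @param transcripts a `transcript_set`.
#' @return data frame with one row per (event, host) match: `event_key`,
#'   `transcript_id`, `cds_len`. Events without a match do not appear.
#' @export
find_hosts <- function(events, transcripts) {
  v <- se_view(events)
  idx <- build_host_index(transcripts)
  out <- list()
  for (i in seq_len(nrow(v))) {
    k1 <- intron_key(v$chrom[i], v$strand[i], v$left_ee[i], v$exon_start[i])
    k2 <- intron_key(v$chrom[i], v$strand[i], v$exon_end[i], v$right_es[i])
    hit <- intersect(idx[[k1]], idx[[k2]])
    if (length(hit) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      event_key = v$event_key[i],
      transcript_id = vapply(hit, function(j)
        transcripts[[j]]$transcript_id, character(1)),
      tx_index = hit,
      cds_len = vapply(hit, function(j) tx_cds_len(transcripts[[j]]),
                       numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(event_key = character(0),
                      transcript_id = character(0), tx_index = integer(0),
                      cds_len = numeric(0)))
  do.call(rbind, out)
}

#' Delete the skipped exon from a host transcript
#'
#' @param host a transcript model whose exon chain contains the exact
#'   interval `[exon_start, exon_end)`.
#' @param exon_start,exon_end skipped exon, 0-based half-open genomic.
#' @return the skipped-isoform transcript model (CDS span inherited).
#' @export
build_skipped_isoform <- function(host, exon_start, exon_end) {
  hit <- which(host$exons[, "start"] == exon_start &
                 host$exons[, "end"] == exon_end)
  if (length(hit) != 1L)
    stop_fmt("transcript %s has no exact exon [%s,%s)", host$transcript_id,
             format(exon_start, scientific = FALSE),
             format(exon_end, scientific = FALSE))
  iso <- host
  iso$exons <- host$exons[-hit, , drop = FALSE]
  iso
}

#' The 50-nt NMD rule
#'
#' An isoform is an NMD candidate when its translation terminates more
#' than 50 nt upstream of its final exon-exon junction: strictly
#' `last_junction_tx_pos - ptc_tx_pos > 50`, with both positions in
#' 1-based transcript coordinates and the termination codon located at
#' its last base. Stops in the final exon (negative distance) or at most
#' 50 nt upstream of the junction are not candidates.
#'
#' @param ptc_tx_pos transcript position of the last base of the
#'   termination codon (`NA` when translation runs off the transcript).
#' @param last_junction_tx_pos transcript position of the last base
#'   before the final exon-exon junction.
#' @return logical vector.
#' @export
classify_nmd <- function(ptc_tx_pos, last_junction_tx_pos) {
  !is.na(ptc_tx_pos) & (last_junction_tx_pos - ptc_tx_pos) > 50
}

translate_cds <- function(cds_seq) {
  n <- 3L * (nchar(cds_seq) %/% 3L)
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_seq, 1L, n))))
}

#' Translate a skipped isoform and classify its outcome
#'
#' @param iso the skipped isoform from [build_skipped_isoform()].
#' @param host the host transcript model.
#' @param exon_start,exon_end the skipped exon (genomic).
#' @param genome a `genome_seq`.
#' @return list of class `isoform_outcome`: `region` (one of
#'   `cds_overlap`, `utr5_only`, `utr3_only`, `noncoding`),
#'   `frame_class` (`in_frame`, `frameshift`, `not_applicable`),
#'   `removed_coding_len`, `protein`, `host_protein`, `ptc_tx_pos`,
#'   `last_junction_tx_pos`, `nmd`, `neopeptide`, `excised_peptide`,
#'   `flags`.
#' @export
translate_outcome <- function(iso, host, exon_start, exon_end, genome) {
  out <- list(transcript_id = host$transcript_id, region = "noncoding",
              frame_class = "not_applicable", removed_coding_len = 0,
              protein = "", host_protein = "", ptc_tx_pos = NA_real_,
              last_junction_tx_pos = NA_real_, nmd = FALSE,
              neopeptide = "", excised_peptide = "", flags = "")
  class(out) <- "isoform_outcome"

  ex_iso <- tx_oriented_exons(iso)
  iso_len <- tx_length(iso)
  out$last_junction_tx_pos <-
    if (nrow(ex_iso) > 1L)
      iso_len - (ex_iso[nrow(ex_iso), "end"] - ex_iso[nrow(ex_iso), "start"])
    else NA_real_

  if (is.null(host$cds)) return(out)

  rem <- max(0, min(exon_end, host$cds[2L]) - max(exon_start, host$cds[1L]))
  out$removed_coding_len <- rem
  if (rem == 0) {
    before_cds <- if (host$strand == "+") exon_end <= host$cds[1L]
                  else exon_start >= host$cds[2L]
    out$region <- if (before_cds) "utr5_only" else "utr3_only"
  } else {
    out$region <- "cds_overlap"
    out$frame_class <- if (rem %% 3 == 0) "in_frame" else "frameshift"
  }

  cds_g <- cds_start_gpos(host)
  cs_i <- genomic_to_tx(iso, cds_g)
  cs_h <- genomic_to_tx(host, cds_g)
  if (is.na(cs_i)) {
    out$flags <- "cds_start_removed"
    return(out)
  }

  iso_seq <- transcript_sequence(iso, genome)
  host_seq <- transcript_sequence(host, genome)
  iso_cds <- substr(iso_seq, cs_i + 1L, nchar(iso_seq))
  host_cds <- substr(host_seq, cs_h + 1L, nchar(host_seq))
  if (substr(iso_cds, 1L, 3L) != "ATG")
    out$flags <- paste0(out$flags, "non_atg_start;")

  aa_host <- translate_cds(host_cds)
  host_stop <- regexpr("*", aa_host, fixed = TRUE)
  out$host_protein <- if (host_stop > 0) substr(aa_host, 1L, host_stop - 1L)
                      else aa_host

  aa <- translate_cds(iso_cds)
  stop_idx <- regexpr("*", aa, fixed = TRUE)
  if (stop_idx > 0) {
    out$protein <- substr(aa, 1L, stop_idx - 1L)
    out$ptc_tx_pos <- cs_i + 3 * stop_idx   # 1-based last base of the stop
  } else {
    out$protein <- aa
    out$flags <- paste0(out$flags, "no_stop;")
  }

  out$nmd <- unname(classify_nmd(out$ptc_tx_pos, out$last_junction_tx_pos))
  if (is.na(out$nmd)) out$nmd <- FALSE

  # coding offset of the new junction: bases of the isoform preceding
  # the position where the exon was removed
  ex_host <- tx_oriented_exons(host)
  rem_ord <- which(ex_host[, "start"] == exon_start &
                     ex_host[, "end"] == exon_end)
  j0 <- if (rem_ord > 1L)
    sum(ex_host[seq_len(rem_ord - 1L), "end"] -
          ex_host[seq_len(rem_ord - 1L), "start"])
  else 0

  if (out$frame_class == "frameshift") {
    off <- j0 - cs_i
    if (off >= 0) {
      a0 <- off %/% 3
      if (a0 + 1 <= nchar(out$protein))
        out$neopeptide <- substr(out$protein, a0 + 1, nchar(out$protein))
    }
  }
  if (out$frame_class == "in_frame") {
    g0 <- if (host$strand == "+") max(exon_start, host$cds[1L])
          else min(exon_end, host$cds[2L]) - 1
    off_h <- genomic_to_tx(host, g0) - cs_h
    from <- off_h %/% 3 + 1
    to <- min(ceiling((off_h + rem) / 3), nchar(out$host_protein))
    if (from <= to)
      out$excised_peptide <- substr(out$host_protein, from, to)
  }
  out
}

outcome_row <- function(v, oc, hosted, n_hosts) {
  data.frame(
    event_key = v$event_key, gene_symbol = v$gene_symbol,
    sign = sign_class(v$inc_diff), hosted = hosted, n_hosts = n_hosts,
    transcript_id = if (hosted) oc$transcript_id else NA_character_,
    region = if (hosted) oc$region else NA_character_,
    frame_class = if (hosted) oc$frame_class else NA_character_,
    removed_coding_len = if (hosted) oc$removed_coding_len else NA_real_,
    protein = if (hosted) oc$protein else "",
    protein_len = if (hosted) nchar(oc$protein) else NA_integer_,
    host_protein_len = if (hosted) nchar(oc$host_protein) else NA_integer_,
    ptc_tx_pos = if (hosted) oc$ptc_tx_pos else NA_real_,
    last_junction_tx_pos = if (hosted) oc$last_junction_tx_pos else NA_real_,
    nmd = if (hosted) oc$nmd else NA,
    neopeptide = if (hosted) oc$neopeptide else "",
    excised_peptide = if (hosted) oc$excised_peptide else "",
    flags = if (hosted) oc$flags else "unhosted",
    stringsAsFactors = FALSE)
}

#' Run the translation / NMD analysis over significant SE events
#'
#' When several transcripts host an event, the one with the longest CDS
#' (ties broken lexicographically by transcript ID) is the
#' representative; hosts whose exon chain does not carry the skipped
#' exon as one exact exon are skipped with a warning flag. The NMD
#' fraction is reported over translatable events (hosted, coding host,
#' CDS start intact), with all counts alongside.
#'
#' @param events significant SE `splice_events`.
#' @param transcripts a `transcript_set`.
#' @param genome a `genome_seq`.
#' @param outdir optional output directory; when given, writes protein /
#'   neopeptide / excised-peptide FASTAs, a BED12 of NMD events, NMD
#'   gene lists per sign and TSV summaries.
#' @return list of class `translate_nmd_result` with `outcomes` (per
#'   event) and `summary` (per sign).
#' @export
run_translate_nmd <- function(events, transcripts, genome, outdir = NULL) {
  v <- se_view(events)
  hosts <- find_hosts(events, transcripts)
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    h <- hosts[hosts$event_key == v$event_key[i], , drop = FALSE]
    if (nrow(h) == 0L) {
      rows[[i]] <- outcome_row(v[i, ], NULL, FALSE, 0L)
      next
    }
    h <- h[order(-h$cds_len, h$transcript_id), , drop = FALSE]
    oc <- NULL
    for (j in seq_len(nrow(h))) {
      host <- transcripts[[h$tx_index[j]]]
      oc <- tryCatch({
        iso <- build_skipped_isoform(host, v$exon_start[i], v$exon_end[i])
        translate_outcome(iso, host, v$exon_start[i], v$exon_end[i], genome)
      }, error = function(e) NULL)
      if (!is.null(oc)) break
    }
    if (is.null(oc)) {
      row <- outcome_row(v[i, ], NULL, FALSE, nrow(h))
      row$flags <- "host_exon_mismatch"
      rows[[i]] <- row
    } else {
      rows[[i]] <- outcome_row(v[i, ], oc, TRUE, nrow(h))
    }
  }
  outcomes <- if (nrow(v)) do.call(rbind, rows) else data.frame(
    event_key = character(0), gene_symbol = character(0),
    sign = character(0), hosted = logical(0), n_hosts = integer(0),
    transcript_id = character(0), region = character(0),
    frame_class = character(0), removed_coding_len = numeric(0),
    protein = character(0), protein_len = integer(0),
    host_protein_len = integer(0), ptc_tx_pos = numeric(0),
    last_junction_tx_pos = numeric(0), nmd = logical(0),
    neopeptide = character(0), excised_peptide = character(0),
    flags = character(0), stringsAsFactors = FALSE)

  translatable <- outcomes$hosted & !is.na(outcomes$region) &
    outcomes$region != "noncoding" & !grepl("cds_start_removed",
                                            outcomes$flags)
  summary <- do.call(rbind, lapply(c("negative", "positive"), function(s) {
    sub <- outcomes$sign == s
    tr <- sub & translatable
    n_tr <- sum(tr)
    data.frame(
      sign = s, n_events = sum(sub), n_hosted = sum(sub & outcomes$hosted),
      n_translatable = n_tr,
      n_frameshift = sum(tr & outcomes$frame_class == "frameshift",
                         na.rm = TRUE),
      n_in_frame = sum(tr & outcomes$frame_class == "in_frame",
                       na.rm = TRUE),
      n_nmd = sum(tr & outcomes$nmd, na.rm = TRUE),
      fraction_nmd = if (n_tr) sum(tr & outcomes$nmd, na.rm = TRUE) / n_tr
                     else NA_real_,
      n_neopeptides_gt12 = sum(nchar(outcomes$neopeptide[tr]) > 12))
  }))

  res <- list(outcomes = outcomes, summary = summary)
  class(res) <- "translate_nmd_result"
  if (!is.null(outdir)) write_translate_nmd(res, v, outdir)
  res
}

fasta_write <- function(seqs, headers, path) {
  keep <- nchar(seqs) > 0
  ss <- Biostrings::AAStringSet(seqs[keep])
  names(ss) <- headers[keep]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

write_translate_nmd <- function(res, v, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  oc <- res$outcomes
  hdr <- function(kind, len) paste(oc$gene_symbol, oc$transcript_id,
                                   oc$event_key, kind, len, sep = "|")
  fasta_write(oc$protein, hdr(oc$frame_class, nchar(oc$protein)),
              file.path(outdir, "protein_isoforms.fa"))
  fasta_write(oc$neopeptide, hdr("neopeptide", nchar(oc$neopeptide)),
              file.path(outdir, "neopeptides.fa"))
  fasta_write(oc$excised_peptide,
              hdr("excised_peptide", nchar(oc$excised_peptide)),
              file.path(outdir, "excised_peptides.fa"))
  nmd <- which(!is.na(oc$nmd) & oc$nmd)
  bed <- vapply(nmd, function(i) {
    r <- v[v$event_key == oc$event_key[i], ][1, ]
    starts <- c(r$left_es, r$exon_start, r$right_es)
    ends <- c(r$left_ee, r$exon_end, r$right_ee)
    paste(r$chrom, format(starts[1], scientific = FALSE),
          format(ends[3], scientific = FALSE),
          paste0(oc$gene_symbol[i], "|", oc$event_key[i]), 0, r$strand,
          format(starts[1], scientific = FALSE),
          format(ends[3], scientific = FALSE), "0", 3,
          paste0(paste(format(ends - starts, scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          paste0(paste(format(starts - starts[1], scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(bed, file.path(outdir, "nmd_events.bed"))
  for (s in c("negative", "positive")) {
    genes <- sort(unique(oc$gene_symbol[!is.na(oc$nmd) & oc$nmd &
                                          oc$sign == s]))
    writeLines(genes, file.path(outdir, sprintf("nmd_genes_%s.txt", s)))
  }
  write_tsv(oc[, setdiff(names(oc), c("protein"))],
            file.path(outdir, "outcomes.tsv"))
  write_tsv(res$summary, file.path(outdir, "summary.tsv"))
  invisible(outdir)
}
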