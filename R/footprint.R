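#' Transcriptome footprint of splicing changes
#'
#' What fraction of the expressed transcriptome carries significant
#' splicing changes? A gene is "expressed" at a TPM threshold when its
#' control-condition TPM (mean over control replicates by default) is at
#' least the threshold; it carries a change when at least one significant
#' event of the requested sign maps to its symbol.
#'
#' @name footprint
NULL

#' Read a gene expression table
#'
#' Expects gene IDs in the first column followed by TPM columns, control
#' conditions first then test conditions. A header line is auto-detected
#' (non-numeric second field on line 1). Duplicate gene IDs keep the row
#' with the largest control mean, with a warning.
#'
#' @param path tab-separated expression file.
#' @param n_control number of control TPM columns (required).
#' @param n_test number of test TPM columns; default all remaining.
#' @return list of class `expression_table` with `gene_id`, `control`
#'   (matrix), `test` (matrix) and `control_mean`.
#' @export
read_expression <- function(path, n_control, n_test = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_fmt("%s: empty expression file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_data <- 1L
  if (length(fields[[1L]]) >= 2L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][2L]))))
    first_data <- 2L
  if (first_data > length(fields))
    stop_fmt("%s: header only, no expression rows", path)
  rows <- fields[seq.int(first_data, length(fields))]
  ncol_vals <- length(rows[[1L]]) - 1L
  if (n_control < 1L || n_control > ncol_vals)
    stop_fmt("n_control=%d impossible with %d TPM columns", n_control,
             ncol_vals)
  n_test <- n_test %||% (ncol_vals - n_control)
  genes <- vapply(rows, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncol_vals)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != ncol_vals + 1L)
      stop_fmt("%s: line %d has %d columns, expected %d", path,
               i + first_data - 1L, length(f), ncol_vals + 1L)
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v))
      stop_fmt("%s: line %d: non-numeric TPM value", path,
               i + first_data - 1L)
    vals[i, ] <- v
  }
  if (any(vals < 0)) stop_fmt("%s: negative TPM value", path)
  ctrl <- vals[, seq_len(n_control), drop = FALSE]
  test <- vals[, seq.int(n_control + 1L, length.out = n_test), drop = FALSE]
  cmean <- rowMeans(ctrl)
  if (anyDuplicated(genes)) {
    ord <- order(-cmean)
    keep <- sort(ord[!duplicated(genes[ord])])
    warn_fmt("%s: %d duplicate gene row(s) dropped (largest control mean kept)",
             path, length(genes) - length(keep))
    genes <- genes[keep]; ctrl <- ctrl[keep, , drop = FALSE]
    test <- test[keep, , drop = FALSE]; cmean <- cmean[keep]
  }
  out <- list(gene_id = genes, control = ctrl, test = test,
              control_mean = cmean)
  class(out) <- "expression_table"
  out
}

#' Fraction of expressed genes with significant splicing changes
#'
#' @param events significant `splice_events` (filter with
#'   [filter_significant()] first, or pass `fdr_threshold` to filter
#'   here).
#' @param expr an `expression_table`.
#' @param min_tpms TPM thresholds to evaluate (default `c(1, 2, 3, 5)`).
#' @param sign which inclusion-difference sign counts as a change.
#' @param fdr_threshold optional; when given, events are
#'   significance-filtered internally.
#' @param all_replicates require every control replicate at or above the
#'   threshold instead of the control mean.
#' @return list of class `footprint_summary`: `summary` (one row per
#'   threshold: `min_tpm`, `sign`, `expressed_gene_count`,
#'   `as_gene_count`, `fraction`), `gene_events` (per-gene event
#'   listing), `unmatched_genes` (event genes absent from the expression
#'   table, excluded from the fraction).
#' @export
fraction_expressed <- function(events, expr, min_tpms = c(1, 2, 3, 5),
                               sign = c("negative", "positive", "both"),
                               fdr_threshold = NULL,
                               all_replicates = FALSE) {
  sign <- match.arg(sign)
  if (!inherits(expr, "expression_table") || length(expr$gene_id) == 0L)
    stop_fmt("empty or invalid expression table")
  if (length(min_tpms) == 0L) stop_fmt("min_tpms must be non-empty")
  if (!is.null(fdr_threshold))
    events <- filter_significant(events, fdr_threshold, sign)
  else if (sign != "both")
    events <- events[if (sign == "negative") events$inc_diff < 0
                     else events$inc_diff > 0, , drop = FALSE]
  as_genes <- unique(events$gene_symbol)
  matched <- intersect(as_genes, expr$gene_id)
  unmatched <- setdiff(as_genes, expr$gene_id)
  level <- if (all_replicates) apply(expr$control, 1L, min)
           else expr$control_mean
  summary <- do.call(rbind, lapply(min_tpms, function(t) {
    expressed <- expr$gene_id[level >= t]
    as_expr <- intersect(matched, expressed)
    data.frame(min_tpm = t, sign = sign,
               expressed_gene_count = length(expressed),
               as_gene_count = length(as_expr),
               fraction = if (length(expressed)) length(as_expr) /
                 length(expressed) else NA_real_)
  }))
  ge <- events[events$gene_symbol %in% matched,
               c("gene_symbol", "as_type", "chrom", "strand", "fdr",
                 "inc_diff"), drop = FALSE]
  if (nrow(ge)) {
    ge$event_key <- event_key(events[events$gene_symbol %in% matched, ,
                                     drop = FALSE])
    ge$control_tpm <- level[match(ge$gene_symbol, expr$gene_id)]
  }
  out <- list(summary = summary, gene_events = ge,
              unmatched_genes = unmatched)
  class(out) <- "footprint_summary"
  out
}

write_footprint <- function(fp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(fp$summary, file.path(outdir, "fraction_expressed_summary.tsv"))
  write_tsv(fp$gene_events, file.path(outdir, "gene_event_listing.tsv"))
  writeLines(fp$unmatched_genes, file.path(outdir, "unmatched_genes.txt"))
  invisible(outdir)
}
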