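#' Aggregate drivers
#'
#' One-command drivers that run the full skipped-exon or retained-intron
#' tool set over a single experiment, and a batch driver over a
#' directory of suffix-conforming experiments. Tools whose inputs are
#' missing are skipped with a logged reason; each run writes a manifest
#' with parameters and input checksums so results are reproducible.
#'
#' @name medley
NULL

run_manifest <- function(outdir, params, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  sums <- vapply(unlist(inputs), function(p)
    unname(tools::md5sum(p)), character(1))
  lines <- c(sprintf("package_version\t%s",
                     as.character(utils::packageVersion("splicedown"))),
             sprintf("%s\t%s", names(params), vapply(params, as.character,
                                                     character(1))),
             sprintf("md5_%s\t%s", names(sums), sums))
  writeLines(lines, file.path(outdir, "run_manifest.tsv"))
}

prepare_outdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !force)
    stop_fmt("output directory %s is not empty (use force = TRUE)", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
}

#' Run all skipped-exon tools
#'
#' Runs, over one SE JCEC file: fraction-expressed (when an expression
#' table is given), unannotated-junction classification, multi-exon
#' skipping counts, intron/exon sizes, splice-site scoring and the
#' translation/NMD analysis. Outputs land under `outdir/<tool>/`.
#'
#' @param se_file SE JCEC path.
#' @param annotation BED12 path.
#' @param genome genome FASTA path.
#' @param expression optional expression TSV path.
#' @param outdir output directory (refused when non-empty unless
#'   `force`).
#' @param fdr_threshold significance threshold.
#' @param min_tpms expression thresholds for the footprint tool.
#' @param n_control control columns in the expression table.
#' @param flip_sign negate inclusion differences at parse time.
#' @param force overwrite a non-empty output directory.
#' @return (invisibly) named list of tool results.
#' @export
se_medley <- function(se_file, annotation, genome, expression = NULL,
                      outdir, fdr_threshold = 0.0005,
                      min_tpms = c(1, 2, 3, 5), n_control = 2L,
                      flip_sign = FALSE, force = FALSE) {
  for (p in c(se_file, annotation, genome))
    if (!file.exists(p)) stop_fmt("input not found: %s", p)
  prepare_outdir(outdir, force)
  events <- read_rmats(se_file, "SE", flip_sign = flip_sign)
  sig <- filter_significant(events, fdr_threshold)
  txs <- read_bed12(annotation)
  idx <- build_junction_index(txs)
  gen <- load_genome(genome)
  triples <- annotated_se_triples(txs)
  results <- list()

  if (!is.null(expression)) {
    expr <- read_expression(expression, n_control = n_control)
    for (s in c("negative", "positive")) {
      fp <- fraction_expressed(sig, expr, min_tpms, sign = s)
      write_footprint(fp, file.path(outdir, "fraction_expressed", s))
      results[[paste0("fraction_expressed_", s)]] <- fp
    }
  }

  ann <- classify_annotation(sig, idx)
  dir.create(file.path(outdir, "unannotated"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv(ann$summary, file.path(outdir, "unannotated", "summary.tsv"))
  write_tsv(ann$status, file.path(outdir, "unannotated", "status.tsv"))
  write_unannotated_bed(ann, file.path(outdir, "unannotated",
                                       "unannotated_junctions.bed"))
  results$unannotated <- ann

  dir.create(file.path(outdir, "number_skipped"), showWarnings = FALSE)
  for (s in c("negative", "positive")) {
    ns <- number_skipped_summary(sig, idx, sign = s)
    write_tsv(ns$records, file.path(outdir, "number_skipped",
                                    sprintf("records_%s.tsv", s)))
    write_tsv(data.frame(bin = names(ns$histogram),
                         count = as.integer(ns$histogram)),
              file.path(outdir, "number_skipped",
                        sprintf("histogram_%s.tsv", s)))
    results[[paste0("number_skipped_", s)]] <- ns
  }

  sz <- se_intron_exon_sizes(sig, triples)
  dir.create(file.path(outdir, "intron_exon_sizes"), showWarnings = FALSE)
  write_tsv(sz$records, file.path(outdir, "intron_exon_sizes",
                                  "records.tsv"))
  write_tsv(rbind(sz$summary,
                  if (!is.null(sz$baseline)) sz$baseline),
            file.path(outdir, "intron_exon_sizes", "summary.tsv"))
  results$sizes <- sz

  sc <- score_event_sites(sig, gen, baseline = triples)
  dir.create(file.path(outdir, "splice_site_scores"), showWarnings = FALSE)
  write_tsv(sc$records, file.path(outdir, "splice_site_scores",
                                  "records.tsv"))
  write_tsv(sc$means, file.path(outdir, "splice_site_scores", "means.tsv"))
  write_tsv(sc$ratio, file.path(outdir, "splice_site_scores", "ratio.tsv"))
  if (!is.null(sc$baseline_means))
    write_tsv(sc$baseline_means,
              file.path(outdir, "splice_site_scores", "baseline_means.tsv"))
  results$site_scores <- sc

  results$translate_nmd <- run_translate_nmd(
    sig, txs, gen, outdir = file.path(outdir, "translate_nmd"))

  run_manifest(outdir,
               list(tool = "se_medley", fdr_threshold = fdr_threshold,
                    min_tpms = paste(min_tpms, collapse = ","),
                    flip_sign = flip_sign),
               list(se = se_file, annotation = annotation, genome = genome,
                    expression = expression))
  invisible(results)
}

#' Run all retained-intron tools
#'
#' Fraction-expressed (when an expression table is given), intron/exon
#' sizes and splice-site scoring over one RI JCEC file.
#'
#' @param ri_file RI JCEC path.
#' @inheritParams se_medley
#' @return (invisibly) named list of tool results.
#' @export
ri_medley <- function(ri_file, annotation, genome, expression = NULL,
                      outdir, fdr_threshold = 0.0005,
                      min_tpms = c(1, 2, 3, 5), n_control = 2L,
                      flip_sign = FALSE, force = FALSE) {
  for (p in c(ri_file, annotation, genome))
    if (!file.exists(p)) stop_fmt("input not found: %s", p)
  prepare_outdir(outdir, force)
  events <- read_rmats(ri_file, "RI", flip_sign = flip_sign)
  sig <- filter_significant(events, fdr_threshold)
  txs <- read_bed12(annotation)
  gen <- load_genome(genome)
  introns <- annotated_introns(txs)
  results <- list()

  if (!is.null(expression)) {
    expr <- read_expression(expression, n_control = n_control)
    for (s in c("negative", "positive")) {
      fp <- fraction_expressed(sig, expr, min_tpms, sign = s)
      write_footprint(fp, file.path(outdir, "fraction_expressed", s))
      results[[paste0("fraction_expressed_", s)]] <- fp
    }
  }

  sz <- ri_intron_exon_sizes(sig, introns)
  dir.create(file.path(outdir, "intron_exon_sizes"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv(sz$records, file.path(outdir, "intron_exon_sizes",
                                  "records.tsv"))
  write_tsv(rbind(sz$summary, if (!is.null(sz$baseline)) sz$baseline),
            file.path(outdir, "intron_exon_sizes", "summary.tsv"))
  results$sizes <- sz

  sc <- score_event_sites(sig, gen, baseline = introns)
  dir.create(file.path(outdir, "splice_site_scores"), showWarnings = FALSE)
  write_tsv(sc$records, file.path(outdir, "splice_site_scores",
                                  "records.tsv"))
  write_tsv(sc$means, file.path(outdir, "splice_site_scores", "means.tsv"))
  results$site_scores <- sc

  run_manifest(outdir,
               list(tool = "ri_medley", fdr_threshold = fdr_threshold,
                    flip_sign = flip_sign),
               list(ri = ri_file, annotation = annotation, genome = genome,
                    expression = expression))
  invisible(results)
}

#' Batch medley runs over an experiment directory
#'
#' Finds every `"<experiment>_SE.MATS.JCEC.txt"` /
#' `"<experiment>_RI.MATS.JCEC.txt"` in a directory, runs the matching
#' medley per experiment into `outdir/<experiment>/`, and writes a
#' cross-experiment summary. Experiments whose files fail to parse are
#' skipped and listed in `skip_report.tsv`.
#'
#' @param dir input directory of suffix-conforming JCEC files.
#' @inheritParams se_medley
#' @return (invisibly) list with `results` per experiment and `skipped`.
#' @export
batch_medley <- function(dir, annotation, genome, expression = NULL,
                         outdir, fdr_threshold = 0.0005,
                         min_tpms = c(1, 2, 3, 5), n_control = 2L,
                         force = FALSE) {
  if (!dir.exists(dir)) stop_fmt("no such directory: %s", dir)
  se_files <- list.files(dir, pattern = "_SE\\.MATS\\.JCEC\\.txt$",
                         full.names = TRUE)
  ri_files <- list.files(dir, pattern = "_RI\\.MATS\\.JCEC\\.txt$",
                         full.names = TRUE)
  if (length(se_files) + length(ri_files) == 0L)
    stop_fmt("%s: no suffix-conforming JCEC files", dir)
  prepare_outdir(outdir, force)
  results <- list(); skipped <- character(0); summary_rows <- list()
  run_one <- function(f, kind) {
    name <- sub(sprintf("_%s\\.MATS\\.JCEC\\.txt$", kind), "", basename(f))
    res <- tryCatch({
      if (kind == "SE")
        se_medley(f, annotation, genome, expression,
                  outdir = file.path(outdir, name, "SE"),
                  fdr_threshold = fdr_threshold, min_tpms = min_tpms,
                  n_control = n_control, force = force)
      else
        ri_medley(f, annotation, genome, expression,
                  outdir = file.path(outdir, name, "RI"),
                  fdr_threshold = fdr_threshold, min_tpms = min_tpms,
                  n_control = n_control, force = force)
    }, error = function(e) {
      warn_fmt("skipping %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      skipped <<- c(skipped, basename(f))
    } else {
      results[[paste(name, kind, sep = "_")]] <<- res
      ev <- read_rmats(f, kind)
      sig <- filter_significant(ev, fdr_threshold)
      summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
        experiment = name, as_type = kind, n_tested = nrow(ev),
        n_sig_negative = sum(sig$inc_diff < 0),
        n_sig_positive = sum(sig$inc_diff > 0))
    }
  }
  for (f in se_files) run_one(f, "SE")
  for (f in ri_files) run_one(f, "RI")
  if (length(summary_rows))
    write_tsv(do.call(rbind, summary_rows),
              file.path(outdir, "batch_summary.tsv"))
  write_tsv(data.frame(skipped_file = skipped),
            file.path(outdir, "skip_report.tsv"))
  invisible(list(results = results, skipped = skipped))
}
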