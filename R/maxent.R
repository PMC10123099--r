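#' Maximum-entropy splice-site scoring
#'
#' Donor (5', 9-mer: 3 exonic + 6 intronic bases) and acceptor (3',
#' 23-mer: 20 intronic + 3 exonic bases) splice sites are scored as
#' log2 likelihood ratios (bits) of a maximum-entropy sequence model
#' against a background base composition.
#'
#' The model machinery follows the classic maximum-entropy splice-site
#' decomposition: the near-invariant GT (donor positions +1/+2) and AG
#' (acceptor intron positions -2/-1) are scored by consensus frequency
#' ratios, the remaining donor positions by a joint probability-ratio
#' table over all 4^7 variable sequences, and the 21 variable acceptor
#' positions by a product/quotient combination of nine overlapping
#' sub-models. The tables shipped with this package are synthetic: they
#' are expanded from compact position-marginal frequency matrices shaped
#' on canonical human splice-site composition (a maximum-entropy model
#' constrained on marginals only), because the original trained tables
#' are not redistributable here. Scores are therefore internally
#' consistent and rank sites sensibly, but are not numerically
#' comparable to scores from the published trained models.
#'
#' @name maxent
NULL

BASES <- c("A", "C", "G", "T")

# synthetic position marginals, shaped on canonical human donor site
# composition; columns are positions -3..+6 across the exon|intron boundary
donor_marginal_freqs <- function() {
  m <- matrix(c(
    # A     C     G     T
    0.33, 0.36, 0.19, 0.12,   # -3
    0.60, 0.13, 0.13, 0.14,   # -2
    0.08, 0.03, 0.81, 0.08,   # -1
    0.0034, 0.0030, 0.9903, 0.0033,  # +1 (G consensus)
    0.0027, 0.0015, 0.0009, 0.9949,  # +2 (T consensus)
    0.52, 0.03, 0.42, 0.03,   # +3
    0.71, 0.08, 0.12, 0.09,   # +4
    0.06, 0.04, 0.84, 0.06,   # +5
    0.17, 0.19, 0.20, 0.44),  # +6
    nrow = 4, dimnames = list(BASES, NULL))
  m / rep(colSums(m), each = 4)
}

# acceptor: intron positions -20..-1 then 3 exonic bases; pyrimidine
# tract over -20..-5, branch-adjacent -4..-3, invariant AG at -2/-1
acceptor_marginal_freqs <- function() {
  tract <- c(0.09, 0.31, 0.12, 0.48)
  cols <- c(rep(list(tract), 15),
            list(c(0.09, 0.33, 0.09, 0.49)),   # -5
            list(c(0.24, 0.30, 0.21, 0.25)),   # -4
            list(c(0.06, 0.64, 0.01, 0.29)),   # -3
            list(c(0.9965, 0.0012, 0.0012, 0.0011)),  # -2 (A)
            list(c(0.0008, 0.0008, 0.9975, 0.0009)),  # -1 (G)
            list(c(0.24, 0.14, 0.52, 0.10)),   # +1 exonic
            list(c(0.31, 0.24, 0.23, 0.22)),   # +2
            list(c(0.23, 0.26, 0.31, 0.20)))   # +3
  m <- do.call(cbind, cols)
  dimnames(m) <- list(BASES, NULL)
  m / rep(colSums(m), each = 4)
}

background_freqs <- function() c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)

# acceptor sub-model segments: indices into the 21 variable positions
# (the 23-mer minus the invariant AG); score multiplies segments 1-5 and
# divides by the overlap corrections 6-9
acceptor_segments <- function() {
  list(1:7, 8:14, 15:21, 5:11, 12:18, 5:7, 8:11, 12:14, 15:18)
}

seq_codes <- function(seq) {
  codes <- match(strsplit(seq, "")[[1L]], BASES) - 1L
  codes
}

table_index <- function(codes) {
  L <- length(codes)
  1L + sum(codes * 4^(seq.int(L - 1L, 0L)))
}

# joint probability-ratio table over the given positions: entry for a
# sequence s is prod_i m[s_i, pos_i] / bg[s_i]; first position is the
# most significant digit of the table index
build_ratio_table <- function(marginals, bg, positions) {
  L <- length(positions)
  t <- rep(1, 4^L)
  for (i in seq_len(L)) {
    ratios <- marginals[, positions[i]] / bg
    digit <- rep(rep(0:3, each = 4^(L - i)), times = 4^(i - 1L))
    t <- t * ratios[digit + 1L]
  }
  t
}

#' Built-in splice-site models
#'
#' Expands the package's synthetic marginal frequency matrices into
#' ready-to-score donor and acceptor models.
#'
#' @return object of class `splice_site_models`.
#' @export
splice_site_models <- function() {
  bg <- background_freqs()
  dm <- donor_marginal_freqs()
  am <- acceptor_marginal_freqs()
  d_var <- setdiff(1:9, c(4L, 5L))
  a_var <- setdiff(1:23, c(19L, 20L))
  segs <- acceptor_segments()
  models <- list(
    donor = list(marginals = dm, bg = bg, cons_pos = c(4L, 5L),
                 var_pos = d_var,
                 table = build_ratio_table(dm, bg, d_var)),
    acceptor = list(marginals = am, bg = bg, cons_pos = c(19L, 20L),
                    var_pos = a_var, segments = segs,
                    tables = lapply(segs, function(s)
                      build_ratio_table(am, bg, a_var[s]))))
  class(models) <- "splice_site_models"
  models
}

#' Write splice-site model tables
#'
#' Emits the plain-text model dialect: `background.tsv`,
#' `donor_marginals.tsv`, `acceptor_marginals.tsv`, `donor_table.txt`
#' (4^7 probability ratios, one per line, first variable position most
#' significant), `acceptor_segments.tsv` and `acceptor_table_<i>.txt`.
#'
#' @param models a `splice_site_models` object.
#' @param dir output directory (created).
#' @export
write_models <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bg <- models$donor$bg
  write_tsv(data.frame(base = names(bg), freq = num_chr(unname(bg))),
            file.path(dir, "background.tsv"))
  marg_df <- function(m)
    cbind(data.frame(pos = seq_len(ncol(m))),
          as.data.frame(t(apply(m, 2, identity))))
  write_tsv(marg_df(models$donor$marginals),
            file.path(dir, "donor_marginals.tsv"))
  write_tsv(marg_df(models$acceptor$marginals),
            file.path(dir, "acceptor_marginals.tsv"))
  writeLines(num_chr(models$donor$table), file.path(dir, "donor_table.txt"))
  segs <- models$acceptor$segments
  write_tsv(data.frame(segment = seq_along(segs),
                       positions = vapply(segs, paste, character(1),
                                          collapse = ",")),
            file.path(dir, "acceptor_segments.tsv"))
  for (i in seq_along(segs))
    writeLines(num_chr(models$acceptor$tables[[i]]),
               file.path(dir, sprintf("acceptor_table_%d.txt", i)))
  invisible(dir)
}

read_marginals <- function(path, n_pos) {
  df <- utils::read.delim(path)
  m <- t(as.matrix(df[, BASES]))
  dimnames(m) <- list(BASES, NULL)
  if (ncol(m) != n_pos)
    stop_fmt("%s: expected %d positions, found %d", path, n_pos, ncol(m))
  if (any(m <= 0) || any(m > 1) ||
      any(abs(colSums(m) - 1) > 1e-6))
    stop_fmt("%s: marginal frequencies must be in (0,1] and sum to 1", path)
  m
}

read_table_file <- function(path, n_expected) {
  if (!file.exists(path)) stop_fmt("missing model table: %s", path)
  v <- as.numeric(readLines(path, warn = FALSE))
  if (length(v) != n_expected || anyNA(v) || any(v <= 0) ||
      any(!is.finite(v)))
    stop_fmt("%s: expected %d positive finite values", path, n_expected)
  v
}

#' Load splice-site models from table files
#'
#' Reads the dialect written by [write_models()]; the probability-ratio
#' tables are taken from the files as-is (not recomputed from the
#' marginals), so a loaded model scores exactly what its tables say.
#'
#' @param dir directory of model files.
#' @return a `splice_site_models` object.
#' @export
load_models <- function(dir) {
  if (!dir.exists(dir)) stop_fmt("no such model directory: %s", dir)
  bg_df <- utils::read.delim(file.path(dir, "background.tsv"))
  bg <- stats::setNames(bg_df$freq, bg_df$base)[BASES]
  if (anyNA(bg) || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6)
    stop_fmt("%s: invalid background frequencies", dir)
  dm <- read_marginals(file.path(dir, "donor_marginals.tsv"), 9L)
  am <- read_marginals(file.path(dir, "acceptor_marginals.tsv"), 23L)
  d_var <- setdiff(1:9, c(4L, 5L))
  a_var <- setdiff(1:23, c(19L, 20L))
  seg_df <- utils::read.delim(file.path(dir, "acceptor_segments.tsv"))
  segs <- lapply(strsplit(as.character(seg_df$positions), ","), as.integer)
  tables <- lapply(seq_along(segs), function(i)
    read_table_file(file.path(dir, sprintf("acceptor_table_%d.txt", i)),
                    4^length(segs[[i]])))
  models <- list(
    donor = list(marginals = dm, bg = bg, cons_pos = c(4L, 5L),
                 var_pos = d_var,
                 table = read_table_file(file.path(dir, "donor_table.txt"),
                                         4^7)),
    acceptor = list(marginals = am, bg = bg, cons_pos = c(19L, 20L),
                    var_pos = a_var, segments = segs, tables = tables))
  class(models) <- "splice_site_models"
  models
}

score_one <- function(seq, model, kind) {
  L <- if (kind == "donor") 9L else 23L
  if (nchar(seq) != L)
    stop_fmt("%s sequence must be %d nt, got %d ('%s')", kind, L,
             nchar(seq), seq)
  if (grepl("[^ACGT]", seq)) return(NA_real_)
  codes <- seq_codes(seq)
  cons <- prod(model$marginals[cbind(codes[model$cons_pos] + 1L,
                                     model$cons_pos)] /
                 model$bg[codes[model$cons_pos] + 1L])
  var_codes <- codes[model$var_pos]
  if (kind == "donor") {
    ratio <- model$table[table_index(var_codes)]
  } else {
    lk <- vapply(seq_along(model$segments), function(i)
      model$tables[[i]][table_index(var_codes[model$segments[[i]]])],
      numeric(1))
    ratio <- prod(lk[1:5]) / prod(lk[6:9])
  }
  log2(cons * ratio)
}

#' Score donor (5') splice sites
#'
#' @param seqs character vector of 9-mers (3 exonic + 6 intronic bases).
#'   Sequences containing ambiguity codes score `NA` and are excluded
#'   from downstream averages.
#' @param models a `splice_site_models` object (default: built-in).
#' @return numeric vector of scores in bits.
#' @export
score_donor <- function(seqs, models = splice_site_models()) {
  seqs <- toupper(seqs)
  vapply(seqs, score_one, numeric(1), model = models$donor,
         kind = "donor", USE.NAMES = FALSE)
}

#' Score acceptor (3') splice sites
#'
#' @param seqs character vector of 23-mers (20 intronic + 3 exonic
#'   bases).
#' @inheritParams score_donor
#' @export
score_acceptor <- function(seqs, models = splice_site_models()) {
  seqs <- toupper(seqs)
  vapply(seqs, score_one, numeric(1), model = models$acceptor,
         kind = "acceptor", USE.NAMES = FALSE)
}

# genomic windows for one SE view row, transcript-oriented roles
se_site_windows <- function(v) {
  if (v$strand == "+") {
    data.frame(
      site_role = c("upstream_donor", "skipped_acceptor", "skipped_donor",
                    "downstream_acceptor"),
      kind = c("donor", "acceptor", "donor", "acceptor"),
      start = c(v$up_ee - 3, v$exon_start - 20, v$exon_end - 3,
                v$down_es - 20),
      end = c(v$up_ee + 6, v$exon_start + 3, v$exon_end + 6, v$down_es + 3),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      site_role = c("upstream_donor", "skipped_acceptor", "skipped_donor",
                    "downstream_acceptor"),
      kind = c("donor", "acceptor", "donor", "acceptor"),
      start = c(v$up_es - 6, v$exon_end - 3, v$exon_start - 6,
                v$down_ee - 3),
      end = c(v$up_es + 3, v$exon_end + 20, v$exon_start + 3,
              v$down_ee + 20),
      stringsAsFactors = FALSE)
  }
}

ri_site_windows <- function(v) {
  if (v$strand == "+") {
    data.frame(site_role = c("ri_donor", "ri_acceptor"),
               kind = c("donor", "acceptor"),
               start = c(v$intron_start - 3, v$intron_end - 20),
               end = c(v$intron_start + 6, v$intron_end + 3),
               stringsAsFactors = FALSE)
  } else {
    data.frame(site_role = c("ri_donor", "ri_acceptor"),
               kind = c("donor", "acceptor"),
               start = c(v$intron_end - 6, v$intron_start - 3),
               end = c(v$intron_end + 3, v$intron_start + 20),
               stringsAsFactors = FALSE)
  }
}

score_view_sites <- function(view, genome, models, as_type, label) {
  recs <- list()
  for (i in seq_len(nrow(view))) {
    v <- view[i, ]
    w <- if (as_type == "SE") se_site_windows(v) else ri_site_windows(v)
    chrom_len <- unname(genome$lengths[normalize_chrom(genome, v$chrom)])
    for (j in seq_len(nrow(w))) {
      flagged <- ""
      seq <- NA_character_; score <- NA_real_
      if (w$start[j] < 0 || w$end[j] > chrom_len) {
        flagged <- "out_of_bounds"
      } else {
        seq <- fetch_sequence(genome, v$chrom, w$start[j], w$end[j],
                              v$strand)
        if (grepl("[^ACGT]", seq)) {
          flagged <- "ambiguous"
        } else {
          score <- if (w$kind[j] == "donor") score_donor(seq, models)
                   else score_acceptor(seq, models)
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        event_key = if ("event_key" %in% names(v)) v$event_key
                    else sprintf("%s_%d", label, i),
        sign = if ("inc_diff" %in% names(v)) sign_class(v$inc_diff)
               else label,
        site_role = w$site_role[j], sequence = seq, score = score,
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L)
    return(data.frame(event_key = character(0), sign = character(0),
                      site_role = character(0), sequence = character(0),
                      score = numeric(0), flagged = character(0)))
  do.call(rbind, recs)
}

#' Score splice sites of significant events
#'
#' For SE events scores the four sites of the skipping configuration
#' (upstream exon donor, skipped exon acceptor, skipped exon donor,
#' downstream exon acceptor); for RI events the donor and acceptor of
#' the retained intron. All windows are taken in transcript orientation.
#' Sites with ambiguity codes or falling off the contig are excluded
#' from the averages and counted in the `excluded` column.
#'
#' @param events significant `splice_events` (SE or RI).
#' @param genome a `genome_seq`.
#' @param models a `splice_site_models`.
#' @param baseline annotated baseline geometry ([annotated_se_triples()]
#'   for SE, [annotated_introns()] for RI), or `NULL`.
#' @return list of class `site_scores` with `records` (per site),
#'   `means` (per sign x role, in bits), `ratio` (negative/positive mean
#'   ratio per role) and `baseline_means`.
#' @export
score_event_sites <- function(events, genome, models = splice_site_models(),
                              baseline = NULL) {
  as_type <- if (nrow(events)) events$as_type[1L] else "SE"
  stopifnot(as_type %in% c("SE", "RI"))
  view <- if (as_type == "SE") se_view(events) else ri_view(events)
  records <- score_view_sites(view, genome, models, as_type, "event")
  agg <- function(df) {
    if (nrow(df) == 0L)
      return(data.frame(sign = character(0), site_role = character(0),
                        n = integer(0), excluded = integer(0),
                        mean_score = numeric(0)))
    out <- do.call(rbind, lapply(split(df, list(df$sign, df$site_role),
                                       drop = TRUE), function(g)
      data.frame(sign = g$sign[1L], site_role = g$site_role[1L],
                 n = sum(!is.na(g$score)), excluded = sum(is.na(g$score)),
                 mean_score = mean(g$score, na.rm = TRUE))))
    rownames(out) <- NULL
    out
  }
  means <- agg(records)
  roles <- unique(means$site_role)
  ratio <- do.call(rbind, lapply(roles, function(r) {
    mn <- means$mean_score[means$sign == "negative" & means$site_role == r]
    mp <- means$mean_score[means$sign == "positive" & means$site_role == r]
    ok <- length(mn) == 1L && length(mp) == 1L && is.finite(mn) &&
      is.finite(mp) && mp != 0
    data.frame(site_role = r, neg_over_pos = if (ok) mn / mp else NA_real_)
  }))
  baseline_means <- NULL
  if (!is.null(baseline) && nrow(baseline)) {
    brec <- score_view_sites(baseline, genome, models, as_type, "annotated")
    baseline_means <- agg(brec)
  }
  out <- list(records = records, means = means, ratio = ratio,
              baseline_means = baseline_means)
  class(out) <- "site_scores"
  out
}
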