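#' Synthetic fixture generation
#'
#' Deterministic generator of a complete toy input bundle: a genome
#' FASTA with real GT..AG introns and planted splice-site strengths, a
#' BED12 annotation with CDS, rMATS JCEC event tables for all five
#' splicing types, a gene expression table, a directory of
#' cross-experiment tables with planted overlap structure, and a
#' machine-readable truth manifest covering every planted property
#' (annotation status, intervening exon counts, element sizes, frame
#' class, termination-codon offsets, NMD verdicts, neopeptide and
#' excised-peptide sequences, pairwise overlap counts). Every analysis
#' module is testable against the manifest without external downloads.
#'
#' Coding gene designs control reading frames at the nucleotide level:
#' coding sequence outside deliberate signals is drawn from the
#' T-free alphabet {A,C,G}, which cannot form a stop codon in any
#' frame, and premature stops are injected at exact planned positions
#' so that frame class and the distance from the termination codon to
#' the final exon-exon junction hold by construction. The generator
#' re-translates every planted isoform at the string level and refuses
#' to write fixtures that fail their own truth.
#'
#' @name fixtures
NULL

rnd_from <- function(alphabet, n, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
rnd_acg <- function(n) rnd_from(c("A", "C", "G"), n)
rnd_dna <- function(n) rnd_from(c("A", "C", "G", "T"), n)

# planted splice-site sequence parts; strong = per-position consensus of
# the built-in models, weak = lowest-frequency choices (T avoided in
# exonic parts so coding frames stay stop-free), mid = sampled from the
# model marginals
site_parts <- function(class) {
  if (class == "strong") {
    return(list(don_ex = "CAG", don_in = "GTAAGT",
                acc_in = paste0(strrep("T", 16), "CCAG"), acc_ex = "GAG"))
  }
  if (class == "weak") {
    return(list(don_ex = "GCC", don_in = "GTCCCA",
                acc_in = paste0(strrep("A", 16), "GGAG"), acc_ex = "CGA"))
  }
  dm <- donor_marginal_freqs()
  am <- acceptor_marginal_freqs()
  pick <- function(m, pos, acg_only = FALSE) {
    paste(vapply(pos, function(p) {
      pr <- m[, p]
      if (acg_only) pr <- pr[c("A", "C", "G")]
      sample(names(pr), 1L, prob = pr / sum(pr))
    }, character(1)), collapse = "")
  }
  list(don_ex = pick(dm, 1:3, acg_only = TRUE),
       don_in = paste0("GT", pick(dm, 6:9)),
       acc_in = paste0(pick(am, 1:18), "AG"),
       acc_ex = pick(am, 21:23, acg_only = TRUE))
}

intron_str <- function(len, donor_class, acceptor_class) {
  d <- site_parts(donor_class)$don_in
  a <- site_parts(acceptor_class)$acc_in
  stopifnot(len >= 26 + 4)
  paste0(d, rnd_dna(len - 26), a)
}

GC <- Biostrings::GENETIC_CODE

# independent string-level translator used for generator self-checks
str_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  paste(vapply(seq_len(n), function(i)
    unname(GC[substr(cds, 3L * i - 2L, 3L * i)]), character(1)),
    collapse = "")
}

#' Fixture specification
#'
#' Returns the default study design: planted event descriptors for the
#' skipped-exon battery (frame classes, termination-codon offsets,
#' neopeptide lengths, annotation status, splice-site strengths,
#' expression levels), multi-exon skipping events, retained-intron
#' events, background annotation genes and the planted overlap design
#' of the comparison experiments. Pass a modified copy to
#' [generate_fixtures()] to change the study conditions.
#'
#' @param seed integer seed; the generator is byte-reproducible given
#'   the same spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L) {
  se_single <- data.frame(
    gene = sprintf("GENE%02d", 1:21),
    class = c("fs_nmd", "fs_nmd", "fs_nmd", "fs_nmd", "fs_nmd", "fs_nmd",
              "fs_non", "fs_non", "in_frame", "in_frame",
              "fs_nmd", "fs_non", "in_frame", "in_frame",
              rep("in_frame", 7)),
    d = c(200, 51, 120, 75, 300, 90, 50, 10, NA, NA,
          100, 20, NA, NA, rep(NA, 7)),
    m = c(39, 120, 15, 60, 24, 90, 45, 21, NA, NA,
          39, 21, NA, NA, rep(NA, 7)),
    c3 = c(100, 98, 103, 110, 121, 131, 100, 98, 99, 45,
           100, 98, 60, 33, rep(48, 7)),
    sign = c(rep("negative", 10), rep("positive", 4), rep("ns", 7)),
    fdr = c(1e-8, 1e-6, 2e-5, 1e-7, 3e-6, 1e-4, 4e-4, 1e-9, 2e-6, 1e-5,
            1e-6, 2e-7, 1e-4, 3e-5, 0.2, 0.5, 0.01, 0.9, 0.05, 0.3,
            0.0005),
    inc_diff = c(-0.42, -0.31, -0.75, -0.22, -0.58, -0.36, -0.63, -0.27,
                 -0.49, -0.33, 0.38, 0.52, 0.21, 0.44, -0.15, 0.12,
                 -0.18, 0.11, -0.22, 0.16, -0.5),
    annotated = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                  TRUE, rep(TRUE, 11)),
    strand = c("+", "-", "+", "+", "-", "+", "+", "-", "+", "-",
               "+", "-", "+", "+", "+", "-", "+", "-", "+", "+", "-"),
    site_skip = c(rep("weak", 10), rep("strong", 4), rep("mid", 7)),
    site_flank = c(rep("strong", 10), rep("weak", 4), rep("mid", 7)),
    tpm = c(8, 5.5, 12, 4, 0.8, 6, 9, 1.5, 20, 3.5,
            4.2, 7.5, 0.6, 11, 2.1, 5, 0.3, 6.5, 1.2, 3.2, 4.4),
    in_expression = c(rep(TRUE, 17), FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  se_multi <- data.frame(
    gene = sprintf("GENE%02d", 22:24),
    n_intervening = c(2L, 3L, 4L),
    annotated = c(TRUE, TRUE, FALSE),
    strand = c("+", "-", "+"),
    fdr = c(1e-6, 4e-5, 2e-8),
    inc_diff = c(-0.55, -0.38, -0.61),
    tpm = c(4, 7, 0.4),
    in_expression = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ri <- data.frame(
    gene = sprintf("RIGENE%02d", 1:7),
    e1 = c(90, 130, 75, 110, 95, 120, 85),
    intron = c(150, 240, 90, 300, 210, 180, 260),
    e2 = c(120, 100, 140, 90, 160, 110, 95),
    sign = c(rep("positive", 5), "ns", "ns"),
    fdr = c(1e-7, 3e-6, 2e-5, 1e-8, 9e-5, 0.4, 0.02),
    inc_diff = c(0.51, 0.33, 0.62, 0.28, 0.45, 0.21, -0.3),
    site = c("strong", "strong", "strong", "weak", "weak", "mid", "mid"),
    strand = c("+", "-", "+", "+", "-", "+", "+"),
    tpm = c(6, 3.8, 0.9, 14, 5.2, 2.4, 8),
    stringsAsFactors = FALSE)
  compare <- list(
    n_population = 60L,
    experiments = list(
      expA = list(neg = 1:20, pos = 55:57),
      expB = list(neg = 5:24, pos = 55:56),
      expC = list(neg = 31:50, pos = 58:59),
      expD = list(neg = 35:54, pos = 58:60),
      expE = list(neg = 3:22, pos = 55:57),
      expF = list(neg = 33:52, pos = 58:60)),
    groups = c(expA = 1L, expB = 1L, expC = 2L, expD = 2L,
               expE = 1L, expF = 2L))
  spec <- list(seed = as.integer(seed), se_single = se_single,
               se_multi = se_multi, ri = ri,
               n_background_genes = 12L, compare = compare,
               background_tpm = c(5, 12, 0.5, 3.1, 8, 1.9, 22, 0.2, 4.4,
                                  6.8, 2.6, 15))
  class(spec) <- "fixture_spec"
  spec
}

# contig builder: an environment accumulating sequence chunks
new_contig <- function() {
  env <- new.env(parent = emptyenv())
  env$chunks <- list()
  env$len <- 0
  env
}

contig_append <- function(ct, seq) {
  ct$chunks[[length(ct$chunks) + 1L]] <- seq
  ct$len <- ct$len + nchar(seq)
}

# place a gene (transcript-oriented segment list) on a contig; returns
# genomic exon coordinates (ascending) and a spliced-position mapper
place_gene <- function(ct, seg_kind, seg_seq, strand) {
  gap <- sample(400:1200, 1L)
  contig_append(ct, rnd_dna(gap))
  gstart <- ct$len
  s_t <- paste(seg_seq, collapse = "")
  L <- nchar(s_t)
  contig_append(ct, if (strand == "+") s_t else revcomp(s_t))
  lens <- nchar(seg_seq)
  offs <- cumsum(c(0, lens))[seq_along(lens)]
  ex <- which(seg_kind == "exon")
  # transcript-order genomic intervals
  ex_gen <- t(vapply(ex, function(i) {
    a <- offs[i]; b <- offs[i] + lens[i]
    if (strand == "+") c(gstart + a, gstart + b)
    else c(gstart + L - b, gstart + L - a)
  }, numeric(2)))
  colnames(ex_gen) <- c("start", "end")
  spliced_lens <- lens[ex]
  tx_off <- cumsum(c(0, spliced_lens))[seq_along(ex)]
  map_spliced <- function(p) {   # 0-based spliced pos -> 0-based genomic
    i <- findInterval(p, tx_off)
    k <- p - tx_off[i]
    if (strand == "+") ex_gen[i, "start"] + k
    else ex_gen[i, "end"] - 1 - k
  }
  asc <- ex_gen[order(ex_gen[, "start"]), , drop = FALSE]
  list(gstart = gstart, exons_tx = ex_gen, exons_asc = asc,
       map_spliced = map_spliced, intron_lens = lens[seg_kind == "intron"])
}

make_tx <- function(id, symbol, chrom, strand, exons_asc, cds = NULL) {
  list(transcript_id = id, gene_symbol = symbol, chrom = chrom,
       strand = strand, exons = exons_asc, cds = cds)
}

# build one five-exon coding gene hosting a single-skip event
design_single_gene <- function(row, chrom, ct, tx_id) {
  L1 <- 120; L2 <- 90; c3 <- row$c3
  is_fs <- row$class %in% c("fs_nmd", "fs_non")
  L4 <- if (is_fs) row$m + 3 + row$d else 84
  pad <- (3 - ((c3 + L4) %% 3)) %% 3
  t5 <- 30 + pad
  L5 <- t5 + 3 + 45

  flank <- row$site_flank; skip <- row$site_skip
  p_i1d <- site_parts("mid"); p_i1a <- site_parts("mid")
  p_i2d <- site_parts(flank); p_i2a <- site_parts(skip)
  p_i3d <- site_parts(skip);  p_i3a <- site_parts(flank)
  p_i4d <- site_parts("mid"); p_i4a <- site_parts("mid")

  e1 <- paste0(rnd_dna(12), "ATG", rnd_acg(102), p_i1d$don_ex)
  e2 <- paste0(p_i1a$acc_ex, rnd_acg(L2 - 6), p_i2d$don_ex)
  e3 <- paste0(p_i2a$acc_ex, rnd_acg(c3 - 6), p_i3d$don_ex)
  e4 <- paste0(p_i3a$acc_ex, rnd_acg(L4 - 6), p_i4d$don_ex)
  if (is_fs) {
    m <- row$m
    substr(e4, m + 1, m + 3) <- "TAA"
  }
  e5 <- paste0(p_i4a$acc_ex, rnd_acg(t5 - 3), "TAA", rnd_dna(45))
  il <- sample(150:500, 4L, replace = TRUE)
  introns <- c(intron_str(il[1], "mid", "mid"),
               intron_str(il[2], flank, skip),
               intron_str(il[3], skip, flank),
               intron_str(il[4], "mid", "mid"))

  cds_len <- 108 + L2 + c3 + L4 + t5 + 3
  # ---- generator self-check: the planted truths must hold exactly ----
  host_tx_seq <- paste0(e1, e2, e3, e4, e5)
  host_cds <- substr(host_tx_seq, 13, 12 + cds_len)
  aa_host <- str_translate(host_cds)
  stopifnot(substr(aa_host, nchar(aa_host), nchar(aa_host)) == "*",
            !grepl("*", substr(aa_host, 1, nchar(aa_host) - 1), fixed = TRUE))
  host_prot <- substr(aa_host, 1, nchar(aa_host) - 1)
  iso_seq <- paste0(e1, e2, e4, e5)
  iso_cds <- substr(iso_seq, 13, nchar(iso_seq))
  aa_iso <- str_translate(iso_cds)
  stop_at <- regexpr("*", aa_iso, fixed = TRUE)
  J <- L1 + L2 + L4
  if (is_fs) {
    stopifnot(stop_at == 67 + row$m / 3)
    ptc <- 12 + 3 * stop_at
    stopifnot(J - ptc == row$d)
    truth_neo <- substr(aa_iso, 67, stop_at - 1)
    stopifnot(nchar(truth_neo) == row$m / 3)
    truth_excised <- ""
    prot_len <- stop_at - 1
    nmd <- row$d > 50
  } else {
    stopifnot(3 * stop_at == cds_len - c3)
    ptc <- 12 + 3 * stop_at
    truth_neo <- ""
    truth_excised <- substr(host_prot, 67, 66 + c3 / 3)
    prot_len <- stop_at - 1
    stopifnot(prot_len == nchar(host_prot) - c3 / 3)
    nmd <- FALSE
  }

  seg_kind <- c("exon", "intron", "exon", "intron", "exon", "intron",
                "exon", "intron", "exon")
  seg_seq <- c(e1, introns[1], e2, introns[2], e3, introns[3], e4,
               introns[4], e5)
  pl <- place_gene(ct, seg_kind, seg_seq, row$strand)
  gs <- pl$map_spliced(12)
  ge <- pl$map_spliced(12 + cds_len - 1)
  cds_gen <- c(min(gs, ge), max(gs, ge) + 1)
  host <- make_tx(tx_id, row$gene, chrom, row$strand, pl$exons_asc, cds_gen)
  skip_tx <- NULL
  if (row$annotated) {
    keep <- pl$exons_tx[-3L, , drop = FALSE]
    skip_tx <- make_tx(paste0(tx_id, "S"), row$gene, chrom, row$strand,
                       keep[order(keep[, "start"]), , drop = FALSE], NULL)
  }
  ev <- pl$exons_tx   # transcript order: E1..E5
  list(host = host, skip_tx = skip_tx,
       coords = c(ev[3, 1], ev[3, 2], ev[2, 1], ev[2, 2], ev[4, 1],
                  ev[4, 2]),
       truth = data.frame(
         gene = row$gene, class = row$class, sign = row$sign,
         fdr = row$fdr, inc_diff = row$inc_diff, annotated = row$annotated,
         n_intervening = 1L,
         up_exon_len = L2, up_intron_len = pl$intron_lens[2],
         exon_len = c3, down_intron_len = pl$intron_lens[3],
         down_exon_len = L4,
         hosted = TRUE, host_tx = tx_id, region = "cds_overlap",
         frame_class = if (is_fs) "frameshift" else "in_frame",
         removed_len = c3, nmd = nmd,
         ptc_offset = if (is_fs) row$d else NA_real_,
         neopeptide = truth_neo, excised_peptide = truth_excised,
         protein_len = prot_len, host_protein_len = nchar(host_prot),
         site_skip = skip, site_flank = flank,
         tpm = row$tpm, in_expression = row$in_expression,
         stringsAsFactors = FALSE))
}

design_multi_gene <- function(row, chrom, ct, tx_id) {
  n_int <- row$n_intervening
  n_ex <- n_int + 4L          # E1, E2 (flank), intervening, flank, last
  ex_lens <- sample(seq(80L, 200L, by = 2L), n_ex, replace = TRUE)
  il <- sample(150:400, n_ex - 1L, replace = TRUE)
  seg_seq <- character(0); seg_kind <- character(0)
  for (i in seq_len(n_ex)) {
    acc <- if (i > 1) site_parts("mid")$acc_ex else rnd_acg(3)
    don <- if (i < n_ex) site_parts("mid")$don_ex else rnd_acg(3)
    seg_seq <- c(seg_seq, paste0(acc, rnd_dna(ex_lens[i] - 6), don))
    seg_kind <- c(seg_kind, "exon")
    if (i < n_ex) {
      seg_seq <- c(seg_seq, intron_str(il[i], "mid", "mid"))
      seg_kind <- c(seg_kind, "intron")
    }
  }
  pl <- place_gene(ct, seg_kind, seg_seq, row$strand)
  host <- make_tx(tx_id, row$gene, chrom, row$strand, pl$exons_asc, NULL)
  skip_tx <- NULL
  if (row$annotated) {
    keep <- pl$exons_tx[-seq.int(3L, 2L + n_int), , drop = FALSE]
    skip_tx <- make_tx(paste0(tx_id, "S"), row$gene, chrom, row$strand,
                       keep[order(keep[, "start"]), , drop = FALSE], NULL)
  }
  ev <- pl$exons_tx
  down_i <- 3L + n_int
  # the event's "downstream intron" spans everything between the first
  # intervening exon and the downstream flank (strand-safe in
  # transcript space)
  down_intron <- sum(il[3:(n_int + 2L)]) +
    if (n_int >= 2L) sum(ex_lens[4:(n_int + 2L)]) else 0
  list(host = host, skip_tx = skip_tx,
       coords = c(ev[3, 1], ev[3, 2], ev[2, 1], ev[2, 2], ev[down_i, 1],
                  ev[down_i, 2]),
       truth = data.frame(
         gene = row$gene, class = "multi", sign = "negative",
         fdr = row$fdr, inc_diff = row$inc_diff, annotated = row$annotated,
         n_intervening = n_int,
         up_exon_len = ex_lens[2], up_intron_len = il[2],
         exon_len = ex_lens[3],
         down_intron_len = down_intron,
         down_exon_len = ex_lens[down_i],
         hosted = FALSE, host_tx = NA_character_, region = NA_character_,
         frame_class = NA_character_, removed_len = NA_real_, nmd = NA,
         ptc_offset = NA_real_, neopeptide = "", excised_peptide = "",
         protein_len = NA_integer_, host_protein_len = NA_integer_,
         site_skip = "mid", site_flank = "mid",
         tpm = row$tpm, in_expression = row$in_expression,
         stringsAsFactors = FALSE))
}

design_ri_gene <- function(row, chrom, ct, tx_id) {
  p_d <- site_parts(row$site); p_a <- site_parts(row$site)
  e1 <- paste0(rnd_dna(3), rnd_dna(row$e1 - 6), p_d$don_ex)
  e2 <- paste0(p_a$acc_ex, rnd_dna(row$e2 - 6), site_parts("mid")$don_ex)
  e3 <- paste0(site_parts("mid")$acc_ex, rnd_dna(74))
  i1 <- intron_str(row$intron, row$site, row$site)
  i2 <- intron_str(200, "mid", "mid")
  pl <- place_gene(ct, c("exon", "intron", "exon", "intron", "exon"),
                   c(e1, i1, e2, i2, e3), row$strand)
  host <- make_tx(tx_id, row$gene, chrom, row$strand, pl$exons_asc, NULL)
  ev <- pl$exons_tx
  ri_span <- range(c(ev[1, ], ev[2, ]))
  list(host = host,
       coords = c(ri_span[1], ri_span[2], ev[1, 1], ev[1, 2], ev[2, 1],
                  ev[2, 2]),
       truth = data.frame(
         gene = row$gene, sign = row$sign, fdr = row$fdr,
         inc_diff = row$inc_diff,
         up_exon_len = row$e1, retained_intron_len = row$intron,
         down_exon_len = row$e2, site = row$site, tpm = row$tpm,
         stringsAsFactors = FALSE))
}

design_background_gene <- function(symbol, chrom, ct, tx_id) {
  n_ex <- sample(3:6, 1L)
  ex_lens <- sample(seq(90L, 240L, by = 3L), n_ex, replace = TRUE)
  il <- sample(150:400, n_ex - 1L, replace = TRUE)
  seg_seq <- character(0); seg_kind <- character(0)
  for (i in seq_len(n_ex)) {
    acc <- if (i > 1) site_parts("mid")$acc_ex else rnd_acg(3)
    don <- if (i < n_ex) site_parts("mid")$don_ex else rnd_acg(3)
    seg_seq <- c(seg_seq, paste0(acc, rnd_dna(ex_lens[i] - 6), don))
    seg_kind <- c(seg_kind, "exon")
    if (i < n_ex) {
      seg_seq <- c(seg_seq, intron_str(il[i], "mid", "mid"))
      seg_kind <- c(seg_kind, "intron")
    }
  }
  strand <- sample(c("+", "-"), 1L)
  pl <- place_gene(ct, seg_kind, seg_seq, strand)
  make_tx(tx_id, symbol, chrom, strand, pl$exons_asc, NULL)
}

events_df <- function(as_type, gene, chrom, strand, coords, fdr, inc) {
  n <- length(gene)
  cmat <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) cmat[i, seq_along(coords[[i]])] <- coords[[i]]
  colnames(cmat) <- paste0("c", 1:8)
  ev <- cbind(data.frame(as_type = as_type, gene_id = paste0("ID_", gene),
                         gene_symbol = gene, chrom = chrom, strand = strand,
                         stringsAsFactors = FALSE),
              as.data.frame(cmat))
  ev$fdr <- fdr; ev$inc_diff <- inc
  ev$source_line <- seq_len(n) + 1
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Generate the fixture bundle
#'
#' @param spec a [fixture_spec()] (or a seed to build one).
#' @param outdir output directory (created). Files written:
#'   `genome.fa`, `annotation.bed`, `expression.tsv`,
#'   `main_<TYPE>.MATS.JCEC.txt` for the five splicing types,
#'   `compare/<experiment>_SE.MATS.JCEC.txt`, and
#'   `manifest_se_events.tsv` / `manifest_ri_events.tsv` /
#'   `manifest_genes.tsv` / `manifest_overlaps.tsv`.
#' @return (invisibly) list with `paths`, `manifest` (data frames:
#'   `se_events` keyed by event, `ri_events`, `genes`, `overlaps`) and
#'   the `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), outdir) {
  if (is.numeric(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  ct1 <- new_contig(); ct2 <- new_contig()
  txs <- list(); se_rows <- list(); se_coords <- list()
  tx_n <- 0L
  next_id <- function() { tx_n <<- tx_n + 1L; sprintf("TX%04d", tx_n) }

  for (i in seq_len(nrow(spec$se_single))) {
    g <- design_single_gene(spec$se_single[i, ], "chr1", ct1, next_id())
    txs <- c(txs, list(g$host), if (!is.null(g$skip_tx)) list(g$skip_tx))
    se_rows[[length(se_rows) + 1L]] <- g$truth
    se_coords[[length(se_coords) + 1L]] <-
      list(gene = g$truth$gene, strand = g$host$strand, coords = g$coords,
           fdr = g$truth$fdr, inc = g$truth$inc_diff)
  }
  for (i in seq_len(nrow(spec$se_multi))) {
    g <- design_multi_gene(spec$se_multi[i, ], "chr1", ct1, next_id())
    txs <- c(txs, list(g$host), if (!is.null(g$skip_tx)) list(g$skip_tx))
    se_rows[[length(se_rows) + 1L]] <- g$truth
    se_coords[[length(se_coords) + 1L]] <-
      list(gene = g$truth$gene, strand = g$host$strand, coords = g$coords,
           fdr = g$truth$fdr, inc = g$truth$inc_diff)
  }
  ri_rows <- list(); ri_coords <- list()
  for (i in seq_len(nrow(spec$ri))) {
    g <- design_ri_gene(spec$ri[i, ], "chr2", ct2, next_id())
    txs <- c(txs, list(g$host))
    ri_rows[[length(ri_rows) + 1L]] <- g$truth
    ri_coords[[length(ri_coords) + 1L]] <-
      list(gene = g$truth$gene, strand = g$host$strand, coords = g$coords,
           fdr = g$truth$fdr, inc = g$truth$inc_diff)
  }
  bg_genes <- sprintf("BGGENE%02d", seq_len(spec$n_background_genes))
  for (i in seq_along(bg_genes)) {
    ctig <- if (i %% 2 == 0) ct2 else ct1
    chrom <- if (i %% 2 == 0) "chr2" else "chr1"
    txs <- c(txs, list(design_background_gene(bg_genes[i], chrom, ctig,
                                              next_id())))
  }
  contig_append(ct1, rnd_dna(2000))
  contig_append(ct2, rnd_dna(2000))

  genome_path <- file.path(outdir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste(unlist(ct1$chunks), collapse = ""),
    chr2 = paste(unlist(ct2$chunks), collapse = "")))
  Biostrings::writeXStringSet(seqs, genome_path, width = 70L)
  if (file.exists(paste0(genome_path, ".fai")))
    file.remove(paste0(genome_path, ".fai"))

  bed_path <- file.path(outdir, "annotation.bed")
  class(txs) <- "transcript_set"
  write_bed12(txs, bed_path)

  # main event tables
  se_ev <- events_df("SE",
                     vapply(se_coords, `[[`, character(1), "gene"), "chr1",
                     vapply(se_coords, `[[`, character(1), "strand"),
                     lapply(se_coords, `[[`, "coords"),
                     vapply(se_coords, `[[`, numeric(1), "fdr"),
                     vapply(se_coords, `[[`, numeric(1), "inc"))
  ri_ev <- events_df("RI",
                     vapply(ri_coords, `[[`, character(1), "gene"), "chr2",
                     vapply(ri_coords, `[[`, character(1), "strand"),
                     lapply(ri_coords, `[[`, "coords"),
                     vapply(ri_coords, `[[`, numeric(1), "fdr"),
                     vapply(ri_coords, `[[`, numeric(1), "inc"))
  write_rmats(se_ev, file.path(outdir, "main_SE.MATS.JCEC.txt"))
  write_rmats(ri_ev, file.path(outdir, "main_RI.MATS.JCEC.txt"))

  # small parse-only tables for the remaining types, derived from the
  # first single-skip genes
  mk_alt <- function(as_type, n, width) {
    rows <- lapply(seq_len(n), function(i) {
      cc <- se_coords[[i]]$coords
      if (as_type == "MXE")
        c(cc[1], cc[2], cc[2] + 10, cc[2] + 60, cc[3], cc[4], cc[5], cc[6])
      else
        c(cc[1], cc[2] + width, cc[1], cc[2], cc[5], cc[6])
    })
    events_df(as_type,
              vapply(seq_len(n), function(i) se_coords[[i]]$gene,
                     character(1)), "chr1",
              vapply(seq_len(n), function(i) se_coords[[i]]$strand,
                     character(1)),
              rows, fdr = c(1e-6, 0.3, 2e-5)[seq_len(n)],
              inc = c(0.4, -0.2, -0.5)[seq_len(n)])
  }
  write_rmats(mk_alt("A5SS", 3, 12), file.path(outdir,
                                               "main_A5SS.MATS.JCEC.txt"))
  write_rmats(mk_alt("A3SS", 3, 9), file.path(outdir,
                                              "main_A3SS.MATS.JCEC.txt"))
  write_rmats(mk_alt("MXE", 2, 0), file.path(outdir,
                                             "main_MXE.MATS.JCEC.txt"))

  # expression table: planted control means are exact (replicates at
  # 0.9x and 1.1x the mean)
  se_truth <- do.call(rbind, se_rows)
  gene_tbl <- rbind(
    data.frame(gene = se_truth$gene, tpm = se_truth$tpm,
               in_expression = se_truth$in_expression,
               stringsAsFactors = FALSE),
    data.frame(gene = do.call(rbind, ri_rows)$gene,
               tpm = do.call(rbind, ri_rows)$tpm, in_expression = TRUE,
               stringsAsFactors = FALSE),
    data.frame(gene = bg_genes, tpm = spec$background_tpm,
               in_expression = TRUE, stringsAsFactors = FALSE))
  expr <- gene_tbl[gene_tbl$in_expression, , drop = FALSE]
  test_mult <- round(stats::runif(nrow(expr), 0.3, 2.5), 3)
  expr_df <- data.frame(gene_id = expr$gene,
                        ctrl_1 = expr$tpm * 0.9, ctrl_2 = expr$tpm * 1.1,
                        test_1 = round(expr$tpm * test_mult, 4),
                        test_2 = round(expr$tpm * test_mult * 1.08, 4))
  write_tsv(expr_df, file.path(outdir, "expression.tsv"))

  # comparison experiments over a shared synthetic population
  cmp_dir <- file.path(outdir, "compare")
  dir.create(cmp_dir, showWarnings = FALSE)
  n_pop <- spec$compare$n_population
  base <- 10000 + (seq_len(n_pop) - 1) * 1000
  pop_coords <- lapply(base, function(b)
    c(b + 200, b + 350, b, b + 100, b + 500, b + 600))
  for (nm in names(spec$compare$experiments)) {
    sel <- spec$compare$experiments[[nm]]
    fdr <- rep(0.9, n_pop); inc <- rep(0.05, n_pop)
    inc[seq_len(n_pop) %% 2 == 0] <- -0.05
    fdr[sel$neg] <- 1e-6; inc[sel$neg] <- -0.4
    fdr[sel$pos] <- 1e-6; inc[sel$pos] <- 0.4
    ev <- events_df("SE", sprintf("POPG%03d", seq_len(n_pop)), "chr2",
                    "+", pop_coords, fdr, inc)
    write_rmats(ev, file.path(cmp_dir,
                              sprintf("%s_SE.MATS.JCEC.txt", nm)))
  }
  exps <- spec$compare$experiments
  pairs <- utils::combn(names(exps), 2)
  overlaps <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- exps[[pairs[1, j]]]; b <- exps[[pairs[2, j]]]
    do.call(rbind, lapply(c("neg", "pos"), function(sg) {
      sa <- a[[sg]]; sb <- b[[sg]]
      data.frame(exp_a = pairs[1, j], exp_b = pairs[2, j], sign = sg,
                 k = length(intersect(sa, sb)), K = length(sa),
                 n = length(sb), N = n_pop, stringsAsFactors = FALSE)
    }))
  }))

  # manifest keys must match the parser's canonical keys
  se_truth <- cbind(data.frame(event_key = event_key(se_ev),
                               stringsAsFactors = FALSE), se_truth)
  ri_truth <- cbind(data.frame(event_key = event_key(ri_ev),
                               stringsAsFactors = FALSE),
                    do.call(rbind, ri_rows))
  gene_manifest <- merge(
    gene_tbl,
    data.frame(gene = se_truth$gene,
               sig_neg_se = se_truth$sign == "negative",
               sig_pos_se = se_truth$sign == "positive",
               stringsAsFactors = FALSE),
    by = "gene", all.x = TRUE)
  gene_manifest$sig_neg_se[is.na(gene_manifest$sig_neg_se)] <- FALSE
  gene_manifest$sig_pos_se[is.na(gene_manifest$sig_pos_se)] <- FALSE

  write_tsv(se_truth, file.path(outdir, "manifest_se_events.tsv"))
  write_tsv(ri_truth, file.path(outdir, "manifest_ri_events.tsv"))
  write_tsv(gene_manifest, file.path(outdir, "manifest_genes.tsv"))
  write_tsv(overlaps, file.path(outdir, "manifest_overlaps.tsv"))

  manifest <- list(se_events = se_truth, ri_events = ri_truth,
                   genes = gene_manifest, overlaps = overlaps)
  invisible(list(
    paths = list(
      genome = genome_path, annotation = bed_path,
      expression = file.path(outdir, "expression.tsv"),
      se = file.path(outdir, "main_SE.MATS.JCEC.txt"),
      ri = file.path(outdir, "main_RI.MATS.JCEC.txt"),
      compare_dir = cmp_dir, outdir = outdir),
    manifest = manifest, spec = spec))
}
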