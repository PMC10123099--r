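# session-cached fixture bundle so the generator runs once per test run

fixture_env <- new.env()

get_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    dir <- file.path(tempdir(), "splicedown-fixture")
    fixture_env$fx <- generate_fixtures(fixture_spec(101), dir)
  }
  fixture_env$fx
}

get_loaded <- function() {
  if (is.null(fixture_env$loaded)) {
    fx <- get_fixture()
    ev <- read_rmats(fx$paths$se, "SE")
    txs <- read_bed12(fx$paths$annotation)
    fixture_env$loaded <- list(
      fx = fx, ev = ev, sig = filter_significant(ev), txs = txs,
      idx = build_junction_index(txs),
      gen = load_genome(fx$paths$genome),
      ri = read_rmats(fx$paths$ri, "RI"),
      manifest = fx$manifest)
  }
  fixture_env$loaded
}

# minimal transcript-model constructor for hand-built annotations
mk_tx <- function(id, exons, chrom = "chr1", strand = "+", cds = NULL,
                  symbol = "GENE") {
  list(transcript_id = id, gene_symbol = symbol, chrom = chrom,
       strand = strand,
       exons = matrix(unlist(exons), ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end"))),
       cds = cds)
}

mk_tx_set <- function(...) {
  txs <- list(...)
  class(txs) <- "transcript_set"
  txs
}

# literal JCEC line builder (1-based column contract)
jcec_line <- function(coords, fdr, inc, gene = "GENEX", chrom = "chr1",
                      strand = "+", n_cols = if (length(coords) == 8) 25
                                    else 23) {
  f <- rep("", n_cols)
  f[1] <- "1"; f[2] <- "ENSG00000001"; f[3] <- gene; f[4] <- chrom
  f[5] <- strand
  f[6:(5 + length(coords))] <- format(coords, scientific = FALSE)
  if (length(coords) == 8) {
    f[22] <- as.character(fdr); f[25] <- as.character(inc)
  } else {
    f[20] <- as.character(fdr); f[23] <- as.character(inc)
  }
  paste(f, collapse = "\t")
}

jcec_header <- function(n_cols = 23) {
  paste(sprintf("col%d", seq_len(n_cols)), collapse = "\t")
}

write_jcec <- function(lines, n_cols = 23, header = TRUE) {
  path <- tempfile(fileext = ".txt")
  writeLines(c(if (header) jcec_header(n_cols), lines), path)
  path
}

# independent marginal-sum oracle for splice-site scores: for a
# first-order maximum-entropy model the score is the per-position sum
# of log2(marginal/background); the package path instead goes through
# consensus ratios and joint lookup tables
oracle_site_score <- function(seq, marginals, bg) {
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  sum(log2(marginals[cbind(b, seq_along(b))] / bg[b]))
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# brute-force upper-tail hypergeometric by direct combinatorial sum
oracle_hyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
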