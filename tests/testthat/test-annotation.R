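bed_line <- function(chrom, start, end, name, strand, thick_s, thick_e,
                     sizes, offs) {
  paste(chrom, start, end, name, 0, strand, thick_s, thick_e, "0",
        length(sizes), paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(offs, collapse = ","), ","), sep = "\t")
}

test_that("BED12 parsing reconstructs exons and splits names at the last underscore", {
  path <- tempfile()
  writeLines(c(
    bed_line("chr1", 1000, 2000, "ENST00000371953_PTEN", "+", 1100, 1900,
             sizes = c(100, 200, 100), offs = c(0, 400, 900)),
    bed_line("chr1", 3000, 3500, "ENST1_MY_ALIAS", "-", 3000, 3000,
             sizes = c(500), offs = c(0))), path)
  txs <- read_bed12(path)
  expect_length(txs, 2L)
  expect_equal(txs[[1]]$transcript_id, "ENST00000371953")
  expect_equal(txs[[1]]$gene_symbol, "PTEN")
  expect_equal(txs[[1]]$exons,
               cbind(start = c(1000, 1400, 1900),
                     end = c(1100, 1600, 2000)))
  expect_equal(txs[[1]]$cds, c(1100, 1900))
  # underscore-containing gene alias: split is at the LAST underscore
  expect_equal(txs[[2]]$transcript_id, "ENST1_MY")
  expect_equal(txs[[2]]$gene_symbol, "ALIAS")
  # thickStart == thickEnd flags a non-coding transcript
  expect_null(txs[[2]]$cds)
})

test_that("malformed BED12 is rejected with the offending property named", {
  bad_count <- tempfile()
  writeLines(bed_line("chr1", 0, 100, "T_X", "+", 0, 0, c(50, 50),
                      c(0)), bad_count)
  expect_error(read_bed12(bad_count), "blockCount")
  overlap <- tempfile()
  writeLines(bed_line("chr1", 0, 100, "T_X", "+", 0, 0, c(60, 40),
                      c(0, 50)), overlap)
  expect_error(read_bed12(overlap), "overlap")
  no_us <- tempfile()
  writeLines(bed_line("chr1", 0, 100, "NAMEONLY", "+", 0, 0, 100, 0),
             no_us)
  expect_warning(txs <- read_bed12(no_us), "without")
  expect_equal(txs[[1]]$gene_symbol, "NAMEONLY")
})

test_that("the junction index holds intron sets and answers containment queries", {
  txs <- mk_tx_set(
    mk_tx("T1", list(c(0, 100), c(200, 300), c(400, 500))),
    mk_tx("T2", list(c(0, 100), c(200, 300), c(400, 500))),  # duplicate
    mk_tx("T3", list(c(700, 800))))                           # single exon
  idx <- build_junction_index(txs)
  expect_setequal(idx$introns, c(intron_key("chr1", "+", 100, 200),
                                 intron_key("chr1", "+", 300, 400)))
  hits <- exons_within(idx, "chr1", "+", 150, 450)
  expect_equal(length(hits), 1L)
  expect_equal(GenomicRanges::start(hits), 201)  # only [200,300) fully inside
})

test_that("annotated skipping configurations and introns enumerate per internal exon", {
  tx3 <- mk_tx("A", list(c(0, 100), c(200, 300), c(400, 500)))
  tx5 <- mk_tx("B", list(c(0, 50), c(100, 150), c(200, 250), c(300, 350),
                         c(400, 450)))
  expect_equal(nrow(annotated_se_triples(mk_tx_set(tx3))), 1L)
  expect_equal(nrow(annotated_se_triples(mk_tx_set(tx5))), 3L)
  # duplicated transcripts collapse
  expect_equal(nrow(annotated_se_triples(mk_tx_set(tx3, tx3))), 1L)
  expect_equal(nrow(annotated_introns(mk_tx_set(tx3))), 2L)
  expect_equal(nrow(annotated_introns(mk_tx_set(tx3, tx3))), 2L)
  expect_equal(nrow(annotated_introns(mk_tx_set(
    mk_tx("C", list(c(0, 100)))))), 0L)
  # transcript-oriented labels on the minus strand
  tr <- annotated_se_triples(mk_tx_set(
    mk_tx("D", list(c(0, 100), c(200, 300), c(400, 500)), strand = "-")))
  expect_equal(tr$up_es, 400)
  expect_equal(tr$down_ee, 100)
})

test_that("sequence fetch is exact, strand-aware and dialect-normalizing", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTAACCGGTTACGT", ">MT", "AAAACCCC"), fa)
  gen <- load_genome(fa)
  expect_equal(fetch_sequence(gen, "chr1", 0, 4), "ACGT")
  expect_equal(fetch_sequence(gen, "chr1", 4, 8, "-"), "GGTT")  # revcomp AACC
  # bare name served via the normalization table
  expect_equal(fetch_sequence(gen, "1", 0, 4), "ACGT")
  expect_equal(fetch_sequence(gen, "chrM", 0, 4), "AAAA")
  expect_error(fetch_sequence(gen, "chr9", 0, 4), "chromosome")
  expect_error(fetch_sequence(gen, "chr1", 10, 40), "bounds")
  # concatenation over a partition equals the whole-range fetch
  whole <- fetch_sequence(gen, "chr1", 0, 16)
  parts <- paste0(fetch_sequence(gen, "chr1", 0, 5),
                  fetch_sequence(gen, "chr1", 5, 11),
                  fetch_sequence(gen, "chr1", 11, 16))
  expect_equal(parts, whole)
  # reverse complement is an involution
  rc2 <- fetch_sequence(gen, "chr1", 0, 16, "-")
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc2))), whole)
})

test_that("BED12 writing round-trips transcript models", {
  l <- get_loaded()
  out <- tempfile()
  write_bed12(l$txs, out)
  txs2 <- read_bed12(out)
  expect_equal(length(txs2), length(l$txs))
  expect_equal(txs2[[1]]$exons, l$txs[[1]]$exons, ignore_attr = TRUE)
  expect_equal(txs2[[1]]$cds, l$txs[[1]]$cds)
})
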