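test_that("SE records are read from the positional column contract", {
  path <- write_jcec(jcec_line(
    c(48052363, 48052463, 48051000, 48051100, 48053000, 48053100),
    fdr = 1e-6, inc = -0.31, gene = "NFE2L1", chrom = "chr17",
    strand = "-"))
  ev <- read_rmats(path, "SE")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_symbol, "NFE2L1")
  expect_equal(ev$chrom, "chr17")
  expect_equal(ev$strand, "-")
  expect_equal(unlist(ev[1, paste0("c", 1:6)], use.names = FALSE),
               c(48052363, 48052463, 48051000, 48051100, 48053000,
                 48053100))
  expect_equal(ev$fdr, 1e-6)
  expect_equal(ev$inc_diff, -0.31)
  expect_equal(ev$source_line, 2)
})

test_that("MXE records use the eight-coordinate layout with FDR in column 22", {
  path <- write_jcec(jcec_line(
    c(100, 200, 300, 400, 10, 50, 500, 600), fdr = 0.002, inc = 0.4),
    n_cols = 25)
  ev <- read_rmats(path, "MXE")
  expect_equal(sum(!is.na(ev[1, paste0("c", 1:8)])), 8L)
  expect_equal(ev$fdr, 0.002)
  expect_equal(ev$inc_diff, 0.4)
})

test_that("a header-only file yields an empty event table", {
  path <- write_jcec(character(0))
  ev <- read_rmats(path, "SE")
  expect_s3_class(ev, "splice_events")
  expect_equal(nrow(ev), 0L)
})

test_that("structural problems are errors; parse failures drop lines with numbers", {
  no_header <- tempfile()
  writeLines(jcec_line(c(1, 2, 3, 4, 5, 6) * 100, 0.1, 0.2), no_header)
  expect_error(read_rmats(no_header, "SE"), "header")

  short <- tempfile()
  writeLines(c(jcec_header(23), "a\tb\tc"), short)
  expect_error(read_rmats(short, "SE"), "columns")
  expect_equal(nrow(suppressWarnings(read_rmats(short, "SE",
                                                lenient = TRUE))), 0L)

  bad_num <- write_jcec(c(
    jcec_line(c(100, 200, 10, 50, 300, 400), 0.1, 0.2),
    sub("0.1", "notanumber", jcec_line(c(100, 200, 10, 50, 700, 800),
                                       0.1, 0.2), fixed = TRUE)))
  expect_warning(ev <- read_rmats(bad_num, "SE"), "line")
  expect_equal(nrow(ev), 1L)

  out_of_range <- write_jcec(jcec_line(c(100, 200, 10, 50, 300, 400),
                                       fdr = 1.5, inc = 0.2))
  expect_error(read_rmats(out_of_range, "SE"), "FDR")
  bad_inc <- write_jcec(jcec_line(c(100, 200, 10, 50, 300, 400),
                                  fdr = 0.5, inc = -1.2))
  expect_error(read_rmats(bad_inc, "SE"), "inclusion")
})

test_that("duplicate events collapse to the smallest FDR with a warning", {
  path <- write_jcec(c(
    jcec_line(c(100, 200, 10, 50, 300, 400), 0.01, -0.2),
    jcec_line(c(100, 200, 10, 50, 300, 400), 1e-8, -0.4)))
  expect_warning(ev <- read_rmats(path, "SE"), "duplicate")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$fdr, 1e-8)
})

test_that("significance filtering is strict and sign-aware", {
  path <- write_jcec(c(
    jcec_line(c(100, 200, 10, 50, 300, 400), 1e-6, -0.4),
    jcec_line(c(500, 600, 410, 450, 700, 800), 0.0005, -0.4),
    jcec_line(c(900, 1000, 810, 850, 1100, 1200), 0.2, -0.4)))
  ev <- read_rmats(path, "SE")
  kept <- filter_significant(ev, 0.0005)
  expect_equal(nrow(kept), 1L)       # ties at the threshold are excluded
  expect_equal(kept$fdr, 1e-6)

  incs <- c(-0.4, -0.1, 0, 0.1, 0.4)
  path2 <- write_jcec(vapply(seq_along(incs), function(i)
    jcec_line(c(100, 200, 10, 50, 300, 400) + i * 1000, 0, incs[i]),
    character(1)))
  ev2 <- read_rmats(path2, "SE")
  neg <- filter_significant(ev2, 0.5, sign = "negative")
  pos <- filter_significant(ev2, 0.5, sign = "positive")
  both <- filter_significant(ev2, 0.5, sign = "both")
  expect_equal(nrow(neg), 2L)
  expect_equal(nrow(pos), 2L)
  # zero inclusion difference belongs to neither sign class
  expect_equal(nrow(both), 5L)
  expect_equal(nrow(neg) + nrow(pos), 4L)
  # idempotent and order-preserving
  expect_identical(filter_significant(neg, 0.5, sign = "negative"), neg)
  expect_true(all(diff(neg$source_line) > 0))
})

test_that("event keys depend on geometry only", {
  mk <- function(fdr, strand = "+", as_type = "SE") {
    ev <- read_rmats(write_jcec(jcec_line(
      c(100, 200, 10, 50, 300, 400), fdr, -0.3, strand = strand)), "SE")
    ev$as_type <- as_type
    ev
  }
  expect_identical(event_key(mk(1e-6)), event_key(mk(0.3)))
  expect_false(event_key(mk(1e-6)) == event_key(mk(1e-6, strand = "-")))
  expect_false(event_key(mk(1e-6)) == event_key(mk(1e-6,
                                                   as_type = "A5SS")))
})

test_that("write/parse round trips are field-wise exact and byte-stable", {
  l <- get_loaded()
  for (ty in c("SE", "RI", "MXE")) {
    src <- file.path(l$fx$paths$outdir,
                     sprintf("main_%s.MATS.JCEC.txt", ty))
    ev <- read_rmats(src, ty)
    out1 <- tempfile(); out2 <- tempfile()
    write_rmats(ev, out1)
    ev2 <- read_rmats(out1, ty)
    expect_equal(ev2[, setdiff(names(ev2), "source_line")],
                 ev[, setdiff(names(ev), "source_line")],
                 ignore_attr = TRUE)
    write_rmats(ev2, out2)
    expect_identical(readLines(out1), readLines(out2))
  }
})

test_that("orientation-normalized SE views hold the flanking order invariant", {
  l <- get_loaded()
  v <- se_view(l$ev)
  expect_true(all(v$left_ee <= v$exon_start))
  expect_true(all(v$exon_end <= v$right_es))
  minus <- v$strand == "-"
  expect_true(all(v$up_es[minus] == v$right_es[minus]))
  expect_true(all(v$up_es[!minus] == v$left_es[!minus]))
})
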