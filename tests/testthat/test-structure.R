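test_that("skip junctions classify against the annotation exactly as planted", {
  l <- get_loaded()
  ann <- classify_annotation(l$sig, l$idx)
  m <- l$manifest$se_events
  cmp <- merge(ann$status, m[, c("event_key", "annotated")],
               by = "event_key")
  expect_equal(nrow(cmp), nrow(ann$status))
  expect_equal(cmp$annotated.x, cmp$annotated.y)
  for (s in c("negative", "positive")) {
    truth <- m[m$sign == s, ]
    row <- ann$summary[ann$summary$sign == s, ]
    expect_equal(row$total, nrow(truth))
    expect_equal(row$unannotated, sum(!truth$annotated))
    expect_equal(row$fraction_unannotated, mean(!truth$annotated))
  }
  expect_equal(nrow(ann$unannotated),
               sum(ann$summary$total) - sum(ann$status$annotated))
})

test_that("an empty annotation makes every junction novel", {
  l <- get_loaded()
  empty_idx <- build_junction_index(mk_tx_set(
    mk_tx("T", list(c(0, 10)), chrom = "chrZ")))
  ann <- classify_annotation(l$sig, empty_idx)
  expect_true(all(!ann$status$annotated))
  expect_equal(ann$summary$fraction_unannotated,
               c(1, 1), ignore_attr = TRUE)
})

test_that("intervening exons count as overlap clusters of contained loci", {
  idx1 <- build_junction_index(mk_tx_set(
    mk_tx("T1", list(c(500, 1000), c(2000, 2100), c(5000, 5500))),
    mk_tx("T2", list(c(500, 1000), c(3000, 3090), c(5000, 5500)))))
  expect_equal(count_intervening_exons(idx1, "chr1", "+", 1000, 5000), 2L)
  # overlapping isoform variants of one exon form a single cluster
  idx2 <- build_junction_index(mk_tx_set(
    mk_tx("T1", list(c(500, 1000), c(2000, 2100), c(5000, 5500))),
    mk_tx("T2", list(c(500, 1000), c(2050, 2150), c(5000, 5500)))))
  expect_equal(count_intervening_exons(idx2, "chr1", "+", 1000, 5000), 1L)
  expect_equal(count_intervening_exons(idx2, "chr1", "+", 1000, 5000,
                                       per_interval = TRUE), 2L)
  # invariant to transcript duplication
  idx3 <- build_junction_index(mk_tx_set(
    mk_tx("T1", list(c(500, 1000), c(2000, 2100), c(5000, 5500))),
    mk_tx("T1b", list(c(500, 1000), c(2000, 2100), c(5000, 5500)))))
  expect_equal(count_intervening_exons(idx3, "chr1", "+", 1000, 5000), 1L)
  expect_equal(count_intervening_exons(idx1, "chr1", "+", 2200, 2300), 0L)
  expect_error(count_intervening_exons(idx1, "chr1", "+", 5000, 1000),
               "degenerate")
})

test_that("the multi-exon skipping distribution matches the planted counts", {
  l <- get_loaded()
  ns <- number_skipped_summary(l$sig, l$idx, sign = "negative")
  m <- l$manifest$se_events
  cmp <- merge(ns$records, m[, c("event_key", "n_intervening")],
               by = "event_key")
  expect_equal(cmp$n_intervening.x, cmp$n_intervening.y)
  truth <- m$n_intervening[m$sign == "negative"]
  expect_equal(unname(ns$histogram),
               c(sum(truth == 0), sum(truth == 1), sum(truth == 2),
                 sum(truth == 3), sum(truth >= 4)))
  expect_equal(sum(ns$histogram), nrow(ns$records))
  none <- number_skipped_summary(l$sig[0, ], l$idx, sign = "negative")
  expect_equal(sum(none$histogram), 0L)
})

test_that("SE size records follow coordinate arithmetic and strand orientation", {
  mk_ev <- function(strand) {
    ev <- read_rmats(write_jcec(jcec_line(
      c(500, 650, 100, 200, 900, 1000), 1e-6, -0.4, strand = strand)),
      "SE")
    ev
  }
  plus <- se_intron_exon_sizes(mk_ev("+"))$records
  expect_equal(unlist(plus[1, 4:8], use.names = FALSE),
               c(100, 300, 150, 250, 100))
  minus <- se_intron_exon_sizes(mk_ev("-"))$records
  expect_equal(unlist(minus[1, 4:8], use.names = FALSE),
               c(100, 250, 150, 300, 100))
})

test_that("size summaries match planted sizes and aggregate conservatively", {
  l <- get_loaded()
  sz <- se_intron_exon_sizes(l$sig, annotated_se_triples(l$txs))
  m <- l$manifest$se_events
  cmp <- merge(sz$records, m, by = "event_key")
  expect_equal(cmp$upstream_exon_len, cmp$up_exon_len)
  expect_equal(cmp$upstream_intron_len, cmp$up_intron_len)
  expect_equal(cmp$skipped_exon_len, cmp$exon_len)
  expect_equal(cmp$downstream_intron_len, cmp$down_intron_len)
  expect_equal(cmp$downstream_exon_len, cmp$down_exon_len)
  # mean over a union equals the weighted mean of disjoint parts
  neg <- sz$records[sz$records$sign == "negative", ]
  a <- neg[1:5, ]; b <- neg[-(1:5), ]
  expect_equal(mean(neg$skipped_exon_len),
               (nrow(a) * mean(a$skipped_exon_len) +
                  nrow(b) * mean(b$skipped_exon_len)) / nrow(neg))
  # per-sign summary means equal arithmetic means of the records
  s_neg <- sz$summary[sz$summary$sign == "negative", ]
  expect_equal(s_neg$skipped_exon_len, mean(neg$skipped_exon_len))
  # annotated baseline equals an independent recomputation
  tr <- annotated_se_triples(l$txs)
  expect_equal(sz$baseline$skipped_exon_len,
               mean(tr$exon_end - tr$exon_start))
  expect_equal(sz$baseline$n_events, nrow(tr))
})

test_that("RI sizes report (exon, retained intron, exon) in transcript orientation", {
  ev <- read_rmats(write_jcec(jcec_line(
    c(100, 600, 100, 200, 500, 600), 1e-6, 0.4)), "RI")
  sz <- ri_intron_exon_sizes(ev)
  expect_equal(unlist(sz$records[1, 4:6], use.names = FALSE),
               c(100, 300, 100))
  l <- get_loaded()
  ri_sig <- filter_significant(l$ri)
  rsz <- ri_intron_exon_sizes(ri_sig, annotated_introns(l$txs))
  cmp <- merge(rsz$records, l$manifest$ri_events, by = "event_key")
  expect_equal(cmp$upstream_exon_len, cmp$up_exon_len)
  expect_equal(cmp$retained_intron_len.x, cmp$retained_intron_len.y)
  expect_equal(cmp$downstream_exon_len, cmp$down_exon_len)
  none <- ri_intron_exon_sizes(ev[0, ])
  expect_equal(nrow(none$records), 0L)
  expect_true(all(is.na(none$summary$retained_intron_len)))
})
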