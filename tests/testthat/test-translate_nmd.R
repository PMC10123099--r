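test_that("host matching requires both flanking introns", {
  l <- get_loaded()
  hosts <- find_hosts(l$sig, l$txs)
  m <- l$manifest$se_events
  keys <- event_key(l$sig)
  hosted_truth <- m$hosted[match(keys, m$event_key)]
  expect_setequal(unique(hosts$event_key), keys[hosted_truth])
  # the planted host transcript is among the matches
  cmp <- merge(hosts, m[, c("event_key", "host_tx")], by = "event_key")
  expect_true(all(tapply(cmp$transcript_id == cmp$host_tx,
                         cmp$event_key, any)))
  # a transcript with only one flanking intron does not host
  one_sided <- mk_tx_set(mk_tx("H", list(c(0, 100), c(200, 300),
                                         c(400, 500))))
  ev <- read_rmats(write_jcec(jcec_line(c(200, 300, 0, 100, 600, 700),
                                        1e-6, -0.4)), "SE")
  expect_equal(nrow(find_hosts(ev, one_sided)), 0L)
})

test_that("skipped-isoform construction deletes exactly one exact exon", {
  host <- mk_tx("H", list(c(0, 100), c(200, 300), c(400, 500)),
                cds = c(10, 450))
  iso <- build_skipped_isoform(host, 200, 300)
  expect_equal(nrow(iso$exons), 2L)
  expect_equal(iso$exons[, "start"], c(0, 400), ignore_attr = TRUE)
  expect_equal(iso$cds, host$cds)
  expect_error(build_skipped_isoform(host, 200, 290), "no exact exon")
})

test_that("the 50-nt rule is a strict boundary", {
  J <- 1000
  offsets <- c(10, 50, 51, 200)
  expect_equal(classify_nmd(J - offsets, rep(J, 4)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_false(classify_nmd(NA_real_, J))
  # a stop downstream of the last junction (final exon) is never a candidate
  expect_false(classify_nmd(J + 30, J))
})

test_that("outcomes reproduce every planted translation truth", {
  l <- get_loaded()
  res <- run_translate_nmd(l$sig, l$txs, l$gen)
  m <- l$manifest$se_events
  cmp <- merge(res$outcomes, m, by = "event_key",
               suffixes = c("", ".t"))
  expect_equal(nrow(cmp), nrow(res$outcomes))
  expect_equal(cmp$hosted, cmp$hosted.t)
  h <- cmp[cmp$hosted, ]
  expect_equal(h$transcript_id, h$host_tx)
  expect_equal(h$region, rep("cds_overlap", nrow(h)))
  expect_equal(h$frame_class, h$frame_class.t)
  expect_equal(h$removed_coding_len, h$removed_len)
  expect_equal(h$nmd, h$nmd.t)
  expect_equal(h$neopeptide, h$neopeptide.t)
  expect_equal(h$excised_peptide, h$excised_peptide.t)
  expect_equal(h$protein_len, h$protein_len.t)
  expect_equal(h$host_protein_len, h$host_protein_len.t)
  fs <- h[h$frame_class == "frameshift", ]
  expect_equal(fs$last_junction_tx_pos - fs$ptc_tx_pos, fs$ptc_offset)
})

test_that("frame class follows removed coding length mod 3", {
  l <- get_loaded()
  res <- run_translate_nmd(l$sig, l$txs, l$gen)
  h <- res$outcomes[res$outcomes$hosted, ]
  expect_equal(h$frame_class == "frameshift",
               h$removed_coding_len %% 3 != 0)
  inf <- h[h$frame_class == "in_frame", ]
  expect_equal(inf$protein_len,
               inf$host_protein_len - inf$removed_coding_len / 3)
  # all three residue classes are exercised by the fixture
  expect_setequal(unique(h$removed_coding_len %% 3), c(0, 1, 2))
})

test_that("proteins terminate at their first stop with no internal stops", {
  l <- get_loaded()
  res <- run_translate_nmd(l$sig, l$txs, l$gen)
  h <- res$outcomes[res$outcomes$hosted, ]
  expect_false(any(grepl("*", h$protein, fixed = TRUE)))
  expect_false(any(grepl("*", h$neopeptide, fixed = TRUE)))
  expect_true(all(h$neopeptide == "" |
                    h$frame_class == "frameshift"))
})

test_that("summaries, gene lists and files follow the outcome table", {
  l <- get_loaded()
  outdir <- tempfile()
  res <- run_translate_nmd(l$sig, l$txs, l$gen, outdir = outdir)
  s <- res$summary
  oc <- res$outcomes
  for (sg in c("negative", "positive")) {
    row <- s[s$sign == sg, ]
    sub <- oc[oc$sign == sg, ]
    expect_equal(row$n_events, nrow(sub))
    expect_equal(row$n_nmd, sum(sub$nmd, na.rm = TRUE))
    expect_equal(row$fraction_nmd, row$n_nmd / row$n_translatable)
    expect_equal(row$n_neopeptides_gt12,
                 sum(nchar(sub$neopeptide) > 12, na.rm = TRUE))
    genes <- readLines(file.path(outdir,
                                 sprintf("nmd_genes_%s.txt", sg)))
    expect_setequal(genes, unique(sub$gene_symbol[!is.na(sub$nmd) &
                                                    sub$nmd]))
    expect_lte(length(genes), row$n_nmd)
  }
  expect_true(file.exists(file.path(outdir, "protein_isoforms.fa")))
  neo <- Biostrings::readAAStringSet(file.path(outdir, "neopeptides.fa"))
  expect_equal(length(neo), sum(nchar(oc$neopeptide) > 0))
  bed <- readLines(file.path(outdir, "nmd_events.bed"))
  expect_equal(length(bed), sum(oc$nmd, na.rm = TRUE))
  expect_true(all(vapply(strsplit(bed, "\t"), length, integer(1)) == 12L))
})

test_that("events in non-coding or absent hosts degrade gracefully", {
  # non-coding host: outcome is noncoding, no translation
  host <- mk_tx("N", list(c(0, 100), c(200, 300), c(400, 500)))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste(rep("ACGT", 150), collapse = "")), fa)
  gen <- load_genome(fa)
  iso <- build_skipped_isoform(host, 200, 300)
  oc <- translate_outcome(iso, host, 200, 300, gen)
  expect_equal(oc$region, "noncoding")
  expect_equal(oc$frame_class, "not_applicable")
  expect_false(oc$nmd)
  expect_equal(oc$protein, "")
  # a UTR-only skip leaves the protein unchanged
  host2 <- mk_tx("U", list(c(0, 100), c(200, 300), c(400, 500)),
                 cds = c(412, 475))
  iso2 <- build_skipped_isoform(host2, 200, 300)
  oc2 <- translate_outcome(iso2, host2, 200, 300, gen)
  expect_equal(oc2$region, "utr5_only")
  expect_equal(oc2$removed_coding_len, 0)
})
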