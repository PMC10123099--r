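test_that("table-driven scores agree with the independent marginal-sum oracle", {
  models <- splice_site_models()
  dm <- splicedown:::donor_marginal_freqs()
  am <- splicedown:::acceptor_marginal_freqs()
  bg <- splicedown:::background_freqs()
  set.seed(7)
  p9 <- random_seqs(500, 9)
  p23 <- random_seqs(500, 23)
  d_pkg <- score_donor(p9, models)
  d_ora <- vapply(p9, oracle_site_score, numeric(1), dm, bg)
  a_pkg <- score_acceptor(p23, models)
  a_ora <- vapply(p23, oracle_site_score, numeric(1), am, bg)
  expect_lt(max(abs(d_pkg - d_ora)), 1e-9)
  expect_lt(max(abs(a_pkg - a_ora)), 1e-9)
  # pure function: identical across calls
  expect_identical(score_donor(p9[1:10], models),
                   score_donor(p9[1:10], models))
})

test_that("the canonical donor attains the maximum over all GT-core 9-mers", {
  models <- splice_site_models()
  all7 <- expand.grid(rep(list(c("A", "C", "G", "T")), 7),
                      stringsAsFactors = FALSE)
  seqs <- apply(all7, 1, function(r)
    paste0(r[1], r[2], r[3], "GT", r[4], r[5], r[6], r[7]))
  sc <- score_donor(seqs, models)
  expect_equal(seqs[which.max(sc)], "CAGGTAAGT")
})

test_that("model tables survive a write/load round trip with exact scores", {
  models <- splice_site_models()
  dir <- tempfile()
  write_models(models, dir)
  m2 <- load_models(dir)
  expect_equal(length(m2$donor$table), 4^7)
  set.seed(11)
  p9 <- random_seqs(200, 9); p23 <- random_seqs(200, 23)
  expect_equal(score_donor(p9, m2), score_donor(p9, models),
               tolerance = 1e-12)
  expect_equal(score_acceptor(p23, m2), score_acceptor(p23, models),
               tolerance = 1e-12)
  # load errors name the offending file / property
  file.remove(file.path(dir, "donor_table.txt"))
  expect_error(load_models(dir), "donor_table")
  expect_error(load_models(tempfile()), "directory")
})

test_that("degenerate sequences are flagged, not scored", {
  expect_true(is.na(score_donor("NNNNNNNNN")))
  expect_true(is.na(score_acceptor(paste(rep("N", 23), collapse = ""))))
  expect_error(score_donor("ACGT"), "9 nt")
  expect_error(score_acceptor("ACGT"), "23 nt")
})

test_that("a canonical acceptor outscores its base-shuffled permutations", {
  models <- splice_site_models()
  canonical <- paste0(strrep("T", 16), "CCAGGAG")
  set.seed(42)
  shuffled <- vapply(1:100, function(i)
    paste(sample(strsplit(canonical, "")[[1]]), collapse = ""),
    character(1))
  sc <- score_acceptor(shuffled, models)
  expect_gt(score_acceptor(canonical, models), stats::median(sc, na.rm = TRUE))
  # non-AG core scores very low but does not crash
  non_ag <- paste0(strrep("T", 16), "CCTTGAG")
  expect_lt(score_acceptor(non_ag, models),
            score_acceptor(canonical, models))
})

test_that("site windows are exact on both strands", {
  # 60-base genome with a donor 9-mer planted at [17,26) and an
  # acceptor 23-mer at [30,53) on the plus strand
  fa <- tempfile(fileext = ".fa")
  pre <- "AAAAACCCCCGGGGGTT"
  donor <- "CAGGTAAGT"
  mid <- "GGGG"
  acceptor <- paste0(strrep("T", 16), "CCAGGAG")
  writeLines(c(">chr1", paste0(pre, donor, mid, acceptor, "AACCGGA")), fa)
  gen <- load_genome(fa)
  models <- splice_site_models()
  # plus strand: exon ends at 20 (the 3 exonic donor bases are [17,20))
  ev <- read_rmats(write_jcec(jcec_line(c(50, 55, 5, 20, 57, 59),
                                        1e-6, -0.4)), "SE")
  rec <- score_event_sites(ev, gen, models)$records
  up <- rec[rec$site_role == "upstream_donor", ]
  expect_equal(up$sequence, donor)
  expect_equal(up$score, score_donor(donor, models))
  # skipped exon starting at 50: acceptor window [30,53)
  sk <- rec[rec$site_role == "skipped_acceptor", ]
  expect_equal(sk$sequence, acceptor)
  # a coordinate-mirrored minus-strand twin yields identical sequences
  L <- 60
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", rc(paste0(pre, donor, mid, acceptor, "AACCGGA"))),
             fa2)
  gen2 <- load_genome(fa2)
  mirror <- function(a, b) c(L - b, L - a)
  co <- c(mirror(50, 55), mirror(5, 20), mirror(57, 59))
  ev2 <- read_rmats(write_jcec(jcec_line(
    c(co[1], co[2], co[3], co[4], co[5], co[6]), 1e-6, -0.4,
    strand = "-")), "SE")
  rec2 <- score_event_sites(ev2, gen2, models)$records
  expect_equal(rec2$sequence[match(rec$site_role, rec2$site_role)],
               rec$sequence)
  expect_equal(rec2$score[match(rec$site_role, rec2$site_role)],
               rec$score)
})

test_that("planted strong sites outscore planted weak sites on the fixture", {
  l <- get_loaded()
  sc <- score_event_sites(l$sig, l$gen,
                          baseline = annotated_se_triples(l$txs))
  m <- l$manifest$se_events
  rec <- merge(sc$records, m[, c("event_key", "site_skip", "site_flank")],
               by = "event_key")
  strong_flank <- rec$score[rec$site_flank == "strong" &
                              rec$site_role %in% c("upstream_donor",
                                                   "downstream_acceptor")]
  weak_skip <- rec$score[rec$site_skip == "weak" &
                           rec$site_role %in% c("skipped_acceptor",
                                                "skipped_donor")]
  expect_gt(mean(strong_flank), mean(weak_skip))
  expect_true(all(!is.na(rec$score)))
  # aggregation conservation: per-sign means equal means of records
  neg_up <- rec$score[rec$sign == "negative" &
                        rec$site_role == "upstream_donor"]
  expect_equal(sc$means$mean_score[sc$means$sign == "negative" &
                                     sc$means$site_role == "upstream_donor"],
               mean(neg_up))
  expect_false(is.null(sc$baseline_means))
  expect_equal(unique(sc$baseline_means$sign), "annotated")
  # out-of-contig windows are excluded and counted, not fatal
  far <- read_rmats(write_jcec(jcec_line(
    c(900200, 900350, 900000, 900100, 900500, 900600), 1e-6, -0.4)), "SE")
  sc2 <- score_event_sites(far, l$gen, splice_site_models())
  expect_true(all(is.na(sc2$records$score)))
  expect_true(all(sc2$records$flagged == "out_of_bounds"))
})

test_that("retained-intron sites score the intron's own donor and acceptor", {
  l <- get_loaded()
  ri_sig <- filter_significant(l$ri)
  sc <- score_event_sites(ri_sig, l$gen,
                          baseline = annotated_introns(l$txs))
  m <- l$manifest$ri_events
  rec <- merge(sc$records, m[, c("event_key", "site")], by = "event_key")
  models <- splice_site_models()
  strong_d <- score_donor("CAGGTAAGT", models)
  expect_equal(rec$score[rec$site == "strong" &
                           rec$site_role == "ri_donor"],
               rep(strong_d, sum(m$site == "strong" & m$sign == "positive")))
  expect_gt(mean(rec$score[rec$site == "strong"]),
            mean(rec$score[rec$site == "weak"]))
})
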