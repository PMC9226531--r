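test_that("SV length filters are strict at the printed boundaries", {
  svs <- data.frame(seqid = "chr1", pos = 1,
                    svtype = "DEL", svlen = c(49, 50, 10000, 10001))
  f <- filter_svs(svs, 1e6)
  expect_equal(unname(f$report["too_short"]), 1)   # 49 bp out
  expect_equal(unname(f$report["too_long"]), 1)    # 10001 > 1% of 1 Mb
  expect_setequal(f$kept$svlen, c(50, 10000))      # boundaries kept
  expect_error(filter_svs(data.frame(seqid = "c", pos = 1, svtype = "DEL",
                                     svlen = 0), 1e6), "non-positive")
})

test_that("duplicate merging is type-aware, transitive and idempotent", {
  # identical DELs from two callers collapse
  two <- data.frame(seqid = "chr1", pos = c(100, 100), end = c(599, 599),
                    svtype = "DEL", svlen = 500,
                    caller = c("c1", "c2"), id = c("a", "b"))
  m <- merge_sv_duplicates(two)
  expect_equal(nrow(m), 1L)
  expect_match(m$merged_ids, "a.*b")
  # same locus, different type: untouched
  mixed <- data.frame(seqid = "chr1", pos = 100, end = 599,
                      svtype = c("DEL", "INV"), svlen = 500,
                      id = c("a", "b"))
  expect_equal(nrow(merge_sv_duplicates(mixed)), 2L)
  # three mutually overlapping DELs at ~98% collapse transitively
  three <- data.frame(seqid = "chr1", pos = c(100, 110, 120),
                      end = c(599, 609, 619), svtype = "DEL", svlen = 500,
                      id = c("a", "b", "c"))
  m3 <- merge_sv_duplicates(three)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$pos, 100)  # longest span tie -> smallest position
  # idempotence
  expect_equal(nrow(merge_sv_duplicates(m3)), 1L)
  # INS breakpoint window + length-ratio rule
  ins <- data.frame(seqid = "chr1", pos = c(500, 550, 900),
                    end = c(500, 550, 900), svtype = "INS",
                    svlen = c(300, 310, 300), id = c("a", "b", "c"))
  expect_equal(nrow(merge_sv_duplicates(ins)), 2L)
})

test_that("event matching applies intersection and length-similarity rules", {
  ann <- data.frame(seqid = "chr1", start = 100, end = 599, class = "2/1/1",
                    id = "te1")
  # worked case: 500 bp TE vs 550 bp DEL overlapping by 250 bp
  sv <- data.frame(seqid = "chr1", pos = 350, end = 899, svtype = "DEL",
                   svlen = 550, id = "sv1")
  ev <- match_te_events(sv, ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$intersection_bp, 250)
  expect_equal(ev$length_ratio, 500 / 550)
  # dissimilar lengths: full overlap but ratio < 0.5
  big <- data.frame(seqid = "chr1", pos = 100, end = 1299, svtype = "DEL",
                    svlen = 1200, id = "sv2")
  expect_equal(nrow(match_te_events(big, ann)), 0L)
  # identical intervals always match
  same <- data.frame(seqid = "chr1", pos = 100, end = 599, svtype = "DEL",
                     svlen = 500, id = "sv3")
  expect_equal(nrow(match_te_events(same, ann)), 1L)
  # length-ratio boundary: 0.5 passes, just under does not
  half <- data.frame(seqid = "chr1", pos = 100, end = 1099, svtype = "DEL",
                     svlen = 1000, id = "sv4")
  expect_equal(nrow(match_te_events(half, ann)), 1L)  # 500/1000 = 0.5
  under <- data.frame(seqid = "chr1", pos = 100, end = 1101, svtype = "DEL",
                      svlen = 1002, id = "sv5")
  expect_equal(nrow(match_te_events(under, ann)), 0L)
})

test_that("insertions match by breakpoint proximity and length", {
  ann <- data.frame(seqid = "chr1", start = 1000, end = 1499,
                    class = "1/2/1", id = "te1")
  ins <- data.frame(seqid = "chr1", pos = c(1100, 1599, 1601, 500),
                    end = 0, svtype = "INS", svlen = c(480, 480, 480, 480),
                    id = paste0("i", 1:4))
  ins$end <- ins$pos
  ev <- match_te_events(ins, ann)
  # inside; within the +/-100 bp window; just outside; far away
  expect_setequal(ev$sv_id, c("i1", "i2"))
  # similar breakpoint but wrong length
  short <- data.frame(seqid = "chr1", pos = 1100, end = 1100,
                      svtype = "INS", svlen = 100, id = "i5")
  expect_equal(nrow(match_te_events(short, ann)), 0L)
})

test_that("best-match flags are unique per SV", {
  ann <- data.frame(seqid = "chr1", start = c(100, 150), end = c(599, 649),
                    class = c("1/1/1", "2/1/1"), id = c("t1", "t2"))
  sv <- data.frame(seqid = "chr1", pos = 120, end = 619, svtype = "DEL",
                   svlen = 500, id = "s1")
  ev <- match_te_events(sv, ann)
  expect_equal(nrow(ev), 2L)
  expect_equal(sum(ev$best), 1L)
})

test_that("pipeline equals the all-pairs brute-force oracle", {
  set.seed(1234)
  for (rep in 1:40) {
    fx <- random_sv_fixture()
    got <- detect_events(fx$svs, fx$ann, fx$genome_len)$events
    want <- oracle_detect(fx$svs, fx$ann, fx$genome_len)
    got_keys <- sort(paste(got$sv_id, got$ann_id))
    want_keys <- sort(paste(want$sv_id, want$ann_id))
    expect_identical(got_keys, want_keys)
  }
})

test_that("event statistics reproduce the share and activity identities", {
  ann <- data.frame(seqid = "chr1",
                    start = c(1, 1001, 2001, 3001),
                    end = c(500, 1500, 2500, 3500),
                    class = c("1/1", "1/1", "2/2", "2/2"),
                    id = paste0("t", 1:4))
  events <- data.frame(sv_id = paste0("s", 1:4), ann_id = paste0("t", 1:4),
                       seqid = "chr1",
                       svtype = c("DEL", "DEL", "DEL", "INS"),
                       class = c("1/1", "1/1", "2/2", "2/2"),
                       sv_len = c(500, 500, 500, 500),
                       ann_len = 500, intersection_bp = 500,
                       length_ratio = 1, best = TRUE)
  st <- event_stats(events, ann)
  expect_equal(unname(st$svtype_share["DEL"]), 0.75)
  # equal bp shares -> relative activity 1 for both classes
  expect_equal(st$relative_activity$relative_activity, c(1, 1))
  # 20% event share vs 10% annotation share -> activity 2
  ann2 <- data.frame(seqid = "chr1", start = c(1, 1001), end = c(100, 1900),
                     class = c("2/2", "1/1"), id = c("t1", "t2"))
  ev2 <- data.frame(sv_id = c("s1", "s2"), ann_id = c("t1", "t2"),
                    seqid = "chr1", svtype = "DEL",
                    class = c("2/2", "1/1"), sv_len = c(100, 400),
                    ann_len = c(100, 900), intersection_bp = c(100, 400),
                    length_ratio = 1, best = TRUE)
  st2 <- event_stats(ev2, ann2)
  ra <- st2$relative_activity
  expect_equal(ra$relative_activity[ra$class == "2/2"], 2.0)
  # activities weighted by annotation shares average to 1
  expect_equal(sum(ra$relative_activity * ra$annotation_bp_share), 1)
  # class present in events but absent from annotations -> Inf flag
  ev3 <- ev2
  ev3$class <- c("9/9", "1/1")
  st3 <- event_stats(ev3, ann2)
  expect_true(is.infinite(
    st3$relative_activity$relative_activity[
      st3$relative_activity$class == "9/9"]))
})

test_that("SVs are read from VCF INFO fields, skipping non-SV records", {
  skip_if_not_installed("vcfR")
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="T">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="L">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="E">',
    "##contig=<ID=chr1,length=100000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", "sv1", "N", "<DEL>", ".", "PASS",
          "SVTYPE=DEL;SVLEN=-500;END=599", sep = "\t"),
    paste("chr1", "2000", "sv2", "N", "<INS>", ".", "PASS",
          "SVTYPE=INS;SVLEN=300", sep = "\t"),
    paste("chr1", "9000", "snp1", "N", "A", ".", "PASS", "DP=30",
          sep = "\t")), path)
  svs <- read_sv_vcf(path, caller = "sniffles")
  expect_equal(nrow(svs), 2L)
  expect_equal(svs$svlen, c(500, 300))      # SVLEN sign normalised
  expect_equal(svs$end, c(599, 2000))       # INS end defaults to pos
  expect_equal(unique(svs$caller), "sniffles")
})

test_that("phylogenetic regression and patristic distances are exact", {
  r <- phylo_event_regression(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$slope, 10)
  expect_equal(r$r, 1)
  flat <- phylo_event_regression(c(1, 2, 3), c(7, 7, 7))
  expect_equal(flat$slope, 0)
  expect_error(phylo_event_regression(1:2, 1:2), "at least 3")
  expect_equal(patristic_distance("(A:2,B:3);", "A", "B"), 5)
  expect_equal(patristic_distance("((A:1,B:2):3,C:4);", "A", "C"), 8)
})
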