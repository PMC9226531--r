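test_that("mask construction unions, coalesces and validates intervals", {
  m <- build_mask(data.frame(seqid = "chr1", start = c(100, 150),
                             end = c(200, 250)))
  expect_equal(m$start, 100); expect_equal(m$end, 250)
  # disjoint intervals stay; total is 1-based inclusive
  m2 <- build_mask(data.frame(seqid = "chr1", start = c(1, 20),
                              end = c(10, 30)))
  expect_equal(nrow(m2), 2L)
  expect_equal(sum(m2$end - m2$start + 1), 21)
  # nested interval disappears into the outer one
  m3 <- build_mask(data.frame(seqid = "chr1", start = c(100, 120),
                              end = c(300, 130)))
  expect_equal(nrow(m3), 1L)
  # book-ended intervals coalesce
  m4 <- build_mask(data.frame(seqid = "chr1", start = c(1, 11),
                              end = c(10, 20)))
  expect_equal(nrow(m4), 1L)
  expect_error(build_mask(data.frame(seqid = "c", start = 10, end = 5)),
               "start > end")
})

test_that("TE content is mask bp over genome bp", {
  ann <- data.frame(seqid = "chr1", start = c(1, 20), end = c(10, 30))
  expect_equal(te_content(ann, 1000), 2.1)
  mask210 <- data.frame(seqid = "chr1", start = 1, end = 210)
  expect_equal(te_content(mask210, 1000), 21.0)
  expect_equal(te_content(ann[0, ], 1000), 0)
  expect_equal(te_content(data.frame(seqid = "c", start = 1, end = 500),
                          500), 100)
  expect_error(te_content(data.frame(seqid = "c", start = 1, end = 501),
                          500), "more base pairs")
})

test_that("mask bp never exceeds summed lengths; equality iff disjoint", {
  overlapping <- data.frame(seqid = "chr1", start = c(100, 150, 400),
                            end = c(200, 250, 450))
  mask <- build_mask(overlapping)
  mask_total <- sum(mask$end - mask$start + 1)
  raw_total <- sum(overlapping$end - overlapping$start + 1)
  expect_lt(mask_total, raw_total)
  disjoint <- data.frame(seqid = "chr1", start = c(1, 100), end = c(50, 150))
  md <- build_mask(disjoint)
  expect_equal(sum(md$end - md$start + 1),
               sum(disjoint$end - disjoint$start + 1))
})

test_that("per-class stats use raw summed lengths, not the mask", {
  ann <- data.frame(seqid = "chr1", start = c(1, 101), end = c(100, 200),
                    class = "2/2")
  cs <- class_stats(ann, 1000)
  expect_equal(cs$content_percent, 20)
  expect_equal(cs$count_share, 1)
  # overlapping copies count twice for class content, once in the mask
  ov <- data.frame(seqid = "chr1", start = c(1, 51), end = c(100, 150),
                   class = "1/1")
  expect_gt(class_stats(ov, 200)$content_percent, te_content(ov, 200))
})

test_that("length percentiles follow the linear-interpolation convention", {
  ann <- data.frame(seqid = "chr1", start = c(1, 201, 501, 901),
                    end = c(100, 400, 800, 1300), class = "1/1")
  cs <- class_stats(ann, 10000)
  # lengths 100, 200, 300, 400
  expect_equal(cs$len_median, 250)
  expect_equal(cs$len_q25, 175)
  expect_equal(cs$len_q75, 325)
  expect_equal(cs$whisker_low, 175 - 1.5 * 150)
  expect_equal(cs$whisker_high, 325 + 1.5 * 150)
})

test_that("density track attributes counts to start windows and splits bp", {
  ann <- data.frame(seqid = "chr1", start = c(10, 95), end = c(59, 144))
  dt <- density_track(ann, 100, c(chr1 = 300))
  expect_equal(dt$count, c(2L, 0L, 0L))       # both start in window 1
  expect_equal(dt$covered_bp, c(56, 44, 0))   # split across the boundary
  empty <- density_track(ann[0, ], 100, c(chr1 = 300))
  expect_true(all(empty$count == 0) && all(empty$covered_bp == 0))
})

test_that("tool overlap is the asymmetric bp containment share", {
  ann <- rbind(
    data.frame(seqid = "chr1", start = 1, end = 100, tool = "A"),
    data.frame(seqid = "chr1", start = 1, end = 200, tool = "B"))
  m <- tool_overlap(ann)
  expect_equal(m["A", "B"], 1.0)
  expect_equal(m["B", "A"], 0.5)
  ident <- rbind(
    data.frame(seqid = "chr1", start = 5, end = 50, tool = "A"),
    data.frame(seqid = "chr1", start = 5, end = 50, tool = "B"))
  expect_true(all(tool_overlap(ident) == 1))
  disj <- rbind(
    data.frame(seqid = "chr1", start = 1, end = 10, tool = "A"),
    data.frame(seqid = "chr1", start = 100, end = 110, tool = "B"))
  md <- tool_overlap(disj)
  expect_equal(md["A", "B"], 0)
  expect_equal(md["B", "A"], 0)
})

test_that("TE content is monotone under adding annotations", {
  set.seed(21)
  base <- data.frame(seqid = "chr1",
                     start = sample.int(900, 5), end = 0)
  base$end <- base$start + sample(10:50, 5)
  prev <- 0
  for (i in 1:5) {
    cur <- te_content(base[1:i, ], 1000)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("GFF3 round-trip preserves coordinates, class and tool", {
  skip_if_not_installed("rtracklayer")
  ann <- data.frame(seqid = "chr1", start = c(100, 400), end = c(199, 499),
                    strand = c("+", "-"), class = c("1/1/2", "2/1/1"),
                    tool = c("toolA", "toolB"), id = c("te1", "te2"),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_te_gff3(ann, path)
  back <- read_te_gff3(path)
  back <- back[order(back$start), ]
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$class, ann$class)
  expect_equal(back$id, ann$id)
})
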