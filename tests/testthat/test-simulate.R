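test_that("sequence simulation is deterministic given the seed", {
  a <- simulate_te_sequences(n_per_class = 10, seed = 5)
  b <- simulate_te_sequences(n_per_class = 10, seed = 5)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$hits, b$hits)
  c <- simulate_te_sequences(n_per_class = 10, seed = 6)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("simulated classes carry signal in both feature families", {
  sim <- simulate_te_sequences(n_per_class = 15, seed = 2)
  # domain hits are class-specific and below the threshold
  expect_true(all(sim$hits$evalue < 5.0))
  lab_of_hit <- sim$labels[sim$hits$seq_id]
  per_dom <- tapply(lab_of_hit, sim$hits$domain_id,
                    function(l) length(unique(l)))
  expect_true(all(per_dom == 1))
  # compositional bias separates classes at the dinucleotide level
  kb <- kmer_block(sim$sequences, ks = 2L)
  centroids <- apply(kb, 2, function(col) tapply(col, sim$labels, mean))
  expect_gt(max(dist(centroids)), 0.1)
})

test_that("identical-bias control removes the class signal", {
  expect_warning(sim <- simulate_te_sequences(n_per_class = 5,
                                              bias_strength = 0, seed = 2),
                 "negative control")
  expect_equal(nrow(sim$hits), 0L)
})

test_that("genome simulation plants the requested bp exactly", {
  g <- simulate_te_genome(genome_length_bp = 100000, te_fraction = 0.21,
                          n_tes = 30, seed = 8)
  expect_equal(te_content(g$annotations, g$genome_length_bp), 21.0)
  expect_equal(nchar(unname(g$genome)), 100000L)
  # non-overlapping placement: mask bp equals summed lengths
  mask <- build_mask(g$annotations)
  expect_equal(sum(mask$end - mask$start + 1),
               sum(g$annotations$end - g$annotations$start + 1))
  # zero TEs -> empty annotation set
  g0 <- simulate_te_genome(genome_length_bp = 1000, te_lengths = integer(0),
                           seed = 1)
  expect_equal(nrow(g0$annotations), 0L)
  # infeasible packing is refused
  expect_error(simulate_te_genome(genome_length_bp = 1000,
                                  te_lengths = rep(600, 2), seed = 1),
               "exceed")
})

test_that("overlapping mode can shrink the mask below summed lengths", {
  g <- simulate_te_genome(genome_length_bp = 5000,
                          te_lengths = rep(1000, 8), overlap = TRUE,
                          seed = 4)
  mask <- build_mask(g$annotations)
  expect_lt(sum(mask$end - mask$start + 1),
            sum(g$annotations$end - g$annotations$start + 1))
})

test_that("simulated truth files round-trip through the package readers", {
  skip_if_not_installed("rtracklayer")
  g <- simulate_te_genome(genome_length_bp = 20000, te_lengths = rep(400, 5),
                          seed = 3)
  gff <- tempfile(fileext = ".gff3")
  write_te_gff3(g$annotations, gff)
  back <- read_te_gff3(gff)
  expect_equal(sort(back$start), sort(g$annotations$start))
  fa <- tempfile(fileext = ".fa")
  write_fasta(g$genome, fa)
  expect_identical(unname(read_fasta(fa)), unname(g$genome))
})

test_that("SV simulation supports decoys, duplicates and jitter", {
  g <- simulate_te_genome(genome_length_bp = 50000, te_lengths = rep(500, 8),
                          seed = 2)
  sv <- simulate_te_svs(g$annotations, n_events = 8, n_decoys = 4,
                        duplicate_copies = 2, seed = 9)
  expect_equal(nrow(sv$svs), 8 * 3 + 4)
  expect_equal(nrow(sv$truth), 8L)
  expect_true(all(sv$svs$svlen[grepl("decoy", sv$svs$id)] < 50))
  # duplicates carry the second caller
  expect_true(all(sv$svs$caller[grepl("dup", sv$svs$id)] == "caller2"))
  # determinism
  sv2 <- simulate_te_svs(g$annotations, n_events = 8, n_decoys = 4,
                         duplicate_copies = 2, seed = 9)
  expect_identical(sv$svs, sv2$svs)
})

test_that("planted events are recovered exactly by the pipeline", {
  g <- simulate_te_genome(genome_length_bp = 100000,
                          te_lengths = rep(500, 10),
                          classes = c("1/1/1", "2/1/1"), seed = 3)
  sv <- simulate_te_svs(g$annotations, n_events = 10, n_decoys = 6,
                        duplicate_copies = 1, seed = 4)
  res <- detect_events(sv$svs, g$annotations, g$genome_length_bp)
  expect_equal(unname(res$filter_report["too_short"]), 6)
  expect_equal(nrow(res$svs), 10L)          # duplicates merged
  best <- res$events[res$events$best, ]
  expect_equal(nrow(best), 10L)             # every planted event recovered
  got <- best[order(best$sv_id), c("sv_id", "ann_id")]
  want <- sv$truth[order(sv$truth$sv_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})
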