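test_that("reference generation honours length, GC and determinism", {
  cfg <- sim_config(genome_length = 100000L, gc_fraction = 0.5,
                    rng_seed = 7L)
  ref <- generate_reference(cfg)
  expect_equal(Biostrings::width(ref), 100000L)
  gc <- Biostrings::letterFrequency(ref[[1]], "GC", as.prob = TRUE)[1]
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  ref2 <- generate_reference(cfg)
  expect_identical(as.character(ref[[1]]), as.character(ref2[[1]]))

  expect_error(sim_config(genome_length = 0), "positive")
  cfg2 <- sim_config(genome_length = 50000L, gc_fraction = 0.3,
                     rng_seed = 2L)
  gc2 <- Biostrings::letterFrequency(generate_reference(cfg2)[[1]], "GC",
                                     as.prob = TRUE)[1]
  expect_lt(abs(gc2 - 0.3), 0.02)
})

test_that("planted sites follow the geometric occupancy decay and degrade
          the seed PAM-distal first", {
  cfg <- tiny_config(n_offtargets = 4L,
                     mismatch_distribution = c(`0` = 1L, `2` = 1L,
                                               `4` = 1L, `8` = 1L),
                     occupancy_max = 0.8)
  ex <- tiny_experiment(cfg)
  truth <- ex$truth
  on <- truth[truth$mismatch_count == 0L, ]
  expect_equal(on$seed_match_length, 20L)
  expect_equal(on$occupancy, 0.8)
  # closed form of the decay rule
  m8 <- truth[truth$mismatch_count == 8L, ]
  expect_equal(m8$occupancy, 0.8 * 0.65^8, tolerance = 1e-12)
  expect_equal(truth$seed_match_length, 20L - truth$mismatch_count)
  # occupancy non-increasing in mismatch count
  o <- order(truth$mismatch_count)
  expect_true(all(diff(truth$occupancy[o]) <= 1e-12))
})

test_that("planted sites are recovered by the homology scanner with exact
          mismatch counts and strands", {
  ex <- tiny_experiment(tiny_config(
    n_offtargets = 5L,
    mismatch_distribution = c(`0` = 1L, `1` = 1L, `2` = 1L, `3` = 1L,
                              `4` = 1L)))
  peaks <- data.frame(chrom = ex$truth$chrom,
                      start = pmax(0L, ex$truth$start - 50L),
                      end = ex$truth$end + 50L)
  hits <- scan_peaks(peaks, ex$reference, ex$guide, min_score = 20L)
  expect_equal(nrow(hits), nrow(ex$truth))
  expect_equal(hits$start, ex$truth$start)
  expect_equal(hits$strand, ex$truth$strand)
  expect_equal(20L - hits$matches, ex$truth$mismatch_count)
  expect_equal(hits$seed_match_length, ex$truth$seed_match_length)
})

test_that("simulated conversions match the binomial expectation at depth", {
  cfg <- tiny_config(genome_length = 20000L, n_offtargets = 1L,
                     mismatch_distribution = c(`0` = 1L),
                     background_depth = 600, enrichment_factor = 20,
                     sequencing_error = 0, occupancy_max = 0.5,
                     rng_seed = 5L)
  # single on-target with truth 0.8 at -16 only
  editor <- editor_profile("toy-CBE", "C", "T",
                           nts_window = c(`-16` = 0.8))
  ex <- tiny_experiment(cfg, editor = editor)
  reads <- simulate_reads(ex$reference, ex$truth, editor, "pulldown",
                          "plus", config = cfg, seed = 11L)
  s <- ex$truth
  spans <- data.frame(chrom = s$chrom, start = s$start - 65L,
                      end = s$end + 65L)
  pile <- pileup(reads, spans, ex$reference)
  prof <- pam_relative_profile(s, pile, editor)
  at16 <- prof[prof$frame == "NTS" & prof$position == -16L, ]
  expect_true(at16$ref_is_substrate)
  expected <- 0.5 * 0.8
  sd3 <- 3 * sqrt(expected * (1 - expected) / at16$depth)
  expect_gt(at16$depth, 500)
  expect_lt(abs(at16$freq - expected), sd3)
})

test_that("minus-gRNA and zero-dose conditions carry no targeted edits", {
  ex <- tiny_experiment()
  cfg <- ex$config
  null_reads <- simulate_reads(ex$reference, ex$truth, ex$editor,
                               "pulldown", "minus", config = cfg,
                               seed = 21L)
  spans <- data.frame(chrom = ex$truth$chrom,
                      start = pmax(0L, ex$truth$start - 65L),
                      end = ex$truth$end + 65L)
  pile <- pileup(null_reads, spans, ex$reference)
  covered <- pile[pile$depth >= 10L, ]
  mm_freq <- 1 - mapply(function(r, i) covered[[r]][i], covered$ref,
                        seq_len(nrow(covered))) / covered$depth
  # null purity: mismatch frequency bounded by sequencing error
  expect_true(all(mm_freq <= 3 * cfg$sequencing_error + 3 / covered$depth))

  zero_dose <- simulate_reads(ex$reference, ex$truth, ex$editor,
                              "pulldown", "plus", dose_scalar = 0,
                              config = cfg, seed = 22L)
  # zero dose: no enrichment in expectation
  expected_bg <- cfg$background_depth / 1000 *
    (cfg$genome_length - cfg$read_length + 1)
  expect_lt(abs(nrow(zero_dose) - expected_bg), 4 * sqrt(expected_bg))
})

test_that("read counts are conserved and output is deterministic", {
  ex <- tiny_experiment()
  cfg <- ex$config
  r1 <- simulate_reads(ex$reference, ex$truth, ex$editor, "pulldown",
                       "plus", config = cfg, seed = 31L)
  r2 <- simulate_reads(ex$reference, ex$truth, ex$editor, "pulldown",
                       "plus", config = cfg, seed = 31L)
  expect_identical(r1, r2)

  lambda_bp <- cfg$background_depth / 1000
  expected <- lambda_bp * (cfg$genome_length - cfg$read_length + 1)
  for (i in seq_len(nrow(ex$truth))) {
    w_lo <- max(0L, ex$truth$start[i] - cfg$read_length + 1L)
    w_hi <- min(cfg$genome_length - cfg$read_length, ex$truth$end[i] - 1L)
    expected <- expected + lambda_bp * (w_hi - w_lo + 1L) *
      cfg$enrichment_factor * ex$truth$occupancy[i]
  }
  expect_lt(abs(nrow(r1) - expected), 3 * sqrt(expected))
})

test_that("amplicon tables follow the occupancy proportionality", {
  ex <- tiny_experiment()
  ident <- simulate_amplicon_table(ex$truth, occupancy_scaling = 1,
                                   noise_sd = 0, seed = 3L)
  expect_equal(ident$amplicon_freq, ident$rloop_freq)

  toy <- simulate_amplicon_table(rloop_freq = 0.5,
                                 occupancy_scaling = 0.66, noise_sd = 0,
                                 seed = 3L)
  expect_equal(toy$amplicon_freq, 0.33)

  set.seed(9)
  tab <- simulate_amplicon_table(rloop_freq = runif(50, 0.05, 0.9),
                                 occupancy_scaling = 0.84,
                                 noise_sd = 0.02, seed = 41L)
  fit <- fit_occupancy(tab)
  expect_lt(abs(fit$scaling - 0.84), 0.03)

  expect_error(simulate_amplicon_table(rloop_freq = 0.5,
                                       occupancy_scaling = 0), "0, 1")
})
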