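toy_reference <- function(seq, contig = "chrT") {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- contig
  ref
}

toy_reads <- function(seqs, starts, L, contig = "chrT") {
  rs <- data.frame(chrom = contig, start = as.integer(starts),
                   width = nchar(seqs), strand = "+", seq = seqs,
                   qname = sprintf("r%d", seq_along(seqs)),
                   stringsAsFactors = FALSE)
  rs <- rs[order(rs$start), ]
  attr(rs, "seqlengths") <- stats::setNames(as.integer(L), contig)
  class(rs) <- c("read_set", "data.frame")
  rs
}

test_that("pileup tallies substitutions and reports missing depth as NA
          frequencies", {
  ref <- toy_reference("AACGTACGTA")
  reads <- toy_reads(rep("AATGT", 100), rep(0L, 100), 10L)
  p <- pileup(reads, data.frame(chrom = "chrT", start = 0L, end = 10L),
              ref)
  at2 <- p[p$pos == 2L, ]
  expect_equal(at2$ref, "C")
  expect_equal(at2$T, 100L)
  expect_equal(at2$depth, 100L)
  # positions with no reads have zero depth (frequency undefined, not 0)
  expect_equal(p$depth[p$pos >= 5L], rep(0L, 5))
  expect_true(all(rowSums(p[, c("A", "C", "G", "T")]) == p$depth))
})

test_that("pileup agrees with a per-read recount oracle", {
  ex <- tiny_experiment(tiny_config(genome_length = 20000L,
                                    background_depth = 30))
  reads <- simulate_reads(ex$reference, ex$truth, ex$editor, "pulldown",
                          "plus", config = ex$config, seed = 101L)
  iv <- data.frame(chrom = ex$truth$chrom[1],
                   start = ex$truth$start[1] - 60L,
                   end = ex$truth$end[1] + 10L)
  p <- pileup(reads, iv, ex$reference)
  oracle <- oracle_pileup(reads, iv$start, iv$end - 1L)
  for (i in seq_len(nrow(p))) {
    key <- as.character(p$pos[i])
    counts <- if (key %in% names(oracle)) oracle[[key]] else
      c(A = 0L, C = 0L, G = 0L, T = 0L)
    expect_equal(unlist(p[i, c("A", "C", "G", "T")]), counts,
                 ignore_attr = TRUE)
  }
})

test_that("PAM-relative coordinates map plus- and minus-strand sites
          symmetrically", {
  # plus-strand site: genomic C>T at 16 bp 5' of the PAM -> NTS -16
  g16 <- becaskas:::pam_relative_to_genomic(-16L, 100L, "+")
  expect_equal(g16, 104L)
  expect_equal(becaskas:::pam_relative_to_genomic(-1L, 100L, "+"), 119L)
  expect_equal(becaskas:::pam_relative_to_genomic(1L, 100L, "+"), 120L)
  # minus-strand site mirrors
  expect_equal(becaskas:::pam_relative_to_genomic(-1L, 100L, "-"), 103L)
  expect_equal(becaskas:::pam_relative_to_genomic(-16L, 100L, "-"), 118L)
})

test_that("the full profile pipeline is invariant under reverse
          complementation", {
  cfg <- tiny_config(genome_length = 20000L, n_offtargets = 1L,
                     mismatch_distribution = c(`0` = 1L),
                     background_depth = 120, sequencing_error = 0.002)
  ex <- tiny_experiment(cfg)
  reads <- simulate_reads(ex$reference, ex$truth, ex$editor, "pulldown",
                          "plus", config = cfg, seed = 111L)
  L <- cfg$genome_length
  site <- ex$truth[1, ]
  spans <- data.frame(chrom = site$chrom, start = site$start - 65L,
                      end = site$end + 65L)
  prof <- pam_relative_profile(site, pileup(reads, spans, ex$reference),
                               ex$editor)

  rc_ref <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(ex$reference[[1]]))
  names(rc_ref) <- site$chrom
  m_reads <- mirror_reads(reads, L)
  m_site <- mirror_truth(site, L)
  m_spans <- data.frame(chrom = site$chrom, start = m_site$start - 65L,
                        end = m_site$end + 65L)
  m_prof <- pam_relative_profile(m_site,
                                 pileup(m_reads, m_spans, rc_ref),
                                 ex$editor)
  # exact equality of counts position by position, frame by frame
  expect_equal(m_prof$depth, prof$depth)
  expect_equal(m_prof$alt, prof$alt)
  expect_equal(m_prof$ref_is_substrate, prof$ref_is_substrate)
})

test_that("ABE sites show no target-strand signal", {
  cfg <- tiny_config(genome_length = 20000L, n_offtargets = 1L,
                     mismatch_distribution = c(`0` = 1L),
                     background_depth = 150, sequencing_error = 0)
  abe <- abe8e_profile()
  ex <- tiny_experiment(cfg, editor = abe)
  reads <- simulate_reads(ex$reference, ex$truth, abe, "pulldown",
                          "plus", config = cfg, seed = 121L)
  site <- ex$truth[1, ]
  spans <- data.frame(chrom = site$chrom, start = site$start - 65L,
                      end = site$end + 65L)
  prof <- pam_relative_profile(site, pileup(reads, spans, ex$reference),
                               abe)
  ts <- prof[prof$frame == "TS", ]
  expect_true(all(ts$freq[!is.na(ts$freq)] == 0))
  nts17 <- prof[prof$frame == "NTS" & prof$position == -17L, ]
  expect_gt(nts17$freq, 0.3)
})

test_that("edit calling enforces depth, frequency and q thresholds and is
          calibrated under the null", {
  ref <- toy_reference(strrep("ACGT", 25))
  # depth 1000, alt 300 at a C -> called
  reads <- toy_reads(c(rep("ATGT", 300), rep("ACGT", 700)), rep(0L, 1000),
                     100L)
  p <- pileup(reads, data.frame(chrom = "chrT", start = 0L, end = 4L), ref)
  calls <- call_edits(p, error_rate = 0.01)
  expect_true(any(calls$pos == 1L & calls$alt == "T"))

  # depth below min_depth is never called
  reads2 <- toy_reads(rep("ATGT", 10), rep(0L, 10), 100L)
  p2 <- pileup(reads2, data.frame(chrom = "chrT", start = 0L, end = 4L),
               ref)
  expect_equal(nrow(call_edits(p2, error_rate = 0.01)), 0L)

  # null: error-only reads produce (almost) no calls
  cfg <- tiny_config(n_offtargets = 1L,
                     mismatch_distribution = c(`0` = 1L),
                     background_depth = 400, sequencing_error = 0.005)
  exn <- tiny_experiment(cfg)
  nullr <- simulate_reads(exn$reference, exn$truth, exn$editor,
                          "pulldown", "minus", config = cfg, seed = 131L)
  pv <- pileup(nullr, data.frame(chrom = exn$truth$chrom[1], start = 1000L,
                                 end = 4000L), exn$reference)
  nullcalls <- call_edits(pv, error_rate = 0.005)
  tested <- sum(pv$depth >= 20L & pv$ref %in% c("C", "G"))
  expect_lte(nrow(nullcalls), max(2L, 0.05 * 0.05 * tested))
})

test_that("context spectra are normalised and expose the 5'TC preference", {
  ref <- toy_reference(paste0(strrep("GATCA", 20), strrep("TTCAG", 10)))
  calls <- data.frame(chrom = "chrT",
                      pos = seq(3L, 98L, by = 5L),  # every TC context C
                      ref = "C", alt = "T", frame = "NTS",
                      stringsAsFactors = FALSE)
  cs <- context_spectrum(calls, ref, flank = 3L)
  expect_equal(unname(colSums(cs$context)), rep(1, 7), tolerance = 1e-9)
  expect_equal(sum(cs$spectrum), nrow(calls))
  expect_equal(unname(cs$spectrum["C>T"]), nrow(calls))
  # all calls have T at offset -1
  expect_equal(cs$context["T", "-1"], 1)

  bg <- data.frame(chrom = "chrT", start = 0L, end = 150L)
  cs2 <- context_spectrum(calls, ref, flank = 3L,
                          background_intervals = bg)
  expect_gt(cs2$fiveprime_enrichment["T"], 1)
})

test_that("periodicity detection recovers a planted helical period and
          stays silent on flat profiles", {
  positions <- -60:-31
  make_profile <- function(freq) {
    data.frame(position = positions, frame = "NTS", pos_genomic = NA,
               ref_is_substrate = TRUE, depth = 100L,
               alt = round(100 * freq), freq = freq)
  }
  set.seed(8)
  cosine <- 0.1 + 0.05 * cos(2 * pi * (positions + 38) / 10.5) +
    rnorm(30, 0, 0.005)
  det <- detect_periodicity(make_profile(pmax(cosine, 0)))
  expect_true(det$significant)
  expect_true(det$period %in% c(10L, 11L))

  flat <- detect_periodicity(make_profile(rep(0.1, 30)))
  expect_false(flat$significant)

  expect_error(detect_periodicity(make_profile(cosine), range = -40:-31),
               "twice")
})

test_that("the default CBE profile carries its out-of-protospacer maxima
          through simulation", {
  cfg <- tiny_config(genome_length = 20000L, n_offtargets = 1L,
                     mismatch_distribution = c(`0` = 1L),
                     background_depth = 400, enrichment_factor = 10,
                     sequencing_error = 0, occupancy_max = 1,
                     rng_seed = 29L)
  # amplified periodic band so the recovered signal is clearly resolved
  ed <- editor_profile("CBE-strong-band", "C", "T",
                       nts_window = becaskas:::periodic_band(
                         amplitude = 0.6, damping = 1))
  ex <- tiny_experiment(cfg, editor = ed)
  reads <- simulate_reads(ex$reference, ex$truth, ed, "pulldown", "plus",
                          config = cfg, seed = 141L)
  site <- ex$truth[1, ]
  spans <- data.frame(chrom = site$chrom, start = site$start - 65L,
                      end = site$end + 65L)
  prof <- pam_relative_profile(site, pileup(reads, spans, ex$reference),
                               ed)
  det <- detect_periodicity(prof)
  expect_true(det$significant)
  expect_true(det$period %in% c(10L, 11L, 12L))
  # local maxima near the planted -38, -49, -60 (where a substrate C
  # exists the peak must fall within +/-2 of a planted maximum)
  near <- vapply(det$maxima, function(m) {
    min(abs(m - c(-38, -49, -60)))
  }, numeric(1))
  expect_true(any(near <= 2))
})

test_that("site ranking orders by maximal conversion and clamps n", {
  mk <- function(f16, total) {
    data.frame(position = c(-17L, -16L, -15L), frame = "NTS",
               pos_genomic = NA, ref_is_substrate = TRUE, depth = 100L,
               alt = NA_integer_,
               freq = c(total / 2, f16, total / 2))
  }
  profs <- list(a = mk(0.5, 0.2), b = mk(0.8, 0.1), c = mk(0.5, 0.4))
  top <- top_edited_sites(profs, n = 100L)
  expect_equal(top$ranking$site, c("b", "c", "a"))
  expect_equal(nrow(top$matrix), 3L)
  top2 <- top_edited_sites(profs, n = 2L)
  expect_equal(rownames(top2$matrix), c("b", "c"))
})

test_that("aggregate profiles keep pooled and per-site conventions
          consistent", {
  p1 <- data.frame(position = c(-16L, -15L), frame = "NTS",
                   pos_genomic = NA, ref_is_substrate = TRUE,
                   depth = c(100L, 100L), alt = c(50L, 10L),
                   freq = c(0.5, 0.1))
  p2 <- data.frame(position = c(-16L, -15L), frame = "NTS",
                   pos_genomic = NA, ref_is_substrate = TRUE,
                   depth = c(300L, 300L), alt = c(30L, 30L),
                   freq = c(0.1, 0.1))
  agg <- aggregate_profiles(list(p1, p2))
  expect_equal(agg$mean_of_sites[agg$position == -16L], 0.3)
  expect_equal(agg$pooled[agg$position == -16L], 80 / 400)
  # pooled ratio equals recomputed sum(alt)/sum(depth) everywhere
  expect_equal(agg$pooled, (p1$alt + p2$alt) / (p1$depth + p2$depth))
})
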