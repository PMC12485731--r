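embed_site <- function(core, L = 400L, at = 200L, seed = 1L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = "")
  substr(s, at + 1L, at + nchar(core)) <- core
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- "chrT"
  ref
}

test_that("a perfect protospacer+PAM hit scores 40 with a full seed", {
  g <- hek4_guide()
  ref <- embed_site(paste0(g$protospacer, "AGG"))
  peaks <- data.frame(chrom = "chrT", start = 150L, end = 280L)
  hits <- scan_peaks(peaks, ref, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 40L)
  expect_equal(hits$seed_match_length, 20L)
  expect_equal(hits$start, 200L)
  expect_equal(hits$strand, "+")
})

test_that("mismatch scoring follows the +2/-3 formula", {
  g <- hek4_guide()
  proto <- strsplit(g$protospacer, "")[[1]]
  # 3 PAM-distal mismatches -> 17 matches, score 2*17 - 3*3 = 25
  for (j in 1:3) proto[j] <- setdiff(c("A", "C", "G", "T"), proto[j])[1]
  ref <- embed_site(paste0(paste(proto, collapse = ""), "TGG"), seed = 2L)
  hits <- scan_peaks(data.frame(chrom = "chrT", start = 150L, end = 280L),
                     ref, g, min_score = 20L)
  expect_equal(hits$score, 2L * 17L - 3L * 3L)
  expect_equal(hits$matches, 17L)
  expect_equal(hits$seed_match_length, 17L)
  expect_equal(hits$mismatch_positions, "-20,-19,-18")
})

test_that("the PAM acts as a gate and relaxes under NRN", {
  g_ngg <- hek4_guide("NGG")
  g_nrn <- hek4_guide("NRN")
  ref <- embed_site(paste0(g_ngg$protospacer, "ATT"), seed = 3L)
  peaks <- data.frame(chrom = "chrT", start = 150L, end = 280L)
  expect_equal(nrow(scan_peaks(peaks, ref, g_ngg)), 0L)
  # ATT: A matches N, T does not match R -> still no NRN hit
  expect_equal(nrow(scan_peaks(peaks, ref, g_nrn)), 0L)
  ref2 <- embed_site(paste0(g_ngg$protospacer, "TAT"), seed = 3L)
  expect_equal(nrow(scan_peaks(peaks, ref2, g_ngg)), 0L)
  expect_equal(nrow(scan_peaks(peaks, ref2, g_nrn)), 1L)
})

test_that("the scanner agrees with the naive all-window oracle on random
          peaks", {
  g <- hek4_guide()
  set.seed(23)
  for (i in 1:100) {
    L <- sample(80:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    # half the peaks get a degraded protospacer planted
    if (i %% 2 == 0) {
      proto <- strsplit(g$protospacer, "")[[1]]
      nmm <- sample(0:6, 1)
      if (nmm > 0) {
        at <- sample(1:20, nmm)
        for (j in at) proto[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 proto[j]), 1)
      }
      core <- paste0(paste(proto, collapse = ""),
                     sample(c("AGG", "TGG", "CGG", "GGG"), 1))
      pos <- sample(0:(L - 23L), 1)
      substr(s, pos + 1L, pos + 23L) <- core
    }
    ref <- Biostrings::DNAStringSet(s)
    names(ref) <- "chrT"
    hits <- scan_peaks(data.frame(chrom = "chrT", start = 0L, end = L),
                       ref, g, min_score = -100L, flank = 0L)
    oracle <- oracle_scan(s, g$protospacer, g$pam_pattern)
    if (is.null(oracle)) {
      expect_equal(nrow(hits), 0L)
    } else {
      expect_equal(nrow(hits), 1L)
      expect_equal(hits$score, oracle$score)
      expect_equal(hits$start, oracle$offset)
      expect_equal(hits$strand, oracle$strand)
      expect_equal(hits$seed_match_length, oracle$seed)
    }
  }
})

test_that("scanning the reverse complement flips the strand only", {
  g <- hek4_guide()
  ref <- embed_site(paste0(g$protospacer, "AGG"), L = 300L, at = 120L,
                    seed = 4L)
  rc <- Biostrings::reverseComplement(ref[[1]])
  ref_rc <- Biostrings::DNAStringSet(rc)
  names(ref_rc) <- "chrT"
  h1 <- scan_peaks(data.frame(chrom = "chrT", start = 0L, end = 300L),
                   ref, g, flank = 0L)
  h2 <- scan_peaks(data.frame(chrom = "chrT", start = 0L, end = 300L),
                   ref_rc, g, flank = 0L)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 300L - h1$end)
})

test_that("the PWM is normalised and concentrates where hits agree", {
  g <- hek4_guide()
  set.seed(6)
  # hits sharing the PAM-adjacent 5-mer but random distal bases
  seed5 <- substr(g$protospacer, 16L, 20L)
  seqs <- replicate(40, paste0(
    paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
          collapse = ""), seed5))
  hits <- data.frame(protospacer_seq = seqs, stringsAsFactors = FALSE)
  class(hits) <- c("homology_hits", "data.frame")
  pwm <- build_pwm(hits)
  expect_equal(unname(colSums(pwm)), rep(1, 20), tolerance = 1e-9)
  info <- pwm_information(pwm)
  expect_gt(mean(info[16:20]), mean(info[1:15]) + 0.5)

  # single hit: each column peaks at the hit base, at (1 + 0.5) / 3
  # given the 0.5 pseudocount
  one <- hits[1, , drop = FALSE]
  pwm1 <- build_pwm(one)
  hit_bases <- strsplit(one$protospacer_seq, "")[[1]]
  for (j in 1:20) {
    expect_equal(pwm1[hit_bases[j], j], 1.5 / 3)
    expect_equal(names(which.max(pwm1[, j])), hit_bases[j])
  }
  expect_equal(unname(colSums(pwm1)), rep(1, 20), tolerance = 1e-9)
})

test_that("seed rank curves count cumulative edited sites per class", {
  sites <- data.frame(seed_match_length = c(20L, 12L, 9L, 6L),
                      edited = TRUE,
                      edit_strength = c(0.9, 0.7, 0.5, 0.3))
  rc <- seed_rank_curves(sites)
  expect_equal(rc$all, 1:4)
  expect_equal(max(rc$seed11), 2L)
  expect_equal(max(rc$seed8), 3L)
  # containment: total curve dominates threshold curves everywhere
  expect_true(all(rc$all >= rc$seed8 & rc$seed8 >= rc$seed11))

  same <- data.frame(seed_match_length = 20L, edited = TRUE,
                     edit_strength = c(3, 2, 1))
  rc2 <- seed_rank_curves(same)
  expect_equal(rc2$all, rc2$seed8)
  expect_equal(rc2$all, rc2$seed11)
})

test_that("motif occurrence matches an enumeration oracle on a random
          genome", {
  g <- guide_spec("AAAAAAAAAAAAAAACCCCC", "NGG")
  cfg <- sim_config(genome_length = 60000L, rng_seed = 19L)
  ref <- generate_reference(cfg)
  peaks <- data.frame(chrom = names(ref),
                      start = seq(0L, 49000L, by = 1000L))
  peaks$end <- peaks$start + 1000L
  mo <- motif_occurrence(peaks, ref, g, n_background = 200L, seed = 5L)
  expect_equal(mo$motif, "CCCCCNGG")
  # enumeration oracle: per-window motif presence by direct string scan
  refseq <- as.character(ref[[1]])
  oracle_hit <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- substr(refseq, peaks$start[i] + 1L, peaks$end[i])
    found <- FALSE
    for (str in c(s, paste(rev(unname(
      c(A = "T", C = "G", G = "C", T = "A")[strsplit(s, "")[[1]]])),
      collapse = ""))) {
      b <- strsplit(str, "")[[1]]
      for (o in seq_len(length(b) - 7L)) {
        if (all(b[o:(o + 4L)] == "C") && b[o + 6L] == "G" &&
            b[o + 7L] == "G") {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    found
  }, logical(1))
  expect_equal(mo$peak_fraction, mean(oracle_hit))

  # peaks that all contain the motif give fraction 1
  s2 <- as.character(ref[[1]])
  for (at in c(100L, 1100L, 2100L)) {
    substr(s2, at, at + 7L) <- "CCCCCAGG"
  }
  ref2 <- Biostrings::DNAStringSet(s2)
  names(ref2) <- names(ref)
  peaks2 <- data.frame(chrom = names(ref), start = c(0L, 1000L, 2000L),
                       end = c(1000L, 2000L, 3000L))
  mo2 <- motif_occurrence(peaks2, ref2, g, n_background = 50L, seed = 6L)
  expect_equal(mo2$peak_fraction, 1)
})
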