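# Shared fixtures and independent brute-force oracles. Oracles are written
# naively (nested loops, no shared code with the package internals) so they
# can stand as independent references for the optimised implementations.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(genome_length = 30000L, gc_fraction = 0.5,
                   n_offtargets = 3L,
                   mismatch_distribution = c(`0` = 1L, `2` = 1L, `4` = 1L),
                   read_length = 100L, background_depth = 40,
                   enrichment_factor = 20, sequencing_error = 0.002,
                   occupancy_max = 0.8, rng_seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

tiny_experiment <- function(cfg = tiny_config(), editor = cbe_ebe_profile(),
                            guide = hek4_guide()) {
  ref0 <- generate_reference(cfg)
  planted <- plant_offtargets(ref0, guide, cfg, editor)
  planted$config <- cfg
  planted$editor <- editor
  planted$guide <- guide
  planted
}

random_read_set <- function(n, L, rl = 50L, contig = "chrT", seed = 1L) {
  set.seed(seed)
  starts <- sort(sample.int(L - rl + 1L, n, replace = TRUE) - 1L)
  rs <- data.frame(chrom = contig, start = starts, width = rl,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   seq = strrep("A", rl),
                   qname = sprintf("r%d", seq_len(n)),
                   stringsAsFactors = FALSE)
  attr(rs, "seqlengths") <- stats::setNames(L, contig)
  class(rs) <- c("read_set", "data.frame")
  rs
}

# histogram oracle for bin_counts: 5' position, integer division
oracle_bin <- function(reads, L, bin_width) {
  nb <- ceiling(L / bin_width)
  cnt <- integer(nb)
  for (i in seq_len(nrow(reads))) {
    p5 <- if (reads$strand[i] == "-") {
      reads$start[i] + reads$width[i] - 1L
    } else reads$start[i]
    b <- min(p5 %/% bin_width + 1L, nb)
    cnt[b] <- cnt[b] + 1L
  }
  cnt
}

# per-read recount oracle for pileup
oracle_pileup <- function(reads, lo, hi) {
  counts <- list()
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(reads$seq[i], "")[[1]]
    for (j in seq_along(b)) {
      p <- reads$start[i] + j - 1L
      if (p < lo || p > hi) next
      key <- as.character(p)
      if (is.null(counts[[key]])) {
        counts[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      }
      counts[[key]][b[j]] <- counts[[key]][b[j]] + 1L
    }
  }
  counts
}

# naive all-window protospacer scorer: every offset, both strands,
# explicit base-by-base comparison and PAM membership table
oracle_scan <- function(seq, protospacer, pam_pattern,
                        match_score = 2L, mismatch_penalty = 3L) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pr <- strsplit(protospacer, "")[[1]]
  pm <- strsplit(pam_pattern, "")[[1]]
  best <- NULL
  for (strand in c("+", "-")) {
    s <- strsplit(seq, "")[[1]]
    if (strand == "-") s <- rev(unname(comp[s]))
    L <- length(s)
    for (o in seq_len(L - 22L)) {
      pam_ok <- TRUE
      for (k in 1:3) {
        if (!(s[o + 19L + k] %in% iupac[[pm[k]]])) { pam_ok <- FALSE; break }
      }
      if (!pam_ok) next
      matches <- 0L
      last_mm <- 0L
      for (k in 1:20) {
        if (s[o + k - 1L] == pr[k]) matches <- matches + 1L
        else last_mm <- k
      }
      score <- match_score * matches - mismatch_penalty * (20L - matches)
      seed <- 20L - last_mm
      off_plus <- if (strand == "+") o - 1L else L - (o + 22L)
      cand <- list(score = score, seed = seed, strand = strand,
                   offset = off_plus, matches = matches)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$seed > best$seed) ||
          (cand$score == best$score && cand$seed == best$seed &&
           cand$offset < best$offset)) {
        best <- cand
      }
    }
  }
  best
}

# mirror a read set onto the reverse-complemented reference
mirror_reads <- function(reads, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  out <- reads
  out$start <- L - (reads$start + reads$width)
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  out$seq <- vapply(reads$seq, rc, character(1), USE.NAMES = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  attr(out, "seqlengths") <- attr(reads, "seqlengths")
  class(out) <- c("read_set", "data.frame")
  out
}

mirror_truth <- function(truth, L) {
  out <- truth
  out$start <- L - truth$end
  out$end <- L - truth$start
  out$strand <- ifelse(truth$strand == "+", "-", "+")
  out
}
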