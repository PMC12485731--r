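#' Scan peaks for gRNA protospacer homology
#'
#' Exhaustive ungapped scan of every position and both strands of each peak
#' sequence (peak plus a 30 bp flank on each side) for a 20-mer followed by
#' a PAM-pattern match. Scoring is +2 per match, -3 per mismatch over the
#' 20 protospacer positions; the PAM is a hard gate, not scored. The best
#' hit per peak is retained if its score reaches `min_score`; ties are
#' broken by greater PAM-adjacent seed match length, then leftmost position.
#'
#' @param peaks data frame with chrom, start, end (0-based half-open).
#' @param reference DNAStringSet.
#' @param guide a [guide_spec()].
#' @param min_score minimum alignment score, default 20 (>= 16 matches).
#' @param flank bp of sequence added on each side of the peak.
#' @return A `homology_hits` data frame: peak_id, chrom, start, end (the
#'   protospacer+PAM footprint), strand, score, matches, mismatch_positions
#'   (comma-separated PAM-relative coordinates), seed_match_length,
#'   protospacer_seq, pam_seq.
#' @export
scan_peaks <- function(peaks, reference, guide, min_score = 20L,
                       flank = 30L) {
  stopifnot(is(guide, "guide_spec"))
  refseq <- setNames(as.character(reference), names(reference))
  sl <- setNames(nchar(refseq), names(refseq))
  hits <- NULL
  for (i in seq_len(nrow(peaks))) {
    ctg <- peaks$chrom[i]
    if (!ctg %in% names(sl) || peaks$start[i] < 0 ||
        peaks$end[i] > sl[[ctg]]) {
      stop("peak ", i, " (", ctg, ":", peaks$start[i], "-", peaks$end[i],
           ") lies outside the reference")
    }
    lo <- max(0L, peaks$start[i] - flank)
    hi <- min(sl[[ctg]], peaks$end[i] + flank)
    seq <- substr(refseq[[ctg]], lo + 1L, hi)
    best <- best_hit_in_sequence(seq, guide)
    if (is.null(best) || best$score < min_score) next
    hits <- rbind(hits, data.frame(
      peak_id = if ("name" %in% names(peaks)) peaks$name[i] else
        sprintf("peak_%d", i),
      chrom = ctg,
      start = lo + best$offset,
      end = lo + best$offset + 23L,
      strand = best$strand,
      score = best$score,
      matches = best$matches,
      mismatch_positions = best$mismatch_positions,
      seed_match_length = best$seed,
      protospacer_seq = best$proto_seq,
      pam_seq = best$pam_seq,
      stringsAsFactors = FALSE))
  }
  if (is.null(hits)) {
    hits <- data.frame(peak_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), score = integer(0),
                       matches = integer(0),
                       mismatch_positions = character(0),
                       seed_match_length = integer(0),
                       protospacer_seq = character(0),
                       pam_seq = character(0), stringsAsFactors = FALSE)
  }
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

# Best protospacer+PAM hit within one sequence, both strands.
# Returns offset (0-based, on the given sequence's plus strand, start of the
# 23 bp footprint), strand, score, seed length, sequences.
best_hit_in_sequence <- function(seq, guide,
                                 match_score = 2L, mismatch_penalty = 3L) {
  L <- nchar(seq)
  if (L < 23L) return(NULL)
  proto <- strsplit(guide$protospacer, "")[[1]]
  pam <- guide$pam_pattern
  sb <- strsplit(seq, "")[[1]]
  best <- NULL
  consider <- function(cand, best) {
    if (is.null(best)) return(cand)
    if (cand$score > best$score) return(cand)
    if (cand$score == best$score) {
      if (cand$seed > best$seed) return(cand)
      if (cand$seed == best$seed && cand$offset < best$offset) return(cand)
    }
    best
  }
  for (strand in c("+", "-")) {
    bases <- if (strand == "+") sb else rev(unname(COMPLEMENT[sb]))
    n_off <- L - 23L + 1L
    if (n_off < 1L) next
    # matches per offset, vectorised over the 20 protospacer positions
    m <- integer(n_off)
    for (k in 1:20) {
      m <- m + (bases[k:(k + n_off - 1L)] == proto[k])
    }
    pam_ok <- vapply(seq_len(n_off), function(o) {
      all(iupac_match(bases[(o + 20L):(o + 22L)],
                      strsplit(pam, "")[[1]]))
    }, logical(1))
    scores <- match_score * m - mismatch_penalty * (20L - m)
    ok <- which(pam_ok)
    for (o in ok) {
      window <- bases[o:(o + 19L)]
      mism <- which(window != proto)
      # PAM-relative coordinates: protospacer index j -> position j - 21
      seed <- if (length(mism)) 20L - max(mism) else 20L
      # offset on the original plus strand of `seq`
      off_plus <- if (strand == "+") o - 1L else L - (o + 22L)
      cand <- list(offset = off_plus, strand = strand,
                   score = scores[o], matches = m[o],
                   mismatch_positions = paste(mism - 21L, collapse = ","),
                   seed = seed,
                   proto_seq = paste(window, collapse = ""),
                   pam_seq = paste(bases[(o + 20L):(o + 22L)],
                                   collapse = ""))
      best <- consider(cand, best)
    }
  }
  best
}

#' Position frequency matrix of homology hits
#'
#' Hit protospacer sequences are oriented 5'->3' toward the PAM; per-position
#' base frequencies are computed with a pseudocount of 0.5 per base, so each
#' column sums to 1.
#'
#' @param hits a `homology_hits` data frame (>= 1 hit).
#' @param pseudocount per-base pseudocount, default 0.5.
#' @return 4 x 20 numeric matrix (rows A, C, G, T; columns positions 1-20,
#'   position 20 abutting the PAM).
#' @export
build_pwm <- function(hits, pseudocount = 0.5) {
  if (nrow(hits) < 1L) stop("build_pwm needs >= 1 hit")
  mat <- matrix(pseudocount, nrow = 4, ncol = 20,
                dimnames = list(DNA_BASES, as.character(1:20)))
  for (s in hits$protospacer_seq) {
    b <- strsplit(s, "")[[1]]
    for (j in 1:20) mat[b[j], j] <- mat[b[j], j] + 1
  }
  sweep(mat, 2, colSums(mat), "/")
}

#' Information content per PWM column (bits)
#' @param pwm 4 x 20 matrix from [build_pwm()].
#' @return numeric vector of length 20.
#' @export
pwm_information <- function(pwm) {
  apply(pwm, 2, function(p) 2 + sum(p * log2(p)))
}

#' Rank curves of edited sites by seed match length
#'
#' Sites are ranked (most edited first) and cumulative counts of edited
#' sites are reported overall and restricted to seed-match classes.
#'
#' @param sites data frame with `seed_match_length`, logical `edited`, and
#'   a ranking column `edit_strength` (descending order used).
#' @param seed_thresholds seed length classes, default c(8, 11).
#' @return data frame: rank, cumulative counts `all` and `seed>=k` columns.
#' @export
seed_rank_curves <- function(sites, seed_thresholds = c(8L, 11L)) {
  o <- order(-sites$edit_strength)
  s <- sites[o, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(s)),
                    all = cumsum(s$edited))
  for (k in seed_thresholds) {
    out[[sprintf("seed%d", k)]] <-
      cumsum(s$edited & s$seed_match_length >= k)
  }
  out
}

#' Seed+PAM motif occurrence in peaks versus GC-matched background
#'
#' The motif is the 5-nt PAM-adjacent protospacer seed followed by the PAM
#' pattern. Its occurrence fraction (either strand) in peak sequences is
#' compared with `n_background` random genomic intervals, length-matched to
#' the peaks and accepted only when their GC content is within `gc_tol` of
#' the matched peak's GC. A two-proportion test provides the enrichment
#' p-value.
#'
#' @param peaks data frame with chrom, start, end.
#' @param reference DNAStringSet.
#' @param guide a [guide_spec()].
#' @param n_background number of background intervals.
#' @param gc_tol GC acceptance tolerance, default 0.05.
#' @param seed RNG seed for background sampling.
#' @return list with `motif`, `peak_fraction`, `background_fraction`,
#'   `p_value`, `n_peaks`, `n_background`.
#' @export
motif_occurrence <- function(peaks, reference, guide, n_background = 1000L,
                             gc_tol = 0.05, seed = 1L) {
  refseq <- setNames(as.character(reference), names(reference))
  seed5 <- substr(guide$protospacer, 16L, 20L)
  motif <- paste0(seed5, guide$pam_pattern)
  peak_seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    substr(refseq[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
  }, character(1))
  peak_hit <- vapply(peak_seqs, contains_motif, logical(1), motif = motif,
                     USE.NAMES = FALSE)
  peak_gc <- vapply(peak_seqs, gc_fraction, numeric(1), USE.NAMES = FALSE)
  widths <- peaks$end - peaks$start

  bg_hit <- with_seed(seed, {
    hit <- logical(n_background)
    for (b in seq_len(n_background)) {
      j <- ((b - 1L) %% nrow(peaks)) + 1L  # match peak b's length and GC
      ctg <- sample(names(refseq), 1L)
      Lc <- nchar(refseq[[ctg]])
      w <- min(widths[j], Lc)
      ok <- FALSE
      for (try in seq_len(100L)) {
        s0 <- sample.int(Lc - w + 1L, 1L) - 1L
        sq <- substr(refseq[[ctg]], s0 + 1L, s0 + w)
        if (abs(gc_fraction(sq) - peak_gc[j]) <= gc_tol) {
          hit[b] <- contains_motif(sq, motif)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("background sampling failed: no GC-matched interval ",
                    "found in 100 attempts for peak ", j)
    }
    hit
  })
  pt <- suppressWarnings(prop.test(c(sum(peak_hit), sum(bg_hit)),
                                   c(length(peak_hit), length(bg_hit))))
  list(motif = motif,
       peak_fraction = mean(peak_hit),
       background_fraction = mean(bg_hit),
       p_value = pt$p.value,
       n_peaks = length(peak_hit),
       n_background = n_background)
}

# Does `seq` contain the IUPAC motif on either strand?
contains_motif <- function(seq, motif) {
  hit_one <- function(s) {
    length(Biostrings::matchPattern(motif, Biostrings::DNAString(s),
                                    fixed = FALSE)) > 0L
  }
  hit_one(seq) || hit_one(revcomp(seq))
}
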