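#' Synthetic experiment configuration
#'
#' Parameters of a synthetic ssDNA pulldown experiment: a random reference,
#' planted protospacer-homologous sites with homology-dependent R-loop
#' occupancy, and pulldown/input, plus/minus-gRNA read sets.
#'
#' @param genome_length reference length in bp.
#' @param gc_fraction target GC content in [0,1].
#' @param n_offtargets total number of planted sites (including the single
#'   zero-mismatch on-target site).
#' @param mismatch_distribution named integer vector mapping mismatch count
#'   to number of sites; must sum to `n_offtargets`.
#' @param read_length read length in bp.
#' @param background_depth mean number of reads starting per kbp in the
#'   background (input-like) component.
#' @param enrichment_factor fold increase of read density inside an R-loop
#'   footprint at occupancy 1.
#' @param sequencing_error independent per-base error probability.
#' @param occupancy_max occupancy of the zero-mismatch on-target site.
#' @param occupancy_decay multiplicative occupancy decay per protospacer
#'   mismatch (occupancy = occupancy_max * decay^mismatches).
#' @param dose_scalars unitless occupancy multipliers emulating an editor
#'   dose series.
#' @param replicates replicates per condition.
#' @param rng_seed integer seed making the whole experiment reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, gc_fraction = 0.5,
                       n_offtargets = 12L,
                       mismatch_distribution = c(`0` = 1L, `1` = 2L,
                                                 `2` = 3L, `4` = 3L,
                                                 `6` = 3L),
                       read_length = 100L, background_depth = 50,
                       enrichment_factor = 20, sequencing_error = 0.002,
                       occupancy_max = 0.8, occupancy_decay = 0.65,
                       dose_scalars = 1, replicates = 3L,
                       rng_seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_offtargets = as.integer(n_offtargets),
              mismatch_distribution = mismatch_distribution,
              read_length = as.integer(read_length),
              background_depth = background_depth,
              enrichment_factor = enrichment_factor,
              sequencing_error = sequencing_error,
              occupancy_max = occupancy_max,
              occupancy_decay = occupancy_decay,
              dose_scalars = dose_scalars,
              replicates = as.integer(replicates),
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length <= 0L) stop("genome_length must be positive")
  if (cfg$genome_length < 10L * cfg$read_length) {
    stop("genome_length must be at least 10x read_length")
  }
  probs <- c(cfg$gc_fraction, cfg$sequencing_error, cfg$occupancy_max,
             cfg$occupancy_decay)
  if (any(probs < 0) || any(probs > 1)) {
    stop("gc_fraction, sequencing_error, occupancy_max and occupancy_decay ",
         "must lie in [0,1]")
  }
  if (sum(cfg$mismatch_distribution) != cfg$n_offtargets) {
    stop("mismatch_distribution counts must sum to n_offtargets")
  }
  invisible(cfg)
}

#' Generate a random reference sequence
#'
#' @param config a [sim_config()] (its `genome_length`, `gc_fraction` and
#'   `rng_seed` are used).
#' @param contig contig name.
#' @return A [Biostrings::DNAStringSet] of length 1.
#' @examples
#' ref <- generate_reference(sim_config(genome_length = 2000, rng_seed = 7))
#' @export
generate_reference <- function(config, contig = "chrS") {
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
           config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
    bases <- sample(DNA_BASES, config$genome_length, replace = TRUE,
                    prob = p)
    ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(ref) <- contig
    ref
  })
}

#' Write a reference to FASTA (with .fai-style index sidecar)
#' @param reference DNAStringSet.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

# Concretise an IUPAC pattern by sampling uniformly per position.
sample_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(cd) sample(IUPAC_SETS[[cd]], 1L), character(1)),
        collapse = "")
}

# Positions of planted sites are chosen non-overlapping with a guard gap so
# that peak calling and PAM-relative profiling (60 bp 5' flank) stay clean.
place_sites <- function(genome_length, n, site_width = 23L, min_gap = 1500L,
                        edge = 100L) {
  lo <- edge + 60L
  hi <- genome_length - edge - site_width - 60L
  if (hi <= lo) stop("reference too short to place sites")
  starts <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      cand <- sample(lo:hi, 1L)
      if (!length(starts) ||
          all(abs(cand - starts) >= site_width + min_gap)) {
        starts <- c(starts, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("insufficient non-overlapping room to place ", n, " sites")
  }
  sort(starts)
}

#' Plant protospacer-homologous off-target sites into a reference
#'
#' Writes protospacer-like sequences followed by a concrete PAM match into
#' non-overlapping positions on random strands. Mismatches are placed
#' PAM-distal first, so the PAM-adjacent seed degrades last; a site with m
#' mismatches therefore has a seed match of 20 - m consecutive bases.
#' Occupancy decays geometrically in the mismatch count:
#' `occupancy = occupancy_max * occupancy_decay^mismatches`.
#'
#' Per-position true conversion probabilities are derived from the editor
#' profile windows, modulated by the 5' NTS sequence context and restricted
#' to positions where the NTS base actually is the editor's substrate base.
#'
#' @param reference DNAStringSet from [generate_reference()].
#' @param guide a [guide_spec()].
#' @param config a [sim_config()].
#' @param editor an [editor_profile()] used to assign true conversion
#'   probabilities.
#' @return A list with `truth` (a `truth_set` data frame, one row per site,
#'   with list-columns `nts_conversion` / `ts_conversion`) and `reference`
#'   (the modified DNAStringSet).
#' @export
plant_offtargets <- function(reference, guide, config,
                             editor = cbe_ebe_profile()) {
  stopifnot(is(guide, "guide_spec"))
  validate_sim_config(config)
  with_seed(config$rng_seed + 1L, {
    mm_counts <- rep(as.integer(names(config$mismatch_distribution)),
                     config$mismatch_distribution)
    n <- length(mm_counts)
    contig <- names(reference)[1]
    L <- Biostrings::width(reference)[1]
    starts <- place_sites(L, n)
    refseq <- as.character(reference[[1]])
    proto <- strsplit(guide$protospacer, "")[[1]]

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      m <- mm_counts[i]
      site_proto <- proto
      if (m > 0L) {
        # PAM-distal first: protospacer index 1 is farthest from the PAM
        for (j in seq_len(m)) {
          site_proto[j] <- sample(setdiff(DNA_BASES, proto[j]), 1L)
        }
      }
      pam <- sample_iupac(guide$pam_pattern)
      planted_plus <- paste0(paste(site_proto, collapse = ""), pam)
      strand <- sample(c("+", "-"), 1L)
      s <- starts[i]
      insert <- if (strand == "+") planted_plus else revcomp(planted_plus)
      substr(refseq, s + 1L, s + 23L) <- insert
      rows[[i]] <- list(start = s, strand = strand, mismatch = m,
                        planted = planted_plus)
    }
    reference[[1]] <- Biostrings::DNAString(refseq)

    truth <- data.frame(
      site_id = sprintf("site_%02d", seq_len(n)),
      chrom = contig,
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "start") + 23L,
      strand = vapply(rows, `[[`, character(1), "strand"),
      mismatch_count = mm_counts,
      seed_match_length = 20L - mm_counts,
      occupancy = config$occupancy_max * config$occupancy_decay^mm_counts,
      stringsAsFactors = FALSE
    )
    conv <- lapply(seq_len(n), function(i) {
      site_conversion_maps(refseq, truth$start[i], truth$strand[i], editor)
    })
    truth$nts_conversion <- lapply(conv, `[[`, "nts")
    truth$ts_conversion <- lapply(conv, `[[`, "ts")
    # plus-strand product base for each frame, fixed by editor chemistry
    # and site strand (an NTS C>T at a minus-strand site appears as G>A)
    truth$nts_alt <- ifelse(truth$strand == "+", editor$base_to,
                            COMPLEMENT[[editor$base_to]])
    truth$ts_alt <- ifelse(truth$strand == "+",
                           COMPLEMENT[[editor$base_to]], editor$base_to)
    class(truth) <- c("truth_set", "data.frame")
    list(truth = truth, reference = reference)
  })
}

# Map PAM-relative position -> 0-based genomic position for a site whose
# protospacer+PAM footprint starts at `start` (23 bp) on `strand`.
# Position -1 abuts the PAM; +1..+3 are the PAM bases.
pam_relative_to_genomic <- function(rel, start, strand) {
  if (strand == "+") {
    # protospacer [start, start+20), PAM [start+20, start+23)
    ifelse(rel < 0, start + 20L + rel, start + 19L + rel)
  } else {
    # PAM [start, start+3), protospacer [start+3, start+23)
    ifelse(rel < 0, start + 2L - rel, start + 3L - rel)
  }
}

# NTS base (the strand carrying the protospacer sequence) at a PAM-relative
# position, read off the reference plus strand.
nts_base_at <- function(refseq, g, strand) {
  b <- substr(refseq, g + 1L, g + 1L)
  if (strand == "+") b else unname(COMPLEMENT[b])
}

# True conversion maps for one site: editor window probabilities, 5' context
# modulation, restricted to positions whose NTS base is the substrate base.
site_conversion_maps <- function(refseq, start, strand, editor) {
  build <- function(window, from_base) {
    if (!length(window)) return(numeric(0))
    pos <- as.integer(names(window))
    keep <- numeric(0)
    for (k in seq_along(pos)) {
      g <- pam_relative_to_genomic(pos[k], start, strand)
      if (g < 0 || g >= nchar(refseq)) next
      if (nts_base_at(refseq, g, strand) != from_base) next
      g5 <- pam_relative_to_genomic(pos[k] - 1L, start, strand)
      ctx <- if (g5 >= 0 && g5 < nchar(refseq)) {
        nts_base_at(refseq, g5, strand)
      } else "N"
      mult <- editor$context_multipliers[ctx]
      if (is.na(mult)) mult <- 1
      keep[as.character(pos[k])] <- min(1, window[k] * mult)
    }
    keep
  }
  list(nts = build(editor$nts_window, editor$base_from),
       ts = build(editor$ts_window, COMPLEMENT[[editor$base_from]]))
}

#' Simulate aligned pulldown / input reads
#'
#' Background reads start uniformly at `background_depth` per kbp. In the
#' pulldown plus-gRNA condition, read density inside each planted R-loop
#' footprint is multiplied by `1 + enrichment_factor * occupancy *
#' dose_scalar`. Whenever gRNA is present, each read overlapping a site's
#' editing span is drawn from an edited genome with probability
#' `occupancy * dose_scalar`; such reads carry per-position conversions drawn
#' from the site's true conversion maps (strand-aware: conversions defined on
#' the non-target strand are complemented when the site lies on the reference
#' minus strand). Independent per-base sequencing error is applied everywhere.
#' Alignments are emitted pre-aligned, all-match CIGAR, coordinate sorted.
#'
#' @param reference DNAStringSet (post-planting).
#' @param truth a `truth_set` (may be NULL/empty for pure background).
#' @param editor an [editor_profile()].
#' @param condition "pulldown" or "input".
#' @param gRNA "plus" or "minus".
#' @param dose_scalar unitless occupancy multiplier.
#' @param config a [sim_config()].
#' @param seed RNG seed for this read set (conditions/replicates should use
#'   distinct seeds derived from `config$rng_seed`).
#' @return A `read_set` data frame (chrom, start 0-based, width, strand,
#'   seq on the reference plus strand) with a `seqlengths` attribute.
#' @export
simulate_reads <- function(reference, truth, editor,
                           condition = c("pulldown", "input"),
                           gRNA = c("plus", "minus"),
                           dose_scalar = 1, config = sim_config(),
                           seed = config$rng_seed) {
  condition <- match.arg(condition)
  gRNA <- match.arg(gRNA)
  validate_sim_config(config)
  contig <- names(reference)[1]
  L <- Biostrings::width(reference)[1]
  rl <- config$read_length
  refseq <- as.character(reference[[1]])

  with_seed(seed, {
    lambda_bp <- config$background_depth / 1000
    n_bg <- rpois(1L, lambda_bp * (L - rl + 1L))
    starts <- sample.int(L - rl + 1L, n_bg, replace = TRUE) - 1L

    has_truth <- !is.null(truth) && nrow(truth) > 0L
    if (has_truth && condition == "pulldown" && gRNA == "plus") {
      for (i in seq_len(nrow(truth))) {
        w_lo <- max(0L, truth$start[i] - rl + 1L)
        w_hi <- min(L - rl, truth$end[i] - 1L)
        w <- w_hi - w_lo + 1L
        boost <- config$enrichment_factor * truth$occupancy[i] * dose_scalar
        n_extra <- rpois(1L, lambda_bp * w * boost)
        if (n_extra > 0L) {
          starts <- c(starts, w_lo + sample.int(w, n_extra,
                                                replace = TRUE) - 1L)
        }
      }
    }
    starts <- sort(starts)
    n <- length(starts)
    seqs <- substring(refseq, starts + 1L, starts + rl)

    if (has_truth && gRNA == "plus" && n > 0L) {
      seqs <- apply_site_edits(seqs, starts, rl, truth, dose_scalar)
    }
    if (config$sequencing_error > 0 && n > 0L) {
      seqs <- apply_sequencing_error(seqs, config$sequencing_error)
    }

    reads <- data.frame(
      chrom = rep(contig, n),
      start = starts,
      width = rep(rl, n),
      strand = if (n) sample(c("+", "-"), n, replace = TRUE) else character(0),
      seq = seqs,
      stringsAsFactors = FALSE
    )
    reads$qname <- sprintf("r%06d", seq_len(max(n, 0L)))
    attr(reads, "seqlengths") <- setNames(L, contig)
    class(reads) <- c("read_set", "data.frame")
    reads
  })
}

# Per-read edit application. A read overlapping a site's editing span is
# "edited" with probability occupancy * dose; edited reads carry Bernoulli
# conversions at the site's true-conversion positions, expressed on the
# reference plus strand.
apply_site_edits <- function(seqs, starts, rl, truth, dose_scalar) {
  for (i in seq_len(nrow(truth))) {
    site <- truth[i, ]
    nts <- site$nts_conversion[[1]]
    ts <- site$ts_conversion[[1]]
    if (!length(nts) && !length(ts)) next
    conv_pos <- c(as.integer(names(nts)), as.integer(names(ts)))
    conv_p <- c(unname(nts), unname(ts))
    conv_frame <- rep(c("nts", "ts"), c(length(nts), length(ts)))
    g <- vapply(conv_pos, pam_relative_to_genomic, integer(1),
                start = site$start, strand = site$strand)
    span_lo <- min(g, site$start)
    span_hi <- max(g, site$end - 1L)
    idx <- which(starts <= span_hi & (starts + rl - 1L) >= span_lo)
    if (!length(idx)) next
    p_edit <- min(1, site$occupancy * dose_scalar)
    edited <- idx[runif(length(idx)) < p_edit]
    if (!length(edited)) next
    for (k in seq_along(g)) {
      cover <- edited[starts[edited] <= g[k] &
                      (starts[edited] + rl - 1L) >= g[k]]
      if (!length(cover)) next
      hit <- cover[runif(length(cover)) < conv_p[k]]
      if (!length(hit)) next
      alt <- if (conv_frame[k] == "nts") site$nts_alt else site$ts_alt
      off <- g[k] - starts[hit] + 1L
      for (j in seq_along(hit)) {
        substr(seqs[hit[j]], off[j], off[j]) <- alt
      }
    }
  }
  seqs
}

apply_sequencing_error <- function(seqs, error_rate) {
  n <- length(seqs)
  rl <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = rl, ncol = n)
  err <- which(matrix(runif(rl * n) < error_rate, nrow = rl))
  if (length(err)) {
    cur <- mat[err]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    mat[err] <- repl
  }
  apply(mat, 2, paste, collapse = "")
}

#' Simulate an amplicon-sequencing edit frequency table
#'
#' Amplicon sequencing measures the absolute edit frequency at a site,
#' whereas pulldown reads measure the frequency within detected R-loops.
#' The two are related by a proportionality (the editor occupancy scaling):
#' `amplicon = occupancy_scaling * rloop + noise`, truncated to [0,1].
#'
#' @param truth a `truth_set` whose in-R-loop frequencies
#'   (occupancy x true conversion probability) are used; or NULL if
#'   `rloop_freq` is given directly.
#' @param occupancy_scaling proportionality in (0, 1].
#' @param noise_sd Gaussian noise standard deviation.
#' @param rloop_freq optional numeric vector of in-R-loop frequencies used
#'   instead of `truth`.
#' @param seed RNG seed.
#' @return data frame with columns site_id, position, rloop_freq,
#'   amplicon_freq.
#' @export
simulate_amplicon_table <- function(truth = NULL, occupancy_scaling,
                                    noise_sd = 0.02, rloop_freq = NULL,
                                    seed = 1L) {
  if (occupancy_scaling <= 0 || occupancy_scaling > 1) {
    stop("occupancy_scaling must lie in (0, 1]")
  }
  if (is.null(rloop_freq)) {
    stopifnot(!is.null(truth))
    tab <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      conv <- truth$nts_conversion[[i]]
      if (!length(conv)) return(NULL)
      data.frame(site_id = truth$site_id[i],
                 position = as.integer(names(conv)),
                 rloop_freq = truth$occupancy[i] * unname(conv),
                 stringsAsFactors = FALSE)
    }))
  } else {
    tab <- data.frame(site_id = sprintf("site_%03d", seq_along(rloop_freq)),
                      position = NA_integer_,
                      rloop_freq = rloop_freq,
                      stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    amp <- occupancy_scaling * tab$rloop_freq +
      rnorm(nrow(tab), 0, noise_sd)
    tab$amplicon_freq <- pmin(1, pmax(0, amp))
  })
  tab
}

#' Write a truth set as BED6
#'
#' name is the site id; score is `round(1000 * occupancy)`.
#' @param truth a `truth_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(truth$chrom, truth$start, truth$end, truth$site_id,
                    round(1000 * truth$occupancy), truth$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
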