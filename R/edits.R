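#' Base-conversion pileup over intervals
#'
#' Tallies every aligned base of every read over the requested intervals.
#' Alignments are all-match (as emitted by the simulator / accepted by
#' [read_alignments()]), so each read base maps directly onto the reference.
#'
#' @param reads a `read_set` data frame.
#' @param intervals data frame with chrom, start, end (0-based half-open).
#' @param reference DNAStringSet.
#' @return A `conversion_pileup` data frame: chrom, pos (0-based), ref,
#'   depth, and per-base counts A, C, G, T. Positions with depth 0 are
#'   reported with NA frequencies downstream, never 0.
#' @export
pileup <- function(reads, intervals, reference) {
  refseq <- setNames(as.character(reference), names(reference))
  if (!all(unique(intervals$chrom) %in% names(refseq))) {
    stop("interval contig absent from the reference")
  }
  out <- NULL
  for (ctg in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ctg, , drop = FALSE]
    pos_set <- sort(unique(unlist(lapply(seq_len(nrow(iv)), function(i) {
      seq.int(iv$start[i], iv$end[i] - 1L)
    }))))
    if (!length(pos_set)) next
    lo <- min(pos_set); hi <- max(pos_set)
    span <- hi - lo + 1L
    counts <- matrix(0L, nrow = span, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    rs <- reads[reads$chrom == ctg, , drop = FALSE]
    rs <- rs[rs$start <= hi & (rs$start + rs$width - 1L) >= lo, ,
             drop = FALSE]
    if (nrow(rs)) {
      # expand reads to (position, base) pairs, clipped to [lo, hi]
      for (i in seq_len(nrow(rs))) {
        s <- rs$start[i]
        b <- strsplit(rs$seq[i], "")[[1]]
        p <- s + seq_along(b) - 1L
        keep <- p >= lo & p <= hi & b %in% DNA_BASES
        if (!any(keep)) next
        idx <- cbind(p[keep] - lo + 1L, match(b[keep], DNA_BASES))
        # accumulate; duplicated cells within one read cannot occur
        counts[idx] <- counts[idx] + 1L
      }
    }
    sel <- pos_set - lo + 1L
    refb <- strsplit(substr(refseq[[ctg]], lo + 1L, hi + 1L), "")[[1]]
    out <- rbind(out, data.frame(
      chrom = ctg, pos = pos_set, ref = refb[sel],
      depth = rowSums(counts[sel, , drop = FALSE]),
      A = counts[sel, "A"], C = counts[sel, "C"],
      G = counts[sel, "G"], T = counts[sel, "T"],
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), depth = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("conversion_pileup", "data.frame")
  out
}

#' PAM-relative edit profile of one site
#'
#' Maps genomic pileup coordinates into PAM-relative coordinates of a
#' protospacer site (position -1 abuts the PAM) and reports per-position
#' conversion frequencies in two strand frames. The NTS frame always
#' reports the editor's `base_from > base_to` conversion on the non-target
#' strand: at a site whose protospacer lies on the reference minus strand,
#' positions are mirrored and substitutions complemented (a plus-strand
#' G>A at a minus-strand CBE site reports as NTS C>T). The TS frame reports
#' the opposite-strand conversion in the same coordinates.
#'
#' @param site one row of a `homology_hits` data frame (or any data frame
#'   with chrom, start, end, strand of the 23 bp protospacer+PAM footprint).
#' @param pile a `conversion_pileup` covering the site region.
#' @param editor an [editor_profile()].
#' @param upstream,downstream profile extent: `upstream` bp 5' of the PAM
#'   and `downstream` bp into/past the PAM.
#' @return An `edit_profile` data frame: position (PAM-relative), frame
#'   ("NTS"/"TS"), pos_genomic, ref_is_substrate, depth, alt, freq (NA when
#'   depth is 0 or the reference base is not the substrate).
#' @export
pam_relative_profile <- function(site, pile, editor, upstream = 60L,
                                 downstream = 3L) {
  rel <- c(seq.int(-upstream, -1L), seq_len(downstream))
  g <- pam_relative_to_genomic(rel, site$start, site$strand)
  rows <- NULL
  for (frame in c("NTS", "TS")) {
    if (site$strand == "+") {
      from <- if (frame == "NTS") editor$base_from else
        COMPLEMENT[[editor$base_from]]
      to <- if (frame == "NTS") editor$base_to else
        COMPLEMENT[[editor$base_to]]
    } else {
      from <- if (frame == "NTS") COMPLEMENT[[editor$base_from]] else
        editor$base_from
      to <- if (frame == "NTS") COMPLEMENT[[editor$base_to]] else
        editor$base_to
    }
    m <- match(paste(site$chrom, g), paste(pile$chrom, pile$pos))
    depth <- pile$depth[m]
    refb <- pile$ref[m]
    alt <- ifelse(refb == from, pile[[to]][m], NA_integer_)
    freq <- ifelse(!is.na(depth) & depth > 0 & refb == from,
                   alt / depth, NA_real_)
    rows <- rbind(rows, data.frame(
      position = rel, frame = frame, pos_genomic = g,
      ref_is_substrate = !is.na(refb) & refb == from,
      depth = ifelse(is.na(depth), 0L, depth),
      alt = ifelse(is.na(alt), NA_integer_, alt),
      freq = freq, stringsAsFactors = FALSE))
  }
  class(rows) <- c("edit_profile", "data.frame")
  rows
}

#' Call base edits from a conversion pileup
#'
#' Per candidate position and substitution class, a one-sided binomial test
#' of the alt count against `error_rate / 3` (the per-substitution share of
#' the sequencing error rate), BH-corrected across all tested positions.
#' Calls must satisfy `depth >= min_depth`, `freq >= min_freq` and
#' `q < q_threshold`. When an editor is given, only its substitution
#' classes (both reference-strand framings) are tested; otherwise all 12.
#'
#' @param pile a `conversion_pileup`.
#' @param error_rate per-base sequencing error rate, in (0, 0.1).
#' @param min_depth minimum depth, default 20.
#' @param min_freq minimum alt frequency, default 0.02.
#' @param q_threshold BH threshold, default 0.05.
#' @param editor optional [editor_profile()] restricting tested classes.
#' @return An `edit_calls` data frame: chrom, pos, ref, alt, depth,
#'   alt_count, freq, p, q, frame ("NTS" if ref equals the editor substrate
#'   on the plus strand, "TS" otherwise; NA without an editor).
#' @export
call_edits <- function(pile, error_rate, min_depth = 20L, min_freq = 0.02,
                       q_threshold = 0.05, editor = NULL) {
  if (error_rate <= 0 || error_rate >= 0.1) {
    stop("error_rate must lie in (0, 0.1)")
  }
  classes <- if (is.null(editor)) {
    expand.grid(ref = DNA_BASES, alt = DNA_BASES,
                stringsAsFactors = FALSE)
  } else {
    data.frame(ref = c(editor$base_from, COMPLEMENT[[editor$base_from]]),
               alt = c(editor$base_to, COMPLEMENT[[editor$base_to]]),
               stringsAsFactors = FALSE)
  }
  classes <- classes[classes$ref != classes$alt, , drop = FALSE]
  tested <- NULL
  for (k in seq_len(nrow(classes))) {
    sel <- pile$ref == classes$ref[k] & pile$depth >= min_depth
    if (!any(sel)) next
    sub <- pile[sel, c("chrom", "pos", "ref", "depth"), drop = FALSE]
    sub$alt <- classes$alt[k]
    sub$alt_count <- pile[[classes$alt[k]]][sel]
    tested <- rbind(tested, sub)
  }
  if (is.null(tested) || !nrow(tested)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      freq = numeric(0), p = numeric(0), q = numeric(0),
                      frame = character(0), stringsAsFactors = FALSE)
    class(out) <- c("edit_calls", "data.frame")
    return(out)
  }
  tested$freq <- tested$alt_count / tested$depth
  tested$p <- pbinom(tested$alt_count - 1L, tested$depth, error_rate / 3,
                     lower.tail = FALSE)
  tested$q <- p.adjust(tested$p, method = "BH")
  tested$frame <- if (is.null(editor)) NA_character_ else
    ifelse(tested$ref == editor$base_from, "NTS", "TS")
  out <- tested[tested$freq >= min_freq & tested$q < q_threshold, ,
                drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edit_calls", "data.frame")
  out
}

#' Mutational spectrum and sequence context of edit calls
#'
#' Counts the 12 substitution classes in the NTS frame (calls on the
#' opposite reference strand are complemented before counting), builds
#' per-offset base-frequency matrices over a flank around the edited base,
#' and reports the 5' dinucleotide enrichment of the substrate base against
#' the background frequency of that dinucleotide around all substrate
#' occurrences in the supplied interval sequences.
#'
#' @param calls an `edit_calls` data frame with a `frame` column, or calls
#'   made without an editor (then reference-strand classes are counted
#'   as-is).
#' @param reference DNAStringSet.
#' @param flank half-width of the context window, default 5.
#' @param background_intervals optional data frame (chrom, start, end) of
#'   peak intervals providing the background base composition.
#' @return list with `spectrum` (named counts like "C>T"), `context`
#'   (4 x (2*flank+1) frequency matrix, columns summing to 1), and
#'   `fiveprime_enrichment` (named vector over A/C/G/T, NA without
#'   background intervals).
#' @export
context_spectrum <- function(calls, reference, flank = 5L,
                             background_intervals = NULL) {
  if (nrow(calls) < 1L) stop("context_spectrum needs >= 1 call")
  refseq <- setNames(as.character(reference), names(reference))

  # NTS-frame substitution labels: complement TS-frame calls
  lab_ref <- calls$ref
  lab_alt <- calls$alt
  flip <- !is.na(calls$frame) & calls$frame == "TS"
  lab_ref[flip] <- unname(COMPLEMENT[lab_ref[flip]])
  lab_alt[flip] <- unname(COMPLEMENT[lab_alt[flip]])
  spectrum <- table(factor(paste0(lab_ref, ">", lab_alt),
                           levels = apply(expand.grid(DNA_BASES, DNA_BASES),
                                          1, function(x)
                                            paste0(x[1], ">", x[2]))))
  spectrum <- spectrum[!grepl("^(.)>\\1$", names(spectrum))]

  offsets <- seq.int(-flank, flank)
  ctx <- matrix(0, nrow = 4, ncol = length(offsets),
                dimnames = list(DNA_BASES, as.character(offsets)))
  for (i in seq_len(nrow(calls))) {
    s <- refseq[[calls$chrom[i]]]
    p <- calls$pos[i]
    b <- strsplit(substr(s, max(1L, p + 1L - flank),
                         min(nchar(s), p + 1L + flank)), "")[[1]]
    # align to offsets (clip at sequence edges)
    off0 <- max(1L, p + 1L - flank) - (p + 1L)
    for (j in seq_along(b)) {
      o <- off0 + j - 1L
      bj <- b[j]
      if (flip[i]) {
        o <- -o
        bj <- unname(COMPLEMENT[bj])
      }
      oc <- as.character(o)
      if (oc %in% colnames(ctx) && bj %in% DNA_BASES) {
        ctx[bj, oc] <- ctx[bj, oc] + 1
      }
    }
  }
  ctx <- sweep(ctx, 2, pmax(colSums(ctx), 1), "/")

  fp <- setNames(rep(NA_real_, 4), DNA_BASES)
  if (!is.null(background_intervals) && nrow(background_intervals)) {
    sub_base <- names(which.max(table(lab_ref)))
    # observed 5' base distribution at calls (NTS frame)
    obs <- ctx[, as.character(-1L)]
    bg <- bg_fiveprime_distribution(background_intervals, refseq, sub_base)
    fp <- obs / pmax(bg, 1e-9)
  }
  list(spectrum = spectrum, context = ctx, fiveprime_enrichment = fp)
}

# Distribution of the 5' neighbour base over all occurrences of `sub_base`
# (both strands) in the background intervals.
bg_fiveprime_distribution <- function(intervals, refseq, sub_base) {
  counts <- setNames(numeric(4), DNA_BASES)
  for (i in seq_len(nrow(intervals))) {
    s <- substr(refseq[[intervals$chrom[i]]], intervals$start[i] + 1L,
                intervals$end[i])
    b <- strsplit(s, "")[[1]]
    idx <- which(b == sub_base)
    idx <- idx[idx > 1L]
    if (length(idx)) {
      t5 <- table(factor(b[idx - 1L], levels = DNA_BASES))
      counts <- counts + t5
    }
    # opposite strand: occurrences of the complement, 5' neighbour is the
    # complement of the base to the right
    comp <- unname(COMPLEMENT[sub_base])
    idx2 <- which(b == comp)
    idx2 <- idx2[idx2 < length(b)]
    if (length(idx2)) {
      t5 <- table(factor(unname(COMPLEMENT[b[idx2 + 1L]]),
                         levels = DNA_BASES))
      counts <- counts + t5
    }
  }
  counts / max(sum(counts), 1)
}

#' Detect helical periodicity in an out-of-protospacer editing profile
#'
#' Mean-subtracted autocorrelation of the NTS conversion frequencies over a
#' PAM-relative range; the dominant period is the autocorrelation argmax
#' over lags 8-14 bp, reported together with the local maxima positions of
#' the profile. A flat profile yields no significant period (autocorrelation
#' peak below `threshold`).
#'
#' @param profile an `edit_profile` data frame (NTS frame rows are used).
#' @param range PAM-relative positions analysed, default -60...-31.
#' @param lags candidate period lags, default 8:14.
#' @param threshold minimum normalised autocorrelation for significance.
#' @return list with `period` (NA if not significant), `autocorrelation`
#'   (named vector over lags), `significant`, `maxima` (PAM-relative
#'   positions of profile local maxima in the range).
#' @export
detect_periodicity <- function(profile, range = -60:-31, lags = 8:14,
                               threshold = 0.3) {
  if (length(range) < 2L * max(lags)) {
    stop("range must cover at least twice the maximum candidate lag")
  }
  nts <- profile[profile$frame == "NTS", , drop = FALSE]
  m <- match(range, nts$position)
  if (any(is.na(m))) stop("profile does not cover the requested range")
  x <- nts$freq[m]
  x[is.na(x)] <- 0
  x <- x - mean(x)
  denom <- sum(x^2)
  ac <- vapply(lags, function(l) {
    n <- length(x) - l
    if (denom == 0) return(0)
    sum(x[seq_len(n)] * x[seq_len(n) + l]) / denom
  }, numeric(1))
  names(ac) <- lags
  best <- which.max(ac)
  significant <- ac[best] >= threshold
  y <- nts$freq[m]
  y[is.na(y)] <- 0
  maxima <- range[which(diff(sign(diff(c(-Inf, y, -Inf)))) == -2)]
  maxima <- maxima[y[match(maxima, range)] > 0]
  list(period = if (significant) lags[best] else NA_integer_,
       autocorrelation = ac, significant = significant, maxima = maxima)
}

#' Rank sites by editing and assemble a profile heatmap matrix
#'
#' Sites are ranked by their maximum single-position NTS conversion
#' frequency, ties broken by total summed frequency, then site id.
#'
#' @param profiles named list of `edit_profile` data frames (one per site).
#' @param n number of top sites to keep (clamped to the site count).
#' @return list with `ranking` (data frame: site, max_freq, total_freq,
#'   rank) and `matrix` (sites x positions NTS frequency matrix for the
#'   top `n`).
#' @export
top_edited_sites <- function(profiles, n = 100L) {
  stopifnot(length(profiles) >= 1L)
  stats <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    f <- p$freq[p$frame == "NTS"]
    data.frame(site = nm,
               max_freq = if (all(is.na(f))) 0 else max(f, na.rm = TRUE),
               total_freq = sum(f, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  o <- order(-stats$max_freq, -stats$total_freq, stats$site)
  stats <- stats[o, , drop = FALSE]
  stats$rank <- seq_len(nrow(stats))
  top <- head(stats$site, min(n, nrow(stats)))
  pos <- profiles[[1]]$position[profiles[[1]]$frame == "NTS"]
  mat <- t(vapply(top, function(nm) {
    p <- profiles[[nm]]
    f <- p$freq[p$frame == "NTS"]
    f[is.na(f)] <- 0
    f
  }, numeric(length(pos))))
  colnames(mat) <- pos
  list(ranking = stats, matrix = mat)
}

#' Aggregate PAM-relative profiles across sites
#'
#' Emits both aggregation conventions: the unweighted mean of per-site
#' frequencies (`mean_of_sites`) and the pooled ratio of summed alt over
#' summed depth (`pooled`). The two differ when depth varies across sites.
#'
#' @param profiles list of `edit_profile` data frames on a common grid.
#' @return data frame: position, frame, mean_of_sites, pooled, n_sites.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  key <- profiles[[1]][, c("position", "frame")]
  acc_freq <- matrix(NA_real_, nrow(key), length(profiles))
  acc_alt <- matrix(0, nrow(key), length(profiles))
  acc_depth <- matrix(0, nrow(key), length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    stopifnot(nrow(p) == nrow(key))
    acc_freq[, j] <- p$freq
    ok <- !is.na(p$freq)
    acc_alt[ok, j] <- p$alt[ok]
    acc_depth[ok, j] <- p$depth[ok]
  }
  data.frame(position = key$position, frame = key$frame,
             mean_of_sites = rowMeans(acc_freq, na.rm = TRUE),
             pooled = rowSums(acc_alt) / pmax(rowSums(acc_depth), 1),
             n_sites = rowSums(!is.na(acc_freq)))
}
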