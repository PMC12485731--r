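#' Count reads in contiguous, non-overlapping genomic bins
#'
#' Each read is assigned to exactly one bin by its 5' position (alignment
#' start for plus-strand reads, alignment end for minus-strand reads). Bins
#' tile each contig without gaps or overlaps; the last bin is truncated at
#' the contig end. A depth-normalised column (counts per million assigned
#' reads) is computed per sample.
#'
#' @param reads a `read_set` data frame or a named list of them (one per
#'   sample).
#' @param bin_width bin width in bp, >= 100; default 1000.
#' @return A `bin_matrix` data frame: chrom, start, end, then one raw-count
#'   column `<sample>` and one normalised column `<sample>_cpm` per sample.
#' @export
bin_counts <- function(reads, bin_width = 1000L) {
  if (bin_width < 100L) stop("bin_width must be >= 100")
  if (is.data.frame(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads)) || any(names(reads) == "")) {
    names(reads) <- sprintf("sample%d", seq_along(reads))
  }
  sl <- attr(reads[[1]], "seqlengths")
  if (is.null(sl)) stop("read set lacks a seqlengths attribute")

  grid <- do.call(rbind, lapply(names(sl), function(ctg) {
    starts <- seq(0L, sl[[ctg]] - 1L, by = bin_width)
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + bin_width, sl[[ctg]]),
               stringsAsFactors = FALSE)
  }))

  for (nm in names(reads)) {
    rs <- reads[[nm]]
    if (nrow(rs) && is.unsorted(rs$start[rs$chrom == rs$chrom[1]])) {
      # per-contig sortedness check; simulator output is sorted
      for (ctg in unique(rs$chrom)) {
        if (is.unsorted(rs$start[rs$chrom == ctg])) {
          stop("reads are not coordinate sorted; sort them first ",
               "(e.g. reads[order(reads$chrom, reads$start), ])")
        }
      }
    }
    cnt <- integer(nrow(grid))
    if (nrow(rs)) {
      p5 <- ifelse(rs$strand == "-", rs$start + rs$width - 1L, rs$start)
      for (ctg in unique(rs$chrom)) {
        sel <- rs$chrom == ctg
        gsel <- grid$chrom == ctg
        idx <- pmin(p5[sel] %/% bin_width + 1L, sum(gsel))
        cnt[gsel] <- tabulate(idx, nbins = sum(gsel))
      }
    }
    grid[[nm]] <- cnt
    grid[[paste0(nm, "_cpm")]] <- cnt / max(sum(cnt), 1L) * 1e6
  }
  class(grid) <- c("bin_matrix", "data.frame")
  grid
}

#' Pearson correlation of two binned samples
#'
#' Correlates `log2(cpm + 1)` across all bins of a shared grid -- the
#' transform used for replicate and condition concordance summaries.
#'
#' @param bins a `bin_matrix` from [bin_counts()].
#' @param sample_a,sample_b sample (column) names.
#' @return Pearson's r.
#' @export
correlate_bins <- function(bins, sample_a, sample_b) {
  xa <- log2(bins[[paste0(sample_a, "_cpm")]] + 1)
  xb <- log2(bins[[paste0(sample_b, "_cpm")]] + 1)
  if (sd(xa) == 0 || sd(xb) == 0) {
    stop("undefined correlation: a sample has zero variance across bins")
  }
  stats::cor(xa, xb, method = "pearson")
}

# 5' position histogram per contig, as an integer vector of length L.
five_prime_counts <- function(reads, contig, L) {
  sel <- reads$chrom == contig
  if (!any(sel)) return(integer(L))
  p5 <- ifelse(reads$strand[sel] == "-",
               reads$start[sel] + reads$width[sel] - 1L, reads$start[sel])
  tabulate(pmin(p5, L - 1L) + 1L, nbins = L)
}

# Windowed sums of a per-bp count vector centred on window midpoints,
# via cumulative sums. Returns the sum over [mid - w/2, mid + w/2).
centred_window_sum <- function(cs, mids, w) {
  L <- length(cs) - 1L
  lo <- pmax(0L, as.integer(mids - w / 2))
  hi <- pmin(L, as.integer(mids + w / 2))
  cs[hi + 1L] - cs[lo + 1L]
}

#' Call enrichment peaks of pulldown over input (total peak calls)
#'
#' Sharp-peak caller in the local-Poisson style: sliding windows of
#' `window_width` bp advanced by `step` bp are tested against a local
#' Poisson rate. The local rate is the depth-ratio-scaled maximum of input
#' rates estimated at 1 kb, 5 kb and 10 kb around the window and genome
#' wide. One-sided Poisson upper-tail p-values are BH-corrected over all
#' windows; significant windows within `merge_gap` bp are merged and the
#' summit is placed at the maximum pulldown coverage position.
#'
#' @param pulldown,input `read_set` data frames on the same reference.
#' @param q_threshold BH q-value cutoff, default 0.05.
#' @param window_width,step sliding-window geometry (bp).
#' @param merge_gap maximum gap between significant windows that are merged.
#' @param local_scales input background estimation scales (bp).
#' @return A `peak_set` data frame: chrom, start, end, summit, count,
#'   lambda, enrichment, p, q.
#' @export
call_peaks <- function(pulldown, input, q_threshold = 0.05,
                       window_width = 300L, step = 50L, merge_gap = 100L,
                       local_scales = c(1000L, 5000L, 10000L)) {
  sl <- attr(pulldown, "seqlengths")
  if (is.null(sl)) stop("pulldown read set lacks seqlengths")
  total_p <- nrow(pulldown)
  total_i <- nrow(input)
  empty_input <- total_i == 0L
  if (empty_input) {
    warning("input sample is empty; falling back to genome-wide pulldown ",
            "background")
  }
  depth_ratio <- if (empty_input) 1 else total_p / total_i

  win <- NULL
  for (ctg in names(sl)) {
    L <- sl[[ctg]]
    if (L < window_width) next
    cp <- c(0, cumsum(five_prime_counts(pulldown, ctg, L)))
    ci <- if (empty_input) cp else
      c(0, cumsum(five_prime_counts(input, ctg, L)))
    starts <- seq(0L, L - window_width, by = step)
    mids <- starts + window_width / 2
    obs <- cp[starts + window_width + 1L] - cp[starts + 1L]
    gw_rate <- (if (empty_input) total_p else total_i) / L * window_width
    lam <- rep(gw_rate, length(starts))
    for (w in local_scales) {
      s <- centred_window_sum(ci, mids, w)
      # rescale to the test window width, correcting for edge truncation
      eff_w <- pmin(L, mids + w / 2) - pmax(0, mids - w / 2)
      lam <- pmax(lam, s * window_width / eff_w)
    }
    lam <- lam * depth_ratio
    win <- rbind(win, data.frame(chrom = ctg, start = starts,
                                 end = starts + window_width,
                                 count = obs, lambda = lam,
                                 stringsAsFactors = FALSE))
  }
  win$p <- ppois(win$count - 1L, win$lambda, lower.tail = FALSE)
  win$q <- p.adjust(win$p, method = "BH")

  sig <- win[win$q <= q_threshold & win$count > 0, , drop = FALSE]
  peaks <- merge_windows(sig, merge_gap, pulldown, sl)
  attr(peaks, "windows") <- win
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

# Merge significant windows within merge_gap into peaks; per peak take the
# best constituent window's p/q, recount pulldown 5' reads and locate the
# summit at maximum read coverage.
merge_windows <- function(sig, merge_gap, pulldown, sl) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), summit = integer(0),
                    count = integer(0), lambda = numeric(0),
                    enrichment = numeric(0), p = numeric(0), q = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nrow(sig)) return(out)
  for (ctg in unique(sig$chrom)) {
    s <- sig[sig$chrom == ctg, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end),
                          min.gapwidth = merge_gap + 1L)
    L <- sl[[ctg]]
    cov <- read_coverage(pulldown, ctg, L)
    c5 <- c(0, cumsum(five_prime_counts(pulldown, ctg, L)))
    for (k in seq_along(ir)) {
      ps <- IRanges::start(ir)[k] - 1L
      pe <- IRanges::end(ir)[k]
      inwin <- s$start >= ps & s$end <= pe
      p_best <- min(s$p[inwin])
      q_best <- min(s$q[inwin])
      lam_w <- max(s$lambda[inwin])
      cnt <- c5[pe + 1L] - c5[ps + 1L]
      lam_peak <- lam_w * (pe - ps) / (s$end[inwin][1] - s$start[inwin][1])
      summit <- ps + which.max(cov[(ps + 1L):pe]) - 1L
      out <- rbind(out, data.frame(
        chrom = ctg, start = ps, end = pe, summit = summit, count = cnt,
        lambda = lam_peak, enrichment = max(1, cnt / max(lam_peak, 1e-9)),
        p = p_best, q = q_best, stringsAsFactors = FALSE))
    }
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-bp read (full alignment) coverage for one contig.
read_coverage <- function(reads, contig, L) {
  sel <- reads$chrom == contig
  cov <- integer(L)
  if (!any(sel)) return(cov)
  d <- integer(L + 1L)
  st <- reads$start[sel] + 1L
  en <- pmin(reads$start[sel] + reads$width[sel], L)
  for (i in seq_along(st)) {
    d[st[i]] <- d[st[i]] + 1L
    d[en[i] + 1L] <- d[en[i] + 1L] - 1L
  }
  cumsum(d[seq_len(L)])
}
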