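#' Fit the amplicon-to-R-loop occupancy scaling
#'
#' Amplicon (absolute) edit frequencies are proportional to in-R-loop edit
#' frequencies; the proportionality is interpreted as the editor occupancy.
#' A through-origin least-squares regression of amplicon frequency on
#' R-loop frequency estimates the scaling.
#'
#' @param amplicon_table data frame with `rloop_freq` and `amplicon_freq`
#'   columns (as from [simulate_amplicon_table()]), site-matched pairs at
#'   shared edited positions.
#' @return An `occupancy_fit` list: scaling, residual_sd, n.
#' @export
fit_occupancy <- function(amplicon_table) {
  x <- amplicon_table$rloop_freq
  y <- amplicon_table$amplicon_freq
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("occupancy fit needs >= 3 paired frequencies")
  slope <- sum(x * y) / sum(x^2)
  res <- y - slope * x
  structure(list(scaling = slope,
                 residual_sd = sd(res),
                 n = length(x)),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("occupancy_fit: scaling %.3f (residual sd %.4f, n = %d)\n",
              x$scaling, x$residual_sd, x$n))
  invisible(x)
}

#' Absolute edits per genome and peaks per edit
#'
#' Converts in-R-loop edit frequencies at gRNA-dependent (differential)
#' sites into expected edited bases per genome:
#' `edits_per_genome = sum over sites and called positions of
#' freq * scaling * ploidy`. With a supplied differential-peak count the
#' peaks-per-edit ratio is also reported.
#'
#' @param site_freqs numeric vector of in-R-loop edit frequencies, one per
#'   called position over the gRNA-dependent sites (concatenated across
#'   sites); or an `edit_calls` data frame with a `freq` column.
#' @param fit an [fit_occupancy()] result, or a bare scaling in (0, 1].
#' @param n_differential_peaks differential peak count for the
#'   peaks-per-edit ratio (NA to skip).
#' @param ploidy copies of the genome per cell, default 2 (diploid).
#' @return An `absolute_quant` list: edits_per_genome,
#'   n_differential_peaks, peaks_per_edit, scaling, ploidy, n_positions.
#' @export
edits_per_genome <- function(site_freqs, fit, n_differential_peaks = NA,
                             ploidy = 2) {
  if (is.data.frame(site_freqs)) site_freqs <- site_freqs$freq
  scaling <- if (inherits(fit, "occupancy_fit")) fit$scaling else fit
  if (!is.numeric(scaling) || scaling <= 0) {
    stop("occupancy scaling must be positive")
  }
  epg <- sum(site_freqs, na.rm = TRUE) * scaling * ploidy
  ppe <- if (!is.na(n_differential_peaks) && epg > 0) {
    n_differential_peaks / epg
  } else NA_real_
  structure(list(edits_per_genome = epg,
                 n_differential_peaks = n_differential_peaks,
                 peaks_per_edit = ppe,
                 scaling = scaling, ploidy = ploidy,
                 n_positions = sum(!is.na(site_freqs))),
            class = "absolute_quant")
}

#' @export
print.absolute_quant <- function(x, ...) {
  cat(sprintf("absolute_quant: %.1f edits per genome", x$edits_per_genome))
  if (!is.na(x$peaks_per_edit)) {
    cat(sprintf(" (%s peaks -> %.3g peaks per edit)",
                format(x$n_differential_peaks, big.mark = ","),
                x$peaks_per_edit))
  }
  cat("\n")
  invisible(x)
}

#' Fold comparison of two quantities
#'
#' @param a,b numerator and denominator (numbers, or `absolute_quant`
#'   objects whose `edits_per_genome` is compared).
#' @param label_a,label_b labels carried in the report.
#' @return list with `fold` (a/b, 3 significant figures), labels and raw
#'   values.
#' @export
fold_comparisons <- function(a, b, label_a = "A", label_b = "B") {
  va <- if (inherits(a, "absolute_quant")) a$edits_per_genome else a
  vb <- if (inherits(b, "absolute_quant")) b$edits_per_genome else b
  if (vb == 0) stop("zero denominator in fold comparison")
  list(fold = signif(va / vb, 3), numerator = label_a,
       denominator = label_b, value_numerator = va, value_denominator = vb)
}

#' Summarise an editor dose-response series
#'
#' For each metric, the fold change across the series is the value at the
#' highest dose divided by the value at the lowest dose. On-target editing
#' is flagged flat when its fold change is at most `flat_threshold` --
#' the saturation signature that lets the off-target burden be reduced by
#' lowering the dose without losing on-target efficiency.
#'
#' @param series data frame with a `dose` column (e.g. pmol mRNA per 1e6
#'   cells) and one column per metric (on-target edit frequency, off-target
#'   R-loop signal, off-target edit frequency, ...).
#' @param metrics metric column names; defaults to all non-dose columns.
#' @param flat_threshold on-target flatness bound, default 1.2.
#' @return A `dose_response` list: per-metric fold changes, the dose range
#'   used, and `on_target_flat` when a metric named like "on_target*" is
#'   present.
#' @export
dose_response <- function(series, metrics = setdiff(names(series), "dose"),
                          flat_threshold = 1.2) {
  if (nrow(series) < 2L) stop("dose series needs >= 2 doses")
  d <- series$dose
  if (is.unsorted(d) && is.unsorted(rev(d))) {
    stop("doses must be strictly increasing or decreasing")
  }
  hi <- which.max(d); lo <- which.min(d)
  folds <- vapply(metrics, function(m) {
    series[[m]][hi] / series[[m]][lo]
  }, numeric(1))
  on_idx <- grep("^on_target", metrics)
  flat <- if (length(on_idx)) {
    all(pmax(folds[on_idx], 1 / folds[on_idx]) <= flat_threshold)
  } else NA
  structure(list(folds = folds, dose_high = d[hi], dose_low = d[lo],
                 on_target_flat = flat),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response over %.3g to %.3g:\n", x$dose_high,
              x$dose_low))
  for (m in names(x$folds)) {
    cat(sprintf("  %s: %.3g-fold (high/low dose)\n", m, x$folds[m]))
  }
  if (!is.na(x$on_target_flat) && x$on_target_flat) {
    cat("  on-target editing is flat across the series\n")
  }
  invisible(x)
}
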