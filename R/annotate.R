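#' Build a transcript gene model
#'
#' Minimal CDS-exon gene model supporting categorical edit annotation.
#' Exons are given in genomic coordinates (0-based half-open) and must be
#' non-overlapping within a transcript; the concatenated CDS length must be
#' divisible by 3.
#'
#' @param exons data frame with transcript, chrom, strand, start, end.
#' @return A validated `gene_model` data frame sorted by transcript and
#'   genomic position.
#' @export
gene_model <- function(exons) {
  req <- c("transcript", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons))) {
    stop("gene model needs columns: ", paste(req, collapse = ", "))
  }
  exons <- exons[order(exons$transcript, exons$start), , drop = FALSE]
  for (tx in unique(exons$transcript)) {
    e <- exons[exons$transcript == tx, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons in transcript ", tx)
    }
    if (sum(e$end - e$start) %% 3L != 0L) {
      stop("CDS length of transcript ", tx, " is not divisible by 3")
    }
    if (length(unique(e$strand)) != 1L) {
      stop("mixed strands in transcript ", tx)
    }
  }
  class(exons) <- c("gene_model", "data.frame")
  exons
}

# CDS coordinate (0-based, in transcription direction) of a genomic
# position within a transcript's exons, or NA if intronic/outside.
cds_coordinate <- function(pos, exons) {
  strand <- exons$strand[1]
  e <- exons[order(exons$start), , drop = FALSE]
  inside <- which(pos >= e$start & pos < e$end)
  if (!length(inside)) return(NA_integer_)
  if (strand == "+") {
    before <- sum(pmax(0L, e$end[seq_len(inside - 1L)] -
                         e$start[seq_len(inside - 1L)]))
    before + (pos - e$start[inside])
  } else {
    k <- nrow(e) - inside
    after <- if (k > 0L) {
      sum(e$end[(inside + 1L):nrow(e)] - e$start[(inside + 1L):nrow(e)])
    } else 0L
    after + (e$end[inside] - 1L - pos)
  }
}

#' Classify a single edit against a gene model
#'
#' CDS edits are translated through the standard genetic code in transcript
#' frame with strand-aware codon extraction and reported as missense (with
#' a protein change such as T428A; stop changes are reported the same way)
#' or synonymous. Intronic positions within `splice_window` bp of an exon
#' boundary are splice_donor (intron side of the exon's 3' end in
#' transcription direction) or splice_acceptor (intron side of the next
#' exon's 5' end). Other positions inside a transcript span are intronic;
#' everything else is intergenic. The first overlapping transcript is
#' reported as primary; all overlapping transcripts are listed.
#'
#' @param chrom,pos,ref,alt the edit (pos 0-based; ref/alt on the reference
#'   plus strand).
#' @param genes a [gene_model()].
#' @param reference DNAStringSet.
#' @param splice_window intronic bp defining splice sites, default 2
#'   (the canonical GT/AG positions).
#' @return A `site_annotation` list: category, transcript,
#'   protein_change (missense/synonymous only), all_transcripts.
#' @export
classify_edit <- function(chrom, pos, ref, alt, genes, reference,
                          splice_window = 2L) {
  refseq <- setNames(as.character(reference), names(reference))
  if (!chrom %in% names(refseq)) stop("edit contig not in reference")
  txs <- unique(genes$transcript[genes$chrom == chrom])
  overlapping <- character(0)
  primary <- NULL
  for (tx in txs) {
    e <- genes[genes$transcript == tx & genes$chrom == chrom, ,
               drop = FALSE]
    span_lo <- min(e$start); span_hi <- max(e$end)
    if (pos < span_lo || pos >= span_hi) next
    overlapping <- c(overlapping, tx)
    if (!is.null(primary)) next
    cat_tx <- classify_within_transcript(pos, ref, alt, e,
                                         refseq[[chrom]], splice_window)
    primary <- c(list(transcript = tx), cat_tx)
  }
  ann <- if (is.null(primary)) {
    list(category = "intergenic", transcript = NA_character_,
         protein_change = NA_character_)
  } else {
    list(category = primary$category, transcript = primary$transcript,
         protein_change = primary$protein_change)
  }
  ann$all_transcripts <- overlapping
  class(ann) <- "site_annotation"
  ann
}

classify_within_transcript <- function(pos, ref, alt, exons, refseq,
                                       splice_window) {
  e <- exons[order(exons$start), , drop = FALSE]
  strand <- e$strand[1]
  in_exon <- any(pos >= e$start & pos < e$end)
  if (in_exon) {
    cds_pos <- cds_coordinate(pos, e)
    cds_ref <- transcript_cds(e, refseq)
    codon_idx <- cds_pos %/% 3L
    within <- cds_pos %% 3L
    codon <- substr(cds_ref, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    alt_tx <- if (strand == "+") alt else unname(COMPLEMENT[alt])
    codon_alt <- codon
    substr(codon_alt, within + 1L, within + 1L) <- alt_tx
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(codon)))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(codon_alt)))
    if (aa_ref == aa_alt) {
      return(list(category = "synonymous",
                  protein_change = sprintf("%s%d%s", aa_ref,
                                           codon_idx + 1L, aa_alt)))
    }
    return(list(category = "missense",
                protein_change = sprintf("%s%d%s", aa_ref, codon_idx + 1L,
                                         aa_alt)))
  }
  # intronic: locate the flanking exon boundaries
  donor <- FALSE; acceptor <- FALSE
  for (i in seq_len(nrow(e))) {
    # intron 3' of exon i (genomic right side)
    if (pos >= e$end[i] && pos < e$end[i] + splice_window) {
      if (strand == "+") donor <- TRUE else acceptor <- TRUE
    }
    # intron 5' of exon i (genomic left side)
    if (pos < e$start[i] && pos >= e$start[i] - splice_window) {
      if (strand == "+") acceptor <- TRUE else donor <- TRUE
    }
  }
  if (donor) return(list(category = "splice_donor",
                         protein_change = NA_character_))
  if (acceptor) return(list(category = "splice_acceptor",
                            protein_change = NA_character_))
  list(category = "intronic", protein_change = NA_character_)
}

# Spliced CDS sequence of a transcript in transcription direction.
transcript_cds <- function(exons, refseq) {
  e <- exons[order(exons$start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(e)), function(i) {
    substr(refseq, e$start[i] + 1L, e$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (e$strand[1] == "-") revcomp(s) else s
}

#' @export
print.site_annotation <- function(x, ...) {
  cat("site_annotation:", x$category)
  if (!is.na(x$protein_change)) cat(" (", x$protein_change, ")", sep = "")
  if (!is.na(x$transcript)) cat(" in", x$transcript)
  cat("\n")
  invisible(x)
}

#' Overlap sites with named regulatory interval sets
#'
#' Half-open interval intersection (>= 1 bp); abutting intervals do not
#' overlap. One logical flag column per interval set plus a summary count.
#'
#' @param sites data frame with chrom, start, end.
#' @param interval_sets named list of data frames (chrom, start, end), e.g.
#'   list(atac = ..., h3k27ac = ...).
#' @return list with `flags` (sites with one logical column per set) and
#'   `counts` (sites overlapping each set).
#' @export
overlap_regulatory <- function(sites, interval_sets) {
  stopifnot(length(interval_sets) >= 1L, !is.null(names(interval_sets)))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$start + 1L,
                                                 sites$end))
  flags <- sites
  for (nm in names(interval_sets)) {
    iv <- interval_sets[[nm]]
    igr <- GenomicRanges::GRanges(iv$chrom,
                                  IRanges::IRanges(iv$start + 1L, iv$end))
    flags[[nm]] <- IRanges::overlapsAny(sgr, igr)
  }
  counts <- vapply(names(interval_sets), function(nm) sum(flags[[nm]]),
                   integer(1))
  list(flags = flags, counts = counts)
}

#' Score variant effects with a pluggable scorer
#'
#' The scorer contract: a function of (reference window, edited window)
#' returning a scalar effect in log2 fold change convention (negative =
#' loss of accessibility). Deep-learning accessibility models can be
#' plugged in through this interface; the package itself ships no model.
#'
#' @param sites data frame with chrom, pos (0-based), ref, alt.
#' @param scorer function(ref_window, alt_window) -> scalar.
#' @param reference DNAStringSet.
#' @param window half-width of the sequence window around the edit.
#' @return `sites` with a `score` column, ranked by decreasing |score|
#'   (ties by site order).
#' @export
score_variants <- function(sites, scorer, reference, window = 50L) {
  refseq <- setNames(as.character(reference), names(reference))
  scores <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- refseq[[sites$chrom[i]]]
    lo <- max(1L, sites$pos[i] + 1L - window)
    hi <- min(nchar(s), sites$pos[i] + 1L + window)
    ref_w <- substr(s, lo, hi)
    alt_w <- ref_w
    substr(alt_w, sites$pos[i] + 2L - lo, sites$pos[i] + 2L - lo) <-
      sites$alt[i]
    sc <- try(scorer(ref_w, alt_w), silent = TRUE)
    if (inherits(sc, "try-error")) {
      stop("scorer failed for site ", i, " (", sites$chrom[i], ":",
           sites$pos[i], "): ", attr(sc, "condition")$message)
    }
    scores[i] <- sc
  }
  out <- sites
  out$score <- scores
  out[order(-abs(out$score), seq_len(nrow(out))), , drop = FALSE]
}
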