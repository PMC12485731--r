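#' Write a read set as a coordinate-sorted SAM file
#'
#' Alignments are all-match by construction (the simulator emits pre-aligned
#' reads); MD and NM tags are computed against the supplied reference so the
#' emitted bases are self-describing.
#'
#' @param reads a `read_set` data frame.
#' @param reference DNAStringSet the reads were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  sl <- attr(reads, "seqlengths")
  if (is.null(sl)) {
    sl <- setNames(Biostrings::width(reference), names(reference))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ctg in names(sl)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, sl[[ctg]]), con)
  }
  if (nrow(reads) == 0L) return(invisible(path))
  o <- order(match(reads$chrom, names(sl)), reads$start)
  reads <- reads[o, , drop = FALSE]
  refseq <- setNames(as.character(reference), names(reference))
  flags <- ifelse(reads$strand == "-", 16L, 0L)
  md_nm <- mapply(function(chrom, start, seq) {
    ref <- substr(refseq[[chrom]], start + 1L, start + nchar(seq))
    md_tag(ref, seq)
  }, reads$chrom, reads$start, reads$seq, SIMPLIFY = FALSE)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
    reads$qname, flags, reads$chrom, reads$start + 1L, nchar(reads$seq),
    reads$seq, strrep("I", nchar(reads$seq)),
    vapply(md_nm, `[[`, integer(1), "nm"),
    vapply(md_nm, `[[`, character(1), "md"))
  writeLines(lines, con)
  invisible(path)
}

# MD/NM for an all-match alignment: runs of matches interleaved with the
# mismatched reference bases.
md_tag <- function(ref, seq) {
  rb <- strsplit(ref, "")[[1]]
  sb <- strsplit(seq, "")[[1]]
  mm <- which(rb != sb)
  if (!length(mm)) {
    return(list(md = as.character(length(rb)), nm = 0L))
  }
  parts <- character(0)
  prev <- 0L
  for (i in mm) {
    parts <- c(parts, as.character(i - prev - 1L), rb[i])
    prev <- i
  }
  parts <- c(parts, as.character(length(rb) - prev))
  list(md = paste(parts, collapse = ""), nm = length(mm))
}

#' Read aligned reads from a SAM or BAM file into a read set
#'
#' SAM input is converted through [Rsamtools::asBam()]. Only all-match
#' (single `M` CIGAR) alignments are supported, matching what the simulator
#' emits.
#'
#' @param path SAM or BAM file.
#' @return A `read_set` data frame with a `seqlengths` attribute.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)
  sl <- hdr$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  a <- Rsamtools::scanBam(bf, param = p)[[1]]
  keep <- !is.na(a$pos)
  if (any(!grepl("^[0-9]+M$", a$cigar[keep]))) {
    stop("read_alignments supports all-match CIGAR alignments only")
  }
  seqs <- as.character(a$seq)[keep]
  reads <- data.frame(
    chrom = as.character(a$rname)[keep],
    start = a$pos[keep] - 1L,
    width = nchar(seqs),
    strand = ifelse(bitwAnd(a$flag[keep], 16L) > 0L, "-", "+"),
    seq = seqs,
    qname = a$qname[keep],
    stringsAsFactors = FALSE
  )
  attr(reads, "seqlengths") <- sl
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Write peaks in narrowPeak-style BED6+4 format
#'
#' Columns: chrom, start, end, name, score (`round(-10*log10(q))`, capped at
#' 1000), strand ".", enrichment fold, -log10 p, -log10 q, summit offset.
#'
#' @param peaks peak data frame from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- pmin(1000, round(-10 * log10(pmax(peaks$q, 1e-100))))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    sprintf("peak_%d", seq_len(nrow(peaks))), score, ".",
                    signif(peaks$enrichment, 4),
                    signif(-log10(pmax(peaks$p, 1e-300)), 4),
                    signif(-log10(pmax(peaks$q, 1e-300)), 4),
                    peaks$summit - peaks$start)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first 6 columns) as a data frame
#' @param path BED path.
#' @return data frame with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  names(x)[seq_len(min(6, ncol(x)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[
      seq_len(min(6, ncol(x)))]
  x
}

#' Write edit calls as a minimal VCF
#'
#' CHROM/POS (1-based)/REF/ALT with DP, AF, FRAME and SITE INFO keys.
#' @param calls edit call data frame from [call_edits()].
#' @param reference DNAStringSet for header contig lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edit_vcf <- function(calls, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       Biostrings::width(reference)),
               paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
                      "Description=\"Depth\">"),
               paste0("##INFO=<ID=AF,Number=1,Type=Float,",
                      "Description=\"Alt frequency\">"),
               paste0("##INFO=<ID=FRAME,Number=1,Type=String,",
                      "Description=\"NTS or TS strand frame\">"),
               paste0("##INFO=<ID=SITE,Number=1,Type=String,",
                      "Description=\"Site id\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    site <- if ("site_id" %in% names(calls)) calls$site_id else "."
    frame <- if ("frame" %in% names(calls)) calls$frame else "."
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f;FRAME=%s;SITE=%s",
      calls$chrom, calls$pos + 1L, calls$ref, calls$alt, calls$depth,
      calls$freq, frame, site), con)
  }
  invisible(path)
}
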