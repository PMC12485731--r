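#' Read a pipeline run configuration
#'
#' A flat YAML key-value file; unknown keys are rejected. See
#' [run_config()] for keys and defaults.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::yaml.load_file(path))
}

#' Construct a pipeline run configuration
#'
#' @param outdir output directory.
#' @param protospacer,pam_pattern guide definition (defaults: HEK4, NGG).
#' @param editor editor profile name ("CBE-eBE", "ABE8e", "ABE8e-SpRY").
#' @param peak_q,differential_fdr,homology_min_score stage thresholds.
#' @param edit_min_depth,edit_min_freq edit-calling thresholds.
#' @param occupancy_scaling amplicon-to-R-loop proportionality used for
#'   absolute quantification (and for the simulated amplicon table).
#' @param ploidy genome copies for edits-per-genome.
#' @param seed RNG seed for the whole run.
#' @param ... simulator settings forwarded to [sim_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = tempfile("becaskas_run_"),
                       protospacer = hek4_guide()$protospacer,
                       pam_pattern = "NGG", editor = "CBE-eBE",
                       peak_q = 0.05, differential_fdr = 0.05,
                       homology_min_score = 20L, edit_min_depth = 20L,
                       edit_min_freq = 0.02, occupancy_scaling = 0.66,
                       ploidy = 2, seed = 1L, ...) {
  if (differential_fdr <= 0 || differential_fdr >= 1) {
    stop("differential_fdr must lie in (0, 1)")
  }
  sim <- sim_config(rng_seed = seed, ...)
  structure(list(outdir = outdir,
                 guide = guide_spec(protospacer, pam_pattern),
                 editor = editor, peak_q = peak_q,
                 differential_fdr = differential_fdr,
                 homology_min_score = homology_min_score,
                 edit_min_depth = edit_min_depth,
                 edit_min_freq = edit_min_freq,
                 occupancy_scaling = occupancy_scaling,
                 ploidy = ploidy, seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Stages are executed in order: simulate -> signal -> differential ->
#' homology -> edits -> quantify. Each stage writes its declared text
#' outputs under `config$outdir` and a manifest records parameters, seed
#' and a content digest for every file. A stage failure halts the run with
#' a stage-scoped message; outputs of completed stages are retained.
#'
#' @param config a [run_config()].
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  editor <- get_editor_profile(config$editor)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res$simulate <- stage("simulate", {
    ref0 <- generate_reference(config$sim)
    planted <- plant_offtargets(ref0, config$guide, config$sim, editor)
    reference <- planted$reference
    truth <- planted$truth
    write_reference(reference, file.path(config$outdir, "reference.fa"))
    write_truth_bed(truth, file.path(config$outdir, "truth_sites.bed"))
    reads <- list()
    k <- 0L
    for (cond in c("pulldown", "input")) {
      for (g in c("plus", "minus")) {
        for (r in seq_len(config$sim$replicates)) {
          k <- k + 1L
          nm <- sprintf("%s_%s_rep%d", cond, g, r)
          reads[[nm]] <- simulate_reads(
            reference, truth, editor, condition = cond, gRNA = g,
            config = config$sim, seed = config$seed * 1000L + k)
        }
      }
    }
    list(reference = reference, truth = truth, reads = reads)
  })
  reference <- res$simulate$reference
  truth <- res$simulate$truth
  reads <- res$simulate$reads

  res$signal <- stage("signal", {
    bins <- bin_counts(reads)
    write.table(bins, file.path(config$outdir, "bin_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rep_names <- grep("^pulldown_plus", names(reads), value = TRUE)
    rep_cor <- if (length(rep_names) >= 2L) {
      correlate_bins(bins, rep_names[1], rep_names[2])
    } else NA_real_
    peaks <- lapply(seq_len(config$sim$replicates), function(r) {
      call_peaks(reads[[sprintf("pulldown_plus_rep%d", r)]],
                 reads[[sprintf("input_plus_rep%d", r)]],
                 q_threshold = config$peak_q)
    })
    for (r in seq_along(peaks)) {
      write_narrowpeak(peaks[[r]], file.path(
        config$outdir, sprintf("total_peaks_rep%d.narrowPeak", r)))
    }
    list(bins = bins, replicate_correlation = rep_cor, peaks = peaks)
  })

  res$differential <- stage("differential", {
    cons <- consensus_peaks(res$signal$peaks, min_support = 2L)
    plus <- grep("^pulldown_plus", names(reads), value = TRUE)
    minus <- grep("^pulldown_minus", names(reads), value = TRUE)
    ct <- count_table(reads[c(plus, minus)], cons,
                      rep(c("plus", "minus"), c(length(plus),
                                                length(minus))))
    # library-size factors: the consensus intervals are candidate
    # gRNA-dependent sites, so median-of-ratios over them would absorb
    # the very effect being tested
    libsize <- vapply(reads[c(plus, minus)], nrow, integer(1))
    dr <- test_differential(ct, fdr = config$differential_fdr,
                            sf = libsize)
    write.table(dr, file.path(config$outdir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- dr[dr$differential, c("chrom", "start", "end"), drop = FALSE]
    write.table(sig, file.path(config$outdir, "differential_peaks.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    list(consensus = cons, result = dr, peaks = sig)
  })

  res$homology <- stage("homology", {
    peaks <- res$differential$peaks
    if (!nrow(peaks)) stop("no differential peaks to scan")
    hits <- scan_peaks(peaks, reference, config$guide,
                       min_score = config$homology_min_score)
    write.table(hits, file.path(config$outdir, "homology_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pwm <- if (nrow(hits)) build_pwm(hits) else NULL
    if (!is.null(pwm)) {
      write.table(pwm, file.path(config$outdir, "pwm.tsv"), sep = "\t",
                  quote = FALSE)
    }
    list(hits = hits, pwm = pwm)
  })

  res$edits <- stage("edits", {
    hits <- res$homology$hits
    if (!nrow(hits)) stop("no homology hits to profile")
    pd <- do.call(rbind, lapply(
      grep("^pulldown_plus", names(reads), value = TRUE),
      function(nm) reads[[nm]]))
    attr(pd, "seqlengths") <- attr(reads[[1]], "seqlengths")
    class(pd) <- c("read_set", "data.frame")
    pd <- pd[order(pd$chrom, pd$start), , drop = FALSE]
    spans <- data.frame(chrom = hits$chrom,
                        start = pmax(0L, hits$start - 61L),
                        end = hits$end + 61L)
    pile <- pileup(pd, spans, reference)
    profiles <- lapply(seq_len(nrow(hits)), function(i) {
      pam_relative_profile(hits[i, ], pile, editor)
    })
    names(profiles) <- hits$peak_id
    calls <- call_edits(pile, config$sim$sequencing_error,
                        min_depth = config$edit_min_depth,
                        min_freq = config$edit_min_freq, editor = editor)
    write_edit_vcf(calls, reference,
                   file.path(config$outdir, "edit_calls.vcf"))
    agg <- aggregate_profiles(profiles)
    write.table(agg, file.path(config$outdir, "edit_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(pileup = pile, profiles = profiles, calls = calls,
         aggregate = agg)
  })

  res$quantify <- stage("quantify", {
    amp <- simulate_amplicon_table(truth,
                                   occupancy_scaling =
                                     config$occupancy_scaling,
                                   seed = config$seed + 77L)
    fit <- fit_occupancy(amp)
    quant <- edits_per_genome(res$edits$calls, fit,
                              n_differential_peaks =
                                nrow(res$differential$peaks),
                              ploidy = config$ploidy)
    report <- list(occupancy_scaling = fit$scaling,
                   edits_per_genome = quant$edits_per_genome,
                   peaks_per_edit = quant$peaks_per_edit,
                   n_differential_peaks = quant$n_differential_peaks,
                   n_edit_calls = nrow(res$edits$calls),
                   replicate_correlation =
                     res$signal$replicate_correlation)
    jsonlite::write_json(report, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, quant = quant, report = report)
  })

  files <- list.files(config$outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("becaskas")),
    seed = config$seed,
    editor = config$editor,
    guide = config$guide$protospacer,
    parameters = list(peak_q = config$peak_q,
                      differential_fdr = config$differential_fdr,
                      homology_min_score = config$homology_min_score),
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
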