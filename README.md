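# becaskas

Detection and quantification of CRISPR base-editor off-target activity
from ssDNA pulldown sequencing (beCasKAS-style experiments), for genome
editing and gene-therapy safety researchers who need to nominate,
characterise and absolutely quantify off-target R-loops and the deaminase
edits they license.

## The problem and the model

Base editors (a Cas9 nickase/dead-Cas9 fused to a deaminase) edit the
single-stranded DNA exposed when the Cas9 R-loop displaces the non-target
strand (NTS). R-loop formation precedes and rate-limits every edit, so an
assay that covalently labels unwound ssDNA, pulls it down and sequences it
captures both the unwinding intermediate (as read enrichment) and the
edits themselves (as strand-specific base conversions in the reads).

The package implements the complete downstream analysis:

* **Total peaks** — local-Poisson enrichment of pulldown over input:
  sliding 300-bp windows tested against
  λ_local = r · max(λ_1kb, λ_5kb, λ_10kb, λ_genome), one-sided Poisson
  upper tail, BH correction, merge-and-summit.
* **Differential peaks** — negative-binomial Wald test of plus- vs
  minus-gRNA counts over replicate-consensus intervals: median-of-ratios
  size factors, method-of-moments dispersion shrunk halfway in log space
  toward a fitted α(μ) = a₁/μ + a₀ trend, moderated-df t reference,
  positive-fold calls at FDR < 0.05.
* **Homology** — exhaustive ungapped protospacer+PAM scan of peak
  sequences (+2 match / −3 mismatch, PAM as a hard gate), PAM-adjacent
  seed lengths, position weight matrices, and seed+PAM motif enrichment
  against GC-matched background.
* **Edit profiling** — strand-aware conversion pileups mapped into
  PAM-relative coordinates (−1 abuts the PAM), NTS and TS frames,
  binomial edit calling against the sequencing error rate, mutational
  context spectra, and autocorrelation-based detection of the ~11-bp
  helical periodicity of out-of-protospacer edits.
* **Absolute quantification** — the occupancy scaling s from a
  through-origin regression of amplicon on in-R-loop frequencies, then
  edits per genome = Σ_sites,positions f · s · ploidy, peaks-per-edit
  ratios, editor comparisons and dose-response summaries.
* **Annotation** — missense/synonymous/splice/intronic/intergenic
  classification of edits against a CDS gene model, regulatory interval
  overlap, and a pluggable variant-effect-scorer interface.
* **Synthetic experiments** — a fully parameterised generator (reference,
  planted off-target sites with seed-dependent occupancy
  ω = ω_max · δ^mismatches, pulldown/input ± gRNA read sets, amplicon
  tables) with known ground truth, used by every calibration test.

See `vignettes/becaskas-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

A small synthetic experiment, run end to end:

```r
library(becaskas)
cfg <- run_config(outdir = file.path(tempdir(), "demo"), seed = 7,
                  genome_length = 50000, n_offtargets = 4,
                  mismatch_distribution = c(`0` = 1, `2` = 2, `4` = 1),
                  background_depth = 60, replicates = 3)
res <- run_pipeline(cfg)

res$simulate$truth[, c("site_id", "start", "strand", "mismatch_count",
                       "seed_match_length", "occupancy")]
#>   site_id start strand mismatch_count seed_match_length occupancy
#> 1 site_01  6012      -              0                20  0.800000
#> 2 site_02 13779      +              2                18  0.338000
#> 3 site_03 42881      +              2                18  0.338000
#> 4 site_04 47275      -              4                16  0.142805
```

Four sites are planted: the on-target (0 mismatches, occupancy 0.8) and
three off-targets whose occupancy decays 0.65-fold per mismatch. The
differential caller recovers the three strongest as gRNA-dependent peaks
(the 4-mismatch site at occupancy 0.14 falls below the replicate
consensus at this depth):

```r
res$differential$result[, c("start", "end", "log2FC", "q", "differential")]
#>   start   end   log2FC            q differential
#> 1  5650  6400 1.964904 4.859765e-08         TRUE
#> 2 13450 14100 1.150477 1.287057e-05         TRUE
#> 3 42550 43200 1.137756 1.287057e-05         TRUE

res$homology$hits[, c("peak_id", "start", "strand", "score",
                      "seed_match_length")]
#>   peak_id start strand score seed_match_length
#> 1  peak_1  6012      -    40                20
#> 2  peak_2 13779      +    30                18
#> 3  peak_3 42881      +    30                18
```

The homology scan lands exactly on the planted coordinates and strands;
scores follow 2·matches − 3·mismatches (40 for the perfect on-target hit,
30 for 18/20 matches). The aggregate PAM-relative profile shows the CBE
editing window at the target cytosines (both aggregation conventions are
emitted):

```r
subset(res$edits$aggregate, frame == "NTS" & position %in% c(-18, -16, -13))
#>    position frame mean_of_sites    pooled n_sites
#> 43      -18   NTS     0.3015707 0.3131673       3
#> 45      -16   NTS     0.4055460 0.4723708       3
#> 48      -13   NTS     0.2113510 0.2526502       3

print(res$quantify$fit)
#> occupancy_fit: scaling 0.631 (residual sd 0.0152, n = 41)

print(res$quantify$quant)
#> absolute_quant: 4.7 edits per genome (3 peaks -> 0.644 peaks per edit)
```

The occupancy fit recovers the configured amplicon proportionality (0.66)
from the noisy simulated table, and the quantification stage converts the
called in-R-loop edit frequencies into an absolute per-(diploid-)genome
editing burden and a peaks-per-edit ratio.

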