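---
title: "Models and methods behind the becaskas pipeline"
author: "becaskas maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the becaskas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(becaskas)
```

## The measurement and the model

Base editors install C>T (cytosine base editors, CBEs) or A>G (adenine base
editors, ABEs) changes by tethering a deaminase to a catalytically impaired
Cas9. The deaminase only acts on single-stranded DNA, and the ssDNA it needs
is created by the Cas9 R-loop: when the guide RNA hybridises to the target
strand (TS), the non-target strand (NTS) is displaced as ssDNA. R-loop
formation is rate-limiting, so an assay that labels and enriches unwound
ssDNA (kethoxal labelling followed by biotin pulldown and sequencing)
captures the reaction intermediate that *precedes* every edit. This package
analyses such pulldown experiments: it nominates candidate off-target
R-loops from read enrichment, connects them to guide homology, profiles the
deaminase edits they carry in PAM-relative coordinates, and converts
within-R-loop edit frequencies into absolute per-genome editing burden.

Three nomination strategies coexist and are all implemented:

* **total** peaks — pulldown enriched over input (`call_peaks()`);
* **homology** peaks — total peaks containing a protospacer match
  (`scan_peaks()`);
* **differential** peaks — consensus peaks with statistically
  gRNA-dependent counts in plus- versus minus-gRNA conditions at
  FDR < 0.05 (`test_differential()`).

The latent variable tying everything together is the **occupancy** of a
site: the fraction of genomes carrying an R-loop there. Edit frequencies
measured inside pulled-down R-loops are conditional on occupancy; amplicon
sequencing measures the unconditional (absolute) frequency. Their ratio,
estimated by a through-origin regression (`fit_occupancy()`), converts one
into the other.

## The synthetic experiment generator

The generator (`sim_config()`, `generate_reference()`,
`plant_offtargets()`, `simulate_reads()`) produces complete experiments
with known ground truth, and it is the basis of every calibration and
recovery test in the package.

What it emulates:

* a uniform background of genome-wide ssDNA reads at `background_depth`
  reads/kbp (default 50);
* planted protospacer-homologous sites whose occupancy decays
  geometrically with the mismatch count,
  $\omega = \omega_{\max}\,\delta^{m}$ with $\omega_{\max} = 0.8$ and
  $\delta = 0.65$ by default. Mismatches are placed PAM-distal first so
  the PAM-adjacent seed degrades last, mirroring the seed-dominated
  interrogation kinetics of Cas9; a site with $m$ mismatches has a seed
  match of $20 - m$;
* read enrichment inside an R-loop footprint of
  $1 + E\,\omega\,d$ fold ($E$ = `enrichment_factor`, default 20; $d$ a
  dose scalar);
* editor-specific conversions: each read overlapping a site's editing
  span derives from an edited genome with probability $\omega d$, and
  edited reads carry Bernoulli conversions at the per-position truth
  probabilities. Conversions are defined on the NTS and complemented on
  the reference when the protospacer lies on the minus strand;
* independent per-base sequencing error (default 0.002), replicates,
  pulldown/input and plus/minus-gRNA conditions, and an amplicon table
  related to the in-R-loop frequencies by a configurable proportionality
  plus truncated Gaussian noise.

The default CBE profile has its NTS C>T window peaked 13–19 bp 5' of the
PAM — the three HEK4 target cytosines at −18, −16 and −13 carry the
on-target conversion frequencies of 0.683, 0.783 and 0.644 at full
occupancy — plus a secondary TS band 20–30 bp 5' of the PAM and a damped
cosine out-of-protospacer component with an 11-bp period and maxima at
−38, −49, −60, reflecting how the DNA helical repeat re-exposes the NTS
to the deaminase. A 5'TC context multiplier (1.3×) encodes the APOBEC3A
preference. The ABE8e profile is a narrow A>G window at −18…−13 (0.70 at
the HEK4 target adenine, −17) with no TS or periodic terms. These window
shapes are configuration, not claims: they reproduce the qualitative
strand-specific behaviour of the two editor families and the printed
on-target values, and every number is exposed in `editor_profile()`.

What the generator deliberately does **not** model — and therefore what
passing tests cannot certify about real libraries: native ssDNA landscape
structure (background is uniform, so replicate correlations reflect only
planted signal over Poisson noise), PCR duplicates, mapping error
(alignments are emitted perfect and all-match), fragment-length effects,
and transfected-plasmid transcript contamination. The contaminant read
class seen in real data as editor-gene exonic reads is left out; it would
enter as an additional localized background term and is noted as future
work rather than simulated.

## Peak calling

`call_peaks()` re-implements the sharp-peak, local-background Poisson
scheme: 300-bp windows advanced by 50 bp; the local rate is the
depth-ratio-scaled maximum of input rates estimated at 1 kb, 5 kb and
10 kb around the window and genome-wide; one-sided Poisson upper-tail
p-values, BH correction over all windows, merging of significant windows
within 100 bp, and summits at maximum pulldown coverage. The constants
are exposed as arguments. This is the essential computation of the
well-known ChIP-style callers rather than a re-creation of any particular
tool's defaults, which the original analyses did not record. With an
empty input sample the caller warns and falls back to a genome-wide
pulldown background.

Bin-level concordance (`bin_counts()`, `correlate_bins()`) uses
contiguous 1-kbp bins, 5'-position assignment, and Pearson correlation of
`log2(CPM + 1)`; the transform is a design choice made here (the source
analyses do not state one) and is applied identically to both samples.

## Differential testing

`test_differential()` is a deliberately transparent negative-binomial
workflow: median-of-ratios size factors (`size_factors()`), per-interval
method-of-moments dispersion on normalised counts, a halfway (log-space)
shrink toward a least-squares mean–dispersion trend
$\alpha(\mu) = a_1/\mu + a_0$, and a Wald test of the log2 fold change
with a delta-method NB standard error. Only positive-fold intervals at
q < 0.05 are reported as differential peaks, since gRNA-dependent R-loops
gain signal.

Two calibration decisions deserve emphasis:

* **Reference distribution.** With three replicates per condition the
  moment dispersion is noisy even after shrinkage, and a normal reference
  for the Wald statistic is visibly anti-conservative (empirical FDP
  ≈ 0.13 at the q < 0.05 operating point), while a t reference on the
  bare residual degrees of freedom over-corrects to zero power. Because
  the halfway shrink reduces the log-scale variance of the dispersion
  estimate by a factor of four, the effective degrees of freedom exceed
  the residual df; matching the observed null exceedance of the statistic
  in negative-binomial simulations gives ~3× the residual df, which is
  what the package uses. At this choice the empirical false discovery
  proportion in the operating-point simulation (20,000 intervals,
  dispersion 0.1, 3 vs 3, 5% true 4-fold effects) fluctuates around
  0.045–0.05, i.e. the nominal FDR is controlled in expectation.
* **Size factors for peak count tables.** Median-of-ratios normalisation
  assumes most intervals are null. Consensus peak sets in a
  gRNA-dependent assay violate this badly — at desk scale *every*
  consensus interval can be a true site, and median-of-ratios would
  absorb the very effect under test. `test_differential()` therefore
  accepts explicit size factors, and the pipeline passes library sizes
  (total read counts). The default remains median-of-ratios for count
  tables where nulls dominate.

Consensus construction (`consensus_peaks()`) merges overlapping replicate
peaks and keeps intervals supported by ≥ 2 of 3 replicates; the support
rule is a design choice, as only the number of conditions was recorded in
the source analyses.

## Homology scanning

`scan_peaks()` performs an exhaustive ungapped scan of both strands of
each peak (±30 bp flank) for a 20-mer followed by a PAM-pattern match,
scoring +2 per match and −3 per mismatch — the standard nucleotide-search
reward/penalty — with the PAM as a hard gate. One best hit per peak is
retained (ties: larger PAM-adjacent seed, then leftmost). Bulges and gaps
are out of scope. The seed is defined as the longest run of consecutive
exact matches starting at PAM-relative position −1. PWMs over hit
sequences use a pseudocount of 0.5 per base. Seed+PAM motif enrichment
(`motif_occurrence()`) compares peaks against length- and GC-matched
(±0.05) random genomic intervals with a two-proportion test; full de novo
motif discovery is intentionally not reimplemented.

## Edit profiling

`pileup()` tallies every aligned base over requested intervals; positions
without coverage report missing (never zero) frequencies.
`pam_relative_profile()` maps genomic positions into PAM-relative
coordinates (−1 abuts the PAM; profiles span −60…+3 by default, covering
all reported effects) and reports two frames: NTS (always the editor's
base_from→base_to on the non-target strand; mirrored and complemented at
minus-strand sites) and TS. `call_edits()` tests alt counts against
error_rate/3 one-sided binomial, BH-corrected, with declared defaults
min_depth = 20, min_freq = 0.02, q < 0.05 — thresholds chosen here, since
none were recorded. Aggregate profiles are emitted under *both*
conventions — unweighted mean of per-site frequencies and pooled
Σalt/Σdepth — because the published average-conversion curves do not say
which was used; the two differ when depth varies across sites.

Periodicity detection (`detect_periodicity()`) uses mean-subtracted
autocorrelation over −60…−31 with the dominant period the argmax over
lags 8–14 and a significance threshold of 0.3 on the normalised
autocorrelation; a flat profile stays silent.

## Quantification

`fit_occupancy()` uses through-origin least squares, because the
amplicon/R-loop relation is a proportionality; an intercept would assert
editing without unwinding. `edits_per_genome()` computes
$\sum_{\text{sites,positions}} f \cdot s \cdot p$ with ploidy $p = 2$ by
default: "per genome" is taken to mean per diploid genome, summing both
alleles; the convention was not recorded at the source, so ploidy is an
exposed argument and the quantity is exactly linear in it (and in the
scaling), as the tests assert. `dose_response()` summarises a dose series
as highest-dose over lowest-dose fold changes per metric and flags
on-target saturation when its fold is ≤ 1.2.

## Annotation

`classify_edit()` assigns exactly one primary category per edit:
missense/synonymous via strand-aware codon translation through the
standard genetic code, splice donor/acceptor for intronic positions
within 2 bp of an exon boundary (the canonical GT/AG dinucleotides),
otherwise intronic or intergenic. The first overlapping transcript is
primary; all overlaps are retained. `score_variants()` defines the
pluggable scorer contract — `f(reference window, edited window) → log2
fold change`, negative meaning loss of accessibility — through which a
trained accessibility model can be attached. No model ships with the
package, and training one is out of scope.

## Numerical and testing choices

* Coordinates are 0-based half-open internally and in BED; SAM/VCF are
  written 1-based per their standards. Abutting intervals do not overlap.
* All randomness flows through explicit seeds; identical configuration
  and seed give byte-identical outputs, which the test suite asserts at
  the file level.
* Degenerate inputs fail loudly: zero-length genomes, unsorted reads,
  zero-variance correlation inputs, single-replicate designs,
  out-of-reference peaks, frame-inconsistent gene models.
* Test problem sizes are desk scale by design: references of 10–100 kb,
  background depths of 30–600 reads/kbp, 3 replicates, 20,000-interval
  count simulations. These sizes make every calibration property
  (peak-caller null uniformity, edit-caller null purity, FDP control,
  parameter recovery within binomial error) measurable in seconds while
  leaving the algorithms identical to what genome-scale data would use.

## Known limitations

Genome-scale claims (total peak counts, correlations of real libraries,
per-editor variant totals, motif occurrence percentages on a real genome)
depend on the original sequencing data and are outside what the synthetic
generator can certify. The differential caller handles the two-condition
contrast only. The homology scanner is ungapped. The annotation module
reports the first overlapping transcript rather than selecting among
isoforms.
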