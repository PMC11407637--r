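---
title: "Quantifying stop-codon readthrough from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stop-codon readthrough from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

riboRT measures translational readthrough of normal stop codons from
ribosome profiling data and relates it to mRNA sequence features. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the choices made where the design was open.

## Coordinates and the region model

All coordinates are 0-based, half-open, in transcript space. The CDS runs
from the first nucleotide of the annotated AUG to the last nucleotide of the
last sense codon; the stop codon is counted as part of the 3′-UTR. This
convention makes "distance from stop = 0" the last sense nucleotide, so the
3′-UTR is exactly the region with distance > 0.

`partition_regions()` computes two extension conventions side by side,
because they serve different analyses:

- `rt_ext_*`: from the canonical stop codon (inclusive) to the next in-frame
  stop codon (exclusive). This region backs the readthrough statistic: a
  ribosome that decodes the stop with a near-cognate tRNA elongates through
  precisely this interval before re-terminating. Its length is always a
  multiple of 3.
- `figext_*`: from the end of the stop window (stop codon plus 3 nt flanks)
  to the end of `rt_ext`. Together with the 5′-UTR, start window (AUG ± 3
  nt), CDS body, stop window and distal 3′-UTR it tiles the transcript
  exactly once, which is what region-percentage accounting needs. The 3-nt
  flanks absorbed into the start/stop windows are deliberately *not* counted
  as CDS; regions are disjoint with window priority.

Transcripts whose 3′-UTR contains no downstream in-frame stop are flagged
`open_extension`; their extension runs to the last complete codon, and
readthrough analyses exclude them by default because the extension length —
the denominator of the statistic — is then ill-defined.

## P-site model

Footprint lengths 20–23 and 27–32 nt are admitted by default, the two size
classes protected by the ribosome. Each read's P-site is `5′ end +
offset(length)`, with offsets from a curated table or, as a fallback,
estimated per length as the modal distance from read 5′ ends to annotated
start codons (`estimate_offsets()`, minimum 200 supporting reads, neighbor
inheritance below that). The reading frame is `(psite − cds_start) mod 3`;
a footprint spanning two regions is assigned by its P-site position alone.

Metagene windows default to −25..+80 nt around each anchor; the window width
is configuration, not inference, and profiles are normalized by the summed
count over both windows jointly so the two-window profile sums to one.

## The readthrough-efficiency statistic

For each mRNA and strain (replicates pooled),

$$\mathrm{RT} = \frac{n^{f0}_{\text{ext}} / L_{\text{ext}}}
                     {n^{f0}_{\text{cds}} / L_{\text{cds}}}$$

using frame-0 counts only — out-of-frame 3′-UTR footprints arise from
frameshifting or reinitiation, not readthrough — and excluding the first
15 nt of the CDS, where initiating ribosomes pile up. Both the CDS count and
its length use the same truncated support, so numerator and denominator are
densities over identical intervals (the alternative, truncating the count
but not the length, biases the statistic by a fixed factor; consistency of
support decided the choice).

The statistic is reported only for mRNAs passing two density filters:
CDS RPKM > 0.2 and extension RPKM > 0.1, both computed from *all-frame*
region counts over the full region length — RPKM is a plain region density
and the frame restriction applies only to the efficiency itself. Library
size for RPKM is the total number of P-site-assigned footprints passing the
length filter in that unit, the most self-contained definition. Zero
frame-0 extension counts with filters passing give RT = 0; a zero CDS
frame-0 count (essentially impossible once the CDS filter passes) yields an
undefined value rather than infinity.

Under the generator's model (below), RT estimates the per-ribosome
readthrough rate ρ: extension occupancy is ρ × CDS density, so the two are
estimands of each other. The density filters induce a detection limit — at
low coverage, only mRNAs with lucky extension counts pass, which biases
conditional estimates upward. The parameter-recovery tests therefore run at
deep, homogeneous coverage (10 reads/nt, abundance spread 0.3 log units,
extensions of 10–25 codons), where the median estimate across a panel of
transcripts with a common planted ρ ∈ {0.005, 0.02, 0.05, 0.2} lands within
15% of truth and rank correlation with heterogeneous truth exceeds 0.9.
These are properties of the estimator at adequate depth; at survey-depth
coverage the detectability flag, not the point estimate, is the reliable
signal.

## Translation-efficiency testing

TE is CDS footprint density normalized to RNA abundance. Counts enter as a
gene × library matrix per layer (ribo: P-sites within the CDS minus the
first 15 and last 3 nt; RNA: external counts), each layer normalized by
median-of-ratios size factors. The differential machinery is deliberately
simple and fully specified:

- Per-gene dispersions by method of moments on normalized counts, shrunk
  50/50 in log space toward a log-linear mean–dispersion trend. With three
  replicates a raw moment estimate is extremely noisy; the trend supplies
  the stabilization that makes the test usable at this design size.
- A Wald test on the log ratio of condition means (abundance) or on the
  interaction contrast `log2((ribo_B/rna_B)/(ribo_A/rna_A))` (TE), with the
  delta-method variance `1/(n·μ) + α/n` summed over the contributing means
  and a normal reference. A prior count of 0.5 on each condition mean keeps
  the estimate finite at zero counts.

The contract is calibration, not bit-compatibility with any published tool:
on null NB simulations (3 vs 3, dispersion 0.04) the BH-adjusted rejection
fraction stays well below 5% (raw p-values are mildly anti-conservative at
n = 3, which the adjusted criterion absorbs), and planted 4-fold abundance
changes at mean count 200 are recovered with ≥ 80% power. Planted ±1 log2 TE
effects are estimated with median absolute error ≤ 0.2 at mean count ≥ 100
and dispersion 0.02. Classification thresholds follow the layer conventions:
adjusted p < 0.01 (RNA/ribo), < 0.05 (TE), < 0.015 (externally supplied
protein tables), sign of the fold change giving Up/Down, regardless of
magnitude. Optional independent filtering (masking low-count genes before
BH at the threshold maximizing rejections) is off by default so gene sets
are deterministic.

## mRNA features

- **uORFs**: every AUG starting in the 5′-UTR opens a candidate, no minimum
  length; the first in-frame stop ending at or before the main AUG makes it
  `upstream`, otherwise (including no stop before the transcript end) it is
  `overlapping`.
- **Poly(A) tracts**: the rule "at least 10 consecutive adenines allowing at
  most 2 other nucleotides in the window" is self-contradictory read
  literally; it is operationalized as *a 10-nt window containing ≥ 8
  adenines*. For the 5′-UTR the scanned region extends to include the A of
  the main AUG (only up to that A, not the whole codon).
- **Oligo(U)**: an exact run of ≥ 7 uracils, no interruptions.
- **Codon optimality**: tAI weights from tRNA gene copy numbers, with each
  codon served by its Watson-Crick decoder plus the canonical wobble decoder
  for its third base (G34:U s = 0.41, I34:C s = 0.28, I34:A s = 0.9999,
  U34:G s = 0.68; Watson-Crick s = 0). AUG takes only its dedicated
  initiator/elongator decoder. Weights are normalized to the best codon and
  zero weights replaced by the geometric mean of the nonzero ones; the
  per-CDS score is the geometric mean over codons (stop excluded). The
  penalty set ships as an editable TSV; the bundled copy-number table is a
  synthetic yeast-like fixture for tests, not a measured dataset.
- **Stop context**: the stop codon occupies positions +1+2+3; the first
  3′-UTR nucleotide is +4. Context covers +4..+9, the last sense (P-site)
  codon, UTR lengths and extension length.
- **Out-of-frame QC**: the fraction of non-frame-0 P-sites in the last 30 nt
  of the CDS (≥ 30 footprints required for correlation analyses), a flag
  for +1/+2-frame stop triplets in the CDS, and their relation to 3′-UTR
  footprint density — the control that distinguishes readthrough from
  upstream frameshifting.

## Random-forest importance

25 models per strain (5-fold CV, 5 repeats, folds stratified by response
quantile — the stratification choice is ours, recorded here), 100 trees,
`mtry = floor(sqrt(p))`, seeds derived deterministically from one master
seed. Model performance is RMSE on the held-out fold normalized to the range
of the *full* response vector, so all 25 models share one normalization.

The reported importance is %IncMSE: the mean increase in out-of-bag MSE upon
permuting a feature, as a percentage of the model's baseline OOB MSE.
Empirical p-values come from refitting each model on permuted responses;
the observed-vs-null comparison uses the variance-scaled importance (mean
OOB MSE increase divided by its standard error) because %IncMSE normalizes
by the model's own baseline MSE, which differs systematically between a
signal-bearing fit and its permutation nulls — comparing the scaled score
keeps negative controls calibrated even when a strong feature drives the
model. Categorical features stay native factors (the forest implementation
splits on them directly), so a feature is always permuted as one column and
importance is reported per original feature. A feature is overall
significant when p < 0.05 in ≥ 15 of 25 models; with fewer models the rule
rescales proportionally and is flagged.

The full-scale analysis uses 1,000 permutation refits per model; tests and
the acceptance script use 25 (p-resolution 1/26 ≈ 0.038, still below the
0.05 threshold) to keep a 25-model × 20-seed calibration study inside a
desktop time budget. The permutation count is configuration, not semantics.

## The synthetic generator

`sim_config()` defaults encode the emulated study design: three strains
(readthrough multipliers 1 / 1.5 / 3; the double mutant also carries TE and
RNA effects in 10% of genes at ±1 log2), three replicates, frame-0 fidelity
0.9, log-uniform per-ribosome readthrough rates in 0.005–0.1, read lengths
peaking at 28 nt with an S7-style offset table, log-normal transcript
abundance (sdlog 0.8), NB RNA counts with dispersion 0.02 (typical of yeast
replicate libraries), an initiation pause of 5× the per-codon density on the
start codon, and a uniform background at 0.1% of the per-nt CDS density.
Extension occupancy is density-proportional (ρ per CDS ribosome); the
distal 3′-UTR receives ρ² — double readthrough — plus background, giving it
a mechanistically consistent low signal without a free parameter.

Sequences are built to make planted truth exactly recoverable: AUG at
`cds_start`, a stop at `cds_end`, the next in-frame stop planted at the
configured distance with no earlier one (extension codons are drawn from
sense codons only), and 5′/3′ features placed and then *verified with the
package's own scanners*, rejection-sampling until the scanner output matches
the intended flag. What passing plant/detect tests shows is internal
consistency of scanner and generator — not that the scanners match any
external annotation pipeline.

The generator does not simulate sequencing error, rRNA contamination, UMI
artifacts, alignment ambiguity, or nucleotide-composition biases; footprint
counts are Poisson given the transcript's rate, so the ribo layer carries no
extra biological dispersion. Calibration and recovery results on synthetic
data therefore bound what the methods can do under their own model
assumptions; real libraries add noise sources the tests do not exercise.

## Numerical choices and degenerate inputs

- Windows truncate at transcript ends; intervals are never negative.
- A 5′-UTR shorter than the flank produces a truncated start window; a
  3′-UTR shorter than 6 nt yields missing context positions, flagged.
- Rank-sum tests are exact for tie-free samples with min(n) ≤ 8, otherwise
  normal with tie and continuity correction; all-tied input returns p = 1
  with a flag. Spearman p-values are exact below n = 10 without ties.
- Chi-squared tests fall back to Fisher when any expected count is below 1.
  Exact-test p-values are clamped to 1 against floating-point overshoot.
- t-tests default to the Welch variant; the pooled variant is a flag.
- Size factors require at least one gene nonzero in every library and fail
  loudly otherwise.
- All simulation and resampling paths accept explicit seeds and restore the
  caller's RNG state.

## Problem sizes

Tests and the acceptance script run deliberately scaled-down studies chosen
to make each property measurable with margin on a single CPU: 100–150
transcripts per simulated experiment (recovery panels at 10 reads/nt), 20
seeds × 800–1,000 genes for null calibration, 4,000 replicates for empirical
test sizes, 500 planted genes of 3,000 for TE recovery (a panel large enough
that the median-absolute-error measurement reflects the estimator rather
than panel noise), and 120 observations × 25 models × 25 permutations for
the importance scheme.

## Known limitations

- The NB test is a calibrated generic, not a reimplementation of any
  published tool's shrinkage estimators; at one replicate per condition it
  degrades to a pooled-dispersion heuristic with a prominent warning.
- The readthrough statistic cannot distinguish frame-0 reinitiation from
  true readthrough; the out-of-frame QC and distal-region accounting bound,
  but do not eliminate, that confound.
- Detection-limit selection biases conditional readthrough estimates upward
  at low coverage; comparisons across strains with similar depth are robust
  to this, absolute values at shallow depth are not.
- `overlap_filter()` is quadratic within a chromosome-strand group —
  adequate for transcriptome-scale inputs, not for million-interval sets.
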