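# riboRT

Frame-resolved ribosome profiling analysis of stop-codon readthrough.

## The problem

When a ribosome reaches a stop codon it normally terminates, but a
near-cognate tRNA can occasionally out-compete the release factors and decode
the stop, so elongation continues in frame into the 3′-UTR until the next
in-frame stop codon. Genome-wide, this *readthrough* leaves a characteristic
signature in ribosome profiling data: footprints downstream of the annotated
stop that keep the reading frame of the CDS. riboRT quantifies that signature
per mRNA and asks which mRNA features predict it.

The package covers the full analysis path from aligned footprints to feature
importance:

- **Region partition.** Each spliced transcript (0-based, half-open
  coordinates; the CDS excludes the stop codon, which belongs to the 3′-UTR)
  is partitioned into 5′-UTR, a start window (AUG ± 3 nt), the CDS body, a
  stop window (stop ± 3 nt), the *extension* — from the canonical stop codon
  (inclusive) to the next in-frame stop codon (exclusive) — and the distal
  3′-UTR beyond it.
- **P-site accounting.** Footprints of 20–23 nt and 27–32 nt are kept, each
  read's P-site is placed at `5′ end + offset(read length)`, and its reading
  frame is `(psite − cds_start) mod 3`. Metagene profiles and region × frame
  occupancy tables follow from the P-site positions alone.
- **Readthrough efficiency.** Per mRNA,

  ```
  RT = (frame-0 count in extension / extension length)
     / (frame-0 count in CDS      / CDS length)
  ```

  with the first 15 nt of the CDS excluded (start-codon pile-up) and the
  statistic reported only for mRNAs with CDS RPKM > 0.2 and extension
  RPKM > 0.1 ("detectable readthrough").
- **Translation efficiency (TE).** CDS footprint counts (P-sites in UTRs and
  in the first 15 nt / last 3 nt of the CDS discarded) are tested against
  RNA-Seq counts with a generic negative-binomial interaction Wald test;
  genes are classed Up/Down/Unchanged at adjusted p < 0.05 (TE) or < 0.01
  (RNA).
- **mRNA features.** uORFs (AUG-initiated, upstream vs overlapping), poly(A)
  tracts (10-nt window with ≥ 8 adenines), oligo(U) runs (≥ 7 exact), codon
  optimality as the geometric mean of tAI weights (tRNA gene copy numbers
  with wobble penalties), stop codon and its +4..+9 nucleotide context,
  P-site codon, and out-of-frame QC quantities.
- **Feature importance.** Random-forest regression of readthrough efficiency
  on the feature table: 5-fold cross-validation repeated 5 times (25 models,
  100 trees, mtry = √p), permutation importance (%IncMSE) with empirical
  p-values from response-permutation refits, and the aggregate rule that a
  feature is important when p < 0.05 in ≥ 15 of 25 models. Random continuous
  and categorical columns ride along as negative controls.

A synthetic-data generator (`simulate_experiment()`) emulates the study
design — three strains with scaled readthrough, three replicates, frame-0
fidelity ~0.9, NB-distributed RNA counts, planted uORFs/tracts/extension
lengths — with full ground truth, so every stage is testable end to end.

## Worked example

Simulate a three-strain experiment, write it as a fixture, and run the
pipeline:

```r
library(riboRT)
cfg <- sim_config(n_transcripts = 150, ribo_depth = 3, abundance_sdlog = 0.4,
                  ext_codon_range = c(5L, 20L))
sim <- simulate_experiment(cfg, seed = 42)
write_fixture(sim, "demo")
res <- run_pipeline("demo", out_dir = "demo/results")

rt <- res$readthrough
rt[detectable == TRUE,
   .(n_detectable = .N,
     median_rt = signif(median(readthrough_efficiency, na.rm = TRUE), 3)),
   by = strain]
#>        strain n_detectable median_rt
#> 1:         WT          125    0.0314
#> 2: pab1dpbp1d          146    0.0694
#> 3:      pbp1d          130    0.0414

res$strain_tests[, .(strain_a, strain_b, pvalue = signif(pvalue, 3),
                     padj = signif(padj, 3))]
#>      strain_a   strain_b   pvalue     padj
#> 1:         WT pab1dpbp1d 5.28e-11 1.58e-10
#> 2:         WT      pbp1d 7.51e-03 7.51e-03
#> 3: pab1dpbp1d      pbp1d 1.27e-05 1.91e-05

table(res$te$class)
#>      Down Unchanged        Up
#>         6       137         7
```

The double-deletion strain (readthrough multiplier 3 in the generator) shows
more detectable-readthrough mRNAs and a higher median efficiency than the
wild type (0.0694 vs 0.0314), and the pairwise rank-sum tests flag every
strain contrast after Benjamini-Hochberg adjustment — the qualitative
phenotype the statistic is designed to expose. The TE layer, which carries a
planted effect in 10% of genes, classifies a handful of genes Up/Down at
adjusted p < 0.05.

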