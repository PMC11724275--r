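# nacquant

Desk-scale quantification of **nascent**, **mature** and **ambiguous** RNA
from single-cell and single-nucleus RNA-seq, with a background filter built
from **distinguishing flanking k-mers (DFKs)**.

## The problem

Droplet RNA-seq reads come from molecules at every stage of processing:
spliced mRNA, unspliced pre-mRNA, and transcription outside annotated genes
altogether. Two things go wrong when such reads are quantified against a
spliced-transcriptome ("standard") index:

1. **Mismapping.** A read that straddles an exon boundary or comes from an
   intergenic locus can still share k-mers with an indexed transcript and
   will be attributed to it, inflating counts.
2. **Lost modality.** With only mature targets in the index there is no way
   to tell spliced from unspliced molecules, which biophysical models of
   transcription need as separate counts.

`nacquant` implements the combined remedy at desk scale, for method
exploration and teaching:

* a **nac index** containing, per gene, the mature transcripts *and* one
  nascent target spanning the full gene body (exons + introns), so every
  UMI can be classified as
  **M** (spans an exon–exon junction — must be processed),
  **N** (carries sequence unique to an intron — must be unprocessed), or
  **A** (purely exonic — compatible with both);
* a **D-list filter**: the genome (or any decoy set) is scanned against the
  index's compact de Bruijn graph; for every maximal shared stretch of
  ≥ k bases, the flanking k-mers on each side — present in the D-list but
  absent from the graph — are stored as uncolored DFK vertices. A read
  containing any DFK is masked out instead of mismapped. Per graph vertex
  at most 2(|Σ|−1) = 6 flanking k-mers can be distinguishing, so the DFK
  store needs only O(min(N_k, M_k)) space for N_k graph k-mers and M_k
  D-list k-mers.

The three UMI matrices combine as `cell = M + A`, `nucleus = N + A`,
`total = N + M + A`.

The package also ships the surrounding apparatus: pseudoalignment by
color-set intersection with dynamically allocated equivalence classes,
UMI collapse, sparse MatrixMarket output, TCC (EC × cell) matrices, a
seeded read simulator with truth matrices and a
mismatch-then-deletion-then-insertion error model, and the evaluation
metrics used for such pipelines — RMSE, false positive/negative
representation (matrix-size denominator), per-cell Pearson `r` and
zero-filtered Spearman `ρ*`.

## Worked example

Simulate a small experiment (10 genes, 20 cells, 100 UMIs per cell, 0.5%
mismatch errors), build a nac index with the genome as D-list, quantify,
and compare with the simulation truth:

```r
library(nacquant)
library(dplyr)

cfg    <- sim_config(n_genes = 10, n_cells = 20, umis_per_cell = 100, seed = 42)
ref    <- simulate_reference(cfg)
bundle <- simulate_reads(ref)
reads  <- bundle$reads
reads$seq <- inject_errors(reads$seq, cfg$mismatch_rate, seed = 43)

targets <- bind_rows(
  extract_mature_transcripts(ref$genome, ref$annotation),
  extract_nascent_transcripts(ref$genome, ref$annotation))
idx <- build_index(targets, k = 31, dlist = ref$genome)
#> quant_index (nac): k = 31, 20 targets, 14636 colored k-mers, 20 DFKs

q <- quantify_reads(idx, reads, barcodes = bundle$barcodes)
q$counts
#> N/M/A count matrices: 20 barcodes x 10 genes; UMIs N = 472  M = 264  A = 1048

evaluate_counts(sum_matrices(bundle$truth, "total"),
                sum_matrices(q$counts, "total"))
#> quant_metrics over 20 cells x 10 genes
#>   RMSE      0.17321
#>   FPR       0.00000
#>   FNR       0.00000
#>   median r  1.0000   median rho* 1.0000
```

Reading the numbers: of 2000 reads, 31 contained a DFK and were masked
(they straddled a gene boundary), intron-evidence UMIs landed in `N`,
junction UMIs in `M`, purely exonic UMIs in `A`. The residual RMSE of 0.17
comes entirely from reads the 0.5% error rate pushed off their k-mers
(dropped UMIs), not from mismapping: FPR is exactly zero.

`tidy()` / `glance()` give per-cell and one-row summaries of a
`quant_metrics` object, `autoplot()` draws the per-cell correlation
distributions, and `plot_knee()` the barcode rank plot.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "nacquant", package = "nacquant")` with subcommands
`simulate`, `ref`, `index` (`--d-list`, `--d-list-overhang`), `count`
(`--sum cell|nucleus|total`, `--mult`, `--dfk-onlist`) and `evaluate`;
every run writes a `manifest.json` with its resolved parameters and seed.

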