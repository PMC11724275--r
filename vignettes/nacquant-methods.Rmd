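---
title: "Methods: DFK filtering and nascent/mature/ambiguous quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DFK filtering and nascent/mature/ambiguous quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, and the choices made where the design was
genuinely open. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

### Targets

A **standard** index contains one target per mature (spliced) transcript:
exon subsequences concatenated in transcript order, reverse-complemented
for minus-strand genes so every target reads 5'→3'. A **nac** index adds
one **nascent** target per gene: the contiguous genomic subsequence over
the union span of the gene's exons, introns included. GTF input is 1-based
inclusive on disk and converted to 0-based half-open intervals at parse
time; all internal arithmetic uses the converted form. The nascent target
id is the gene id plus a configurable suffix (default `-I`). Overlapping
genes each get their own nascent target; their shared k-mers simply carry
multi-gene colors.

### Graph and colors

Indexing is strand-agnostic: every k-mer is represented by its canonical
form, the lexicographic minimum of the k-mer and its reverse complement.
`k` must therefore be odd (an odd-length k-mer cannot be its own reverse
complement); the default `k = 31` is the common choice for transcriptome
indexes, and toy examples in the tests use `k` in 3–15. The compact de
Bruijn graph merges maximal nonbranching paths of canonical k-mers into
unitigs. Colors (which targets contain each k-mer) are stored per k-mer
rather than per unitig interval — equivalent at this scale, and simpler;
per-unitig color compression is a performance concern this package
deliberately leaves aside, along with minimizer tables and perfect
hashing. Lookups go through an ordinary hash table.

Two compaction details worth stating exactly:

* A k-mer never extends to itself or to its own reverse complement, so a
  homopolymer run stays a single unitig rather than splitting at a formal
  self-loop.
* Because adjacency is defined on the canonical k-mer *set*, two branches
  of the graph can merge through a reverse-complement coincidence that the
  input strings never spell out contiguously. The compaction follows the
  set semantics; the unit tests verify, by exhaustive enumeration, that
  every unitig is a maximal path whose internal vertices have in- and
  out-degree one.

Unitig sequences are normalised to their canonical form and numbered
lexicographically, so graph construction is deterministic for fixed input.

### Distinguishing flanking k-mers

Given a D-list — by default the genome the targets came from — every
D-list sequence is scanned against the graph. A **common run** is a
maximal stretch of consecutive k-mer positions whose canonical k-mer is
present in the graph; it witnesses a shared sequence of at least k bases.
For each run, the up-to-`h` consecutive k-mers immediately upstream and
downstream (default overhang `h = 1`) are collected as DFKs, stopping at
the sequence boundary, at any window containing a non-ACGT character, and
at any k-mer already present in the graph. DFKs are by construction
absent from the graph and are stored apart from the colored k-mers,
uncolored.

During mapping a single DFK anywhere in a read is decisive: the read
carries sequence that continues past a shared stretch into non-target
territory, so it is discarded (or, under `dfk_onlist`, annotated with a
reserved D-list pseudo-target instead — useful for telling "did not map"
from "was filtered"). The pseudo-target id is `n_targets + 1`; it never
appears in the t2g table and is stripped before gene resolution.

On each side of a graph vertex there are |Σ| = 4 candidate flanking
k-mers; one of them is the vertex's own continuation in the target
sequence whenever that continuation exists, leaving at most |Σ|−1 = 3 per
side — 6 per vertex — that can be distinguishing. The acceptance suite
enumerates this capacity on a concrete graph and constructs a worst case
that attains it. At a sequence boundary a vertex may lack an in-graph
continuation, in which case the per-side cap is |Σ| rather than |Σ|−1;
the randomized bound test asserts the cap that actually applies. The
global count is always bounded by the number of distinct D-list k-mers.

**Overhang semantics.** `h` means "the h consecutive flanking k-mers on
each side of each run". The `h = 1` case is the standard one; larger `h`
is a strict superset (monotonicity is property-tested), and the synthetic
benchmark shows no accuracy change at `h = 2, 3` — consistent with single
overhangs being sufficient. Flank extension also stops early at a k-mer
that is in the graph; by run maximality this arises only through
canonicalization coincidences, and such a k-mer could never be a DFK
anyway.

### Pseudoalignment and equivalence classes

A read maps to the intersection of the color sets of its canonical
k-mers. k-mers absent from the index are skipped — they carry no
evidence; only DFK hits are fatal, and the DFK check short-circuits the
intersection. Reads shorter than k are unmapped, not an error. There is
no error-tolerant k-mer rescue: robustness to sequencing errors is
statistical (a read with an error usually retains enough clean k-mers).

Equivalence classes (target sets) receive integer ids on first
observation, in mapping order. Ids are therefore run-local; every export
that needs stability (TCC matrices, `ec.txt`) keys ECs by their sorted
target list instead.

### UMI collapse and classification

Records sharing (barcode, UMI) merge by **intersecting** their ECs'
target sets; a UMI whose reads have no target in common is dropped.
Union is the other defensible choice here; intersection was chosen as the
stricter rule consistent with how a single molecule's reads should agree,
and is stated as a package decision. No Hamming-distance UMI merging is
performed — exact UMI identity only.

A single-gene target set classifies as: only mature targets → **M**; only
the nascent target → **N**; both → **A**. Multi-gene UMIs are discarded
by default; with multimapping enabled they contribute 1/(number of genes)
to each compatible gene, with the status computed per gene from that
gene's own targets within the set, so per-gene N/M/A semantics stay
well-defined. The sum modes are entrywise: `cell = M + A`,
`nucleus = N + A`, `total = N + M + A`, and the identity
`cell + nucleus − A = total` is property-tested.

With a standard index every mapped target set is mature-only, so `N` is
identically zero and `--sum nucleus` is refused at the CLI.

## The simulator

The generator emulates a droplet experiment on a toy genome: `n_genes`
genes (default 20) of 2–4 exons of 150–400 bp separated by introns of
200–600 bp, random uniform base composition, random strand, one transcript
per gene, intergenic spacers sized so 30% of the contig is intergenic;
50 cells with 16 bp barcodes, 200 UMIs per cell with 12 bp UMIs unique
within a cell, one 90 bp read per molecule. Molecules are drawn
mature : nascent : intergenic = 0.55 : 0.35 : 0.10 — single-cell data is
dominated by processed mRNA but retains a sizable unspliced and a small
extragenic fraction. Intergenic windows always cover at least one
intergenic base and may straddle a gene boundary; that is precisely the
read class a genome D-list exists to mask. Errors are injected in three
passes in a fixed order — substitutions first (uniform over the three
alternative bases), then deletions, then insertions (uniform base after
the position) — at a default mismatch rate of 0.5% with indels off; the
order is part of the protocol, the per-event distributions are the
simplest unbiased choices.

**Ground truth.** The expected class of a read is defined by sequence
compatibility with its gene's two target forms: present only in the
spliced form → M, carrying sequence unique to an intron → N, present in
both → A; intergenic reads are expected to be filtered and never enter
the truth matrices. A purely positional rule (junction/intron/exon
footprint) disagrees with *any* sequence-based classifier for reads that
overlap an intron by j bases whose next j bases coincidentally match the
spliced junction (probability 4^−j per boundary read) — so compatibility,
not position, is the definition used; position and origin are still
recorded for diagnostics. Truth matrices tally one count per UMI at its
expected class.

What passing against this simulator does **not** show: real data has
non-uniform base composition and repeats (k-mer collisions between genes
are realistic, not negligible), barcode and UMI sequencing errors, PCR
duplication, coverage bias toward the 3' end, and annotation error. The
simulator makes none of these; results here demonstrate correctness of
the machinery, not performance on tissue.

## Evaluation metrics

For truth matrix entries y and program entries ŷ over n cells × m genes:
RMSE = sqrt(mean((y−ŷ)²)); FPR is the fraction of all n·m entries with
y = 0 and ŷ > 0; FNR the fraction with y > 0 and ŷ = 0 (note the
matrix-size denominator — these are representation rates, not classifier
rates). Per cell, `r` is Pearson over all genes and `ρ*` is Spearman with
average-rank ties computed after dropping gene pairs equal to (0, 0) in
both matrices. "Nonzero in both" is a subtly stricter reading of the same
idea; both are implemented (`rho_pairs = "both_nonzero"`), the
drop-(0,0)-pairs form is the default because it is the displayed
definition rather than a prose paraphrase. Cells with fewer than two
usable pairs, or a constant vector, have an undefined correlation and are
excluded from medians (their count is reported). Matrices are aligned by
barcode/gene label, never by position; differing label sets are an error,
and `conform_matrix()` exists to pad a prediction onto a truth universe.
Top-N barcode selection ranks by total count with lexicographic
tie-breaking.

## Numerical and degenerate-input choices

* Windows containing non-ACGT characters contribute no k-mer and break
  unitig extension, common runs and flank extension alike.
* `build_index` warns and skips targets shorter than k; an all-short
  target set is an error, as is a duplicate target id.
* Under `dfk_onlist`, a read whose only index evidence is DFKs maps to
  the pseudo-target alone (and is counted separately in the mapping
  stats); a read with colored k-mers but an empty intersection stays
  unmapped even if it also hit a DFK.
* All randomness in the simulator flows from explicit seeds
  (`withr::with_seed`), so identical seeds give byte-identical FASTQ and
  matrix files.
* Problem sizes in the test suite (tens of genes, tens of cells, ~10⁴
  reads, k = 5–31) are chosen so every oracle can be brute force and the
  whole suite stays interactive; they are stated in each test.

## Known limitations

* Colors per k-mer and plain hash tables cap practical index size well
  below genome scale; this is a reference implementation of the
  semantics, not a high-throughput tool.
* No barcode error correction against the on-list; unknown barcodes are
  dropped, not rescued.
* Ambiguous (A) counts are reported as their own matrix and never
  probabilistically reallocated to N or M.
* The EC-intersection collapse rule and the sequence-compatibility truth
  rule are documented package decisions where reasonable alternatives
  exist (union collapse; positional truth).
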