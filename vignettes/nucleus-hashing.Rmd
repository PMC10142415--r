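---
title: "Demultiplexing hashed single-nucleus ATAC-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing hashed single-nucleus ATAC-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Droplet snATAC-seq profiles open chromatin one nucleus at a time, but each
library preparation is a batch: samples processed separately pick up
technical variation that is hard to remove downstream. Nucleus hashing
solves this by staining each sample's nuclei with an antibody (against
nuclear pore complex proteins, so it works on nuclei rather than cells)
conjugated to a barcoded oligonucleotide, pooling the samples into one
library, and separating them again computationally from the barcode
("hash") reads. `snhash` implements the computational half of that design:
counting hash reads per nucleus, calling each nucleus's sample of origin,
validating those calls against genome alignments in barnyard (human+mouse)
mixtures, and the downstream peak analysis that compares single-cell peak
cluster structure with bulk ATAC intensities.

# The hashing read and its parsing model

A hashing oligo read has a fixed layout:

```
anchor5 – UMI1 – sample barcode – UMI2 – anchor3
```

with the droplet (cell) barcode carried by the separate index read. A
`hash_design()` records the layout: the barcode set, both UMI lengths
(default 8+8), the two constant anchors, and three mismatch tolerances.

Parsing proceeds in three stages, and a read's status records the first
stage that fails:

1. **Anchor** — `anchor5` is searched at start offsets 0–3 (tolerating
   imprecise trimming), allowing up to `anchor_mismatch_tol` (default 2)
   mismatches per anchor. Both mates are tried (read 2 as reverse
   complement first), and the attempt that parses furthest wins.
2. **Cell barcode** — the index read is matched to the whitelist; a
   non-exact barcode is corrected only to a *unique* whitelist member
   within `cell_mismatch_tol` (default 1). Ties are `ambiguous_cell`,
   misses `unknown_cell`.
3. **Sample barcode** — matched against the design with the same
   unique-winner rule under `hash_mismatch_tol` (default 1).

A design is only accepted when its minimum pairwise Hamming distance is at
least `2 * hash_mismatch_tol + 1`; this makes the unique-winner rule
deterministic — no read can sit within tolerance of two barcodes. The
shipped reference design uses four synthetic 8-nt barcodes at pairwise
distance ≥ 6, so tolerances up to 2 remain unambiguous.

# UMI collapse

Hash counts are PCR-amplified, so reads are deduplicated by UMI within each
(cell, sample) group. Identical UMIs always collapse. Because sequencing
errors split one molecule into near-identical UMIs, the default adds the
directional adjacency rule used by modern UMI deduplicators: UMI `b` is
absorbed into `a` when Hamming(`a`,`b`) = 1 and
`reads(a) >= 2 * reads(b) − 1`. The count threshold is deliberately
asymmetric: a true second molecule is unlikely to have both a 1-mismatch
UMI *and* far fewer reads than its neighbour. Exact-only collapse is
available (`method = "exact"`). The collapse is implemented in C++ for
throughput; tests check it against a slow, independent R implementation.

# Calling nuclei from hash counts

Nuclei are classified by the count-cutoff quadrant rule: with one cutoff
per sample, a nucleus is a **singlet** of the only sample at-or-above
cutoff, a **multiplet** when two or more samples reach cutoff, and
**negative** when none does. Cutoffs can be:

- **fixed** — a user constant (default fallback 10 counts);
- **mixture** (`auto_cutoff()`, default) — a two-component Gaussian
  mixture on `log1p(count)` per sample, fitted by EM with deterministic
  initialization (means at the 25th/75th percentiles, common SD, equal
  weights — reproducible with no seed). The cutoff is the smallest count
  whose high-component posterior exceeds 0.5. If the fitted means are
  closer than one log unit the distribution is treated as unimodal and the
  fixed fallback applies. At least 50 nuclei are required; fewer is an
  error that points to the fixed cutoff.
- **CLR-quantile** (`classify_hash_clr()`) — the cell-hashing convention:
  counts are CLR-normalized and each sample's threshold is the 0.99
  quantile of its negative cluster. Offered as an alternative mode; the
  quadrant rule is the default because it is what the cutoff-line scatter
  diagnostic (`plot_hash_scatter()`) depicts.

Reported percentages round half-up (two decimals for call summaries, one
for doublet summaries), matching how such tables are conventionally
printed.

# Barnyard validation

In a human+mouse mixture, genome alignments give an independent
classification: `assign_species()` calls a nucleus a species singlet when
the major genome holds at least `purity` (default 0.9) of its fragments, a
doublet when below purity with at least `min_minor` (default 100) minor
fragments, and undetermined otherwise. The purity and minor-count defaults
are package choices (alignment-based species calling is usually stated
only as "aligned to one vs both"); both are arguments. `concordance()`
then restricts to nuclei singlet under both schemes, builds the
genome × sample confusion matrix, counts discordant nuclei (hash sample's
species ≠ aligned genome), and tests association with Pearson's
chi-squared without continuity correction. When any expected cell is below
5 the statistic is flagged unreliable rather than silently switching to a
different test. A depth filter (`filter_nuclei()`, default ≥ 10,000 total
reads, inclusive) and the standard per-nucleus QC predicates
(`qc_filter_nuclei()`: reads-in-peaks < 15%, fragments-in-peaks < 2000,
blacklist ratio > 0.05, nucleosome signal outside (0.2, 4); each
toggleable) precede accuracy assessment.

# Peak cnum analysis

Given per-cluster peak sets and a union peak set, `assign_cnum()` counts
for each union peak the number of clusters containing an overlapping peak
(≥ 1 base, BED half-open convention — the common default of overlap
tooling; configurable via `min_overlap`). `attach_bulk()` adds the maximum
overlapping bulk peak score (max, not mean: robust when a union peak spans
two bulk peaks). The maximal-cnum (constitutive) group's bulk intensities
are typically bimodal — stochastic vs constant open regions — and
`dichotomize_intensity()` splits them with the same deterministic mixture
fit on log scores, reporting the density antimode as a bimodality
diagnostic; degenerate (all-equal) or small (< 100) inputs are errors that
point to `manual_threshold`. `annotate_features()` classifies each peak by
its midpoint with precedence promoter (TSS ± 2 kb, symmetric so effectively
strand-free) > 5'UTR > 3'UTR > exon > intron > intergenic; peaks on
chromosomes absent from the gene model are intergenic with a warning.
Short peaks (< 146 bp) are *not* filtered here — that filter belongs to an
upstream enhancer-identification pipeline — but `overlap_fraction()` /
`distance_to_nearest()` support the standard follow-up comparisons
(overlap percentages with a chi-squared contrast, absolute
midpoint-to-TSS distances).

# The synthetic-data generator

`simulate_experiment()` produces a complete, ground-truthed experiment:
record-synchronized FASTQ triplets (read 1 carries the layout, read 2 its
reverse complement, the index read the cell barcode), a whitelist of 10×
the nucleus count (emulating a valid-cell list, sampled without
replacement), per-genome fragment counts, and a truth table. The generative
model, with the `paper-like` defaults of `sim_config()`:

- hash reads per nucleus ~ NegBin(mean 300, size 3) — overdispersed so a
  small low-count tail yields realistic negatives (~2% below a ~30–50
  count cutoff);
- doublets at rate 0.12 receive hash reads from both constituent samples
  (50/50) and, for cross-species pairs, fragments from both genomes;
- ambient contamination: each hash read carries a wrong sample's barcode
  with probability 0.03, drawn uniformly from the other samples;
- substitution errors i.i.d. per base at 0.005 on all three reads;
- genome fragments ~ NegBin(mean 2000, size 2) with 2% cross-genome
  mapping noise; total reads per nucleus lognormal around 27,000 (the
  order of magnitude of ~450M read pairs over ~16k cells), so most nuclei
  clear the 10,000-read filter.

These defaults were calibrated once so the classified fractions echo the
~86% singlet / ~12% multiplet / ~2% negative proportions of a real 2-plex
run — a tuning target for realism, not a claim of distributional fidelity.
Everything is a pure function of `(config, design, seed)`; identical seeds
give byte-identical FASTQ files.

What the generator does **not** emulate: genomic read sequences or Tn5
insertion biology, per-cell depth/ambient correlations, index hopping,
barcode-specific staining efficiency differences, or quality-score
structure (qualities are constant). Passing tests therefore demonstrate
correctness of the computational pipeline under a plausible noise model,
not performance guarantees on any particular real dataset.

`simulate_cnum_fixture()` analogously generates cluster/bulk peak sets on
a synthetic chromosome with non-overlapping union peaks, true cnum drawn
with a constitutive-heavy weighting, bulk log-intensity increasing with
cnum, and an explicit two-component lognormal mixture (means log 1 and
log 4, SD 0.4, 40% low) for the maximal group.

# Accuracy metrics and problem sizes

Two recovery metrics are reported by the acceptance script and tests:

- **clean recovery** — with zero ambient/error/doublet noise, the fraction
  of simulated nuclei recovered as singlets of their true sample. Clean
  runs use a tight hash-depth dispersion (size 10) so that no nucleus draws
  zero hash reads: a nucleus without a single hash read is unrecoverable by
  construction and would measure the generator's tail, not the pipeline.
- **singlet-assignment accuracy** — under the realistic preset, the
  fraction of depth-filtered, truly-non-doublet nuclei *called singlet*
  that are assigned to the correct sample. This mirrors how demultiplexing
  accuracy is assessed in practice (mismatched calls among assigned
  nuclei); negatives are unassigned rather than wrong and are reported
  separately in the call summary.

Simulation sizes are chosen to exercise every code path while keeping the
default test run fast: unit tests use 40–500 nuclei, the end-to-end
acceptance checks 400–800, and the acceptance script 2,000 nuclei
(~600,000 hash reads) and 2,000 peaks.

# Numerical choices

- EM: 500 iterations max, log-likelihood tolerance 1e-8, SD floor 1e-4;
  components are ordered by mean after fitting. Posterior evaluation far
  outside the support falls back to nearest-mean assignment to avoid 0/0.
- Cutoffs are searched over integer counts (`auto_cutoff`) or observed
  unique scores (`dichotomize_intensity`), so thresholds are always
  attainable data values; classification uses `>=` (cutoff-inclusive).
- Anchor location prefers the smallest offset on ties; barcode matching
  breaks impossible ties (excluded by the design invariant) toward the
  first design barcode but records them as ambiguous when tolerances are
  misconfigured.
- Percentages round half away from zero (`round_half_up()`), not
  banker's rounding.
- Midpoints of half-open intervals use `floor((start + end) / 2)`;
  midpoint-to-anchor distances are absolute position differences.

# Limitations

- Cell-barcode correction at tolerance 1 uses neighbourhood expansion;
  higher tolerances fall back to scanning the whitelist per unmatched
  barcode, which is quadratic in the worst case.
- The mixture cutoff assumes a reasonably separated ambient/signal
  structure; heavily overlapping distributions trigger the unimodal
  fallback rather than an attempt at deconvolution.
- `concordance()` treats the sample→species map as total; samples without
  a species label cannot contribute concordant nuclei.
- No rescue of negatives or model-based reassignment of multiplets is
  attempted; nuclei below cutoff stay unassigned.
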