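---
title: "Quantifying RNA-tagging experiments: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA-tagging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyUtag)
```

# The assay and its quantification model

RNA tagging fuses an RNA-binding protein (RBP) to a poly(U) polymerase.
Binding events leave poly(U) stretches after the poly(A) tails of bound
transcripts, which 3'-end sequencing then reads out. Two empirical facts
shape the whole quantification:

* **Short U stretches (1–3 nt) are noise.** Their counts across genes track
  transcript abundance and persist with a catalytically dead enzyme — they
  behave like sequencing errors, not binding events.
* **Long stretches (4 nt and up) are signal.** They concentrate on a
  reproducible set of genes and correlate tightly with each other across
  genes, independent of expression.

All statistics in `polyUtag` follow from this split. The U-count matrix
records, per gene, reads at every stretch length 0–16 (overflow binned at
16, because that is where the matrix convention stops; the choice is
harmless since the binding score ignores lengths above 13 anyway). After
RPM normalization (total scaled to $10^6$):

$$\mathrm{exp}(g) = \sum_{u=0}^{16} \mathrm{RPM}(u,g), \qquad
  \mathrm{bs}(g) = \sum_{u=4}^{13} u\,\mathrm{RPM}(u,g), \qquad
  m(g) = \mathrm{bs}(g)/\mathrm{exp}(g).$$

The modification level $m$ is the average number of enzymatically added
uridines per transcript molecule of gene $g$; it is bounded by
$0 \le m \le 13$ and satisfies the sandwich
$m/13 \le \Pr(\text{molecule tailed with } 4\text{–}13\ \mathrm{U}) \le m/4$,
which the test suite asserts on every simulated matrix. Genes with zero
expression have undefined $m$ and are excluded from all statistics rather
than imputed — a pseudocount would manufacture modification levels for genes
the library never sampled.

**Target calling.** A gene is a target when $\log_2 m > -2.7$, strictly.
The threshold is the background modification level of the dead-enzyme
(dPup2) control; its linear form $2^{-2.7} = 0.1539$ is treated as a rounded
display value (0.15), not as a second threshold, so the log2 rule is the
single source of truth and the package verifies that both parameterizations
return identical sets.

**Tagging reliability.** For each stretch length $u \in 4..13$ we take the
best Pearson correlation of column $u$ with any *other* column in that
block (self excluded, undefined entries skipped) and report the median of
the ten values. The 4–13 restriction follows the block actually used for
reliability assessment; lengths 0–3 are error-dominated and 14–16 too rare
to correlate. Correlations are computed on untransformed RPM values (a log
display of the same matrix is a plotting choice, not part of the
statistic). On a dead-enzyme sample columns 4–16 can be identically zero, in
which case reliability is reported as undefined by an error rather than a
fabricated zero.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Per molecule (read):

1. a gene is drawn with probability proportional to its expression weight;
   weights come from a log-normal distribution (location 0, scale 1.5) —
   the standard heavy-tailed shape of mRNA abundance;
2. if the gene is a target and the enzyme is active, the molecule carries a
   genuine tail with probability $f$ (`tailed_fraction`, default 0.2), with
   length from `tail_length_dist` (default uniform on 4–13, zero mass on
   14–16);
3. otherwise, with probability $e$ (`error_stretch_rate`, default 0.05) it
   records a spurious stretch of length 1–3 (default probabilities
   0.5/0.3/0.2, decreasing with length as expected of error processes).

Defaults for the full experiment are 2000 genes, 200 targets, $10^6$ reads.
The per-molecule error model is deliberately gene-blind, so error counts
scale with abundance — the mechanism inferred from the dead-enzyme control.
The per-read error rate of the real assay is not known; $e = 0.05$ is a
placeholder at the right order of magnitude, not an estimate. Tails and
error stretches cannot co-occur on one molecule (errors apply only to
untailed molecules); at these rates the overlap would be a second-order
correction and modelling it would add a parameter the data cannot pin down.

The read-level simulator renders the *same* molecule stream (same seed
arithmetic) as the count-level simulator: read 1 falls inside the
$[\mathrm{TTS}-300, \mathrm{TTS}+100)$ sense window of its gene; read 2 is
an 8-mer UMI followed by the reverse complement of
`body + poly(A) (10–30 nt, uniform) + poly(U)-as-T + adapter stub`. The two
simulators therefore agree *exactly* after read processing, which the test
suite checks entry-for-entry on a 50,000-read experiment. To keep that
equivalence exact, UMIs are drawn without replacement within each gene
(cross-gene reuse still occurs); random 8-mers would occasionally collide
within a gene and be collapsed by deduplication, making the round trip
approximate for no modelling benefit. Collision handling in `dedup_umis()`
(keep the largest U count per `(gene, UMI)` pair) is tested separately on
hand-built records.

What the generator does **not** emulate: base-call quality profiles, PCR
duplication beyond UMI collisions, splice isoforms, antisense transcription,
internal priming, or overlapping gene windows (the toy transcriptome spaces
TTSs 1 kb apart). Passing tests therefore demonstrate the correctness of
the quantification logic under the stated generative model, not robustness
to every artefact of real libraries — window-overlap resolution is instead
tested directly against exhaustive enumeration on random annotations.

# Read processing conventions

* Coordinates are 0-based half-open throughout; the TTS window is
  $[\mathrm{TTS}-300, \mathrm{TTS}+100)$ measured along the direction of
  transcription (the upstream/downstream sizes are given; the half-open
  convention is this package's choice, asserted at the boundaries).
* Only sense reads are counted; a read inside the windows of several genes
  goes to the nearest TTS, with exact distance ties broken toward the
  lexicographically smaller gene id — any deterministic rule would do, this
  one needs no extra state.
* The poly(A) anchor is the **last** A-run of length ≥ 5 (`min_polya_run`,
  configurable); the U count is the contiguous T-run immediately after it,
  capped at 16. Pure runs only — a mismatch-tolerant run definition would
  need an error model the assay description does not provide. Reads without
  a qualifying A-run are rejected with reason `no_polya`.
* Replicates are combined by averaging RPM matrices (after a QC gate of
  > 200,000 raw reads *or* median reliability ≥ 0.8) and re-normalizing.
  "Combining" is not otherwise specified; the mean of normalized matrices
  weights replicates equally regardless of depth, which matches treating
  each passing replicate as one measurement. The reliability gate's 0.8
  default is this package's choice of a working threshold; it is exposed as
  a parameter because the appropriate value depends on the RBP panel.

# Downstream statistics

**Enrichment** uses the upper-tail hypergeometric probability
$P(X \ge k)$ with the expressed genes (exp > 0) as background. Raw p-values
are flagged at $\alpha = 0.05$ by default to match the conventional
reporting of GO slim scans; a Benjamini–Hochberg option (`adjust = TRUE`)
exists because a 100-term scan at raw 0.05 carries an obvious
multiple-testing caveat.

**Mutant–WT comparison** correlates $\log_2 m$ across genes. Genes with
$m = 0$ in either sample are excluded (log of zero), which restricts the
comparison to genes modified in both samples; a `pseudocount` argument
offers the all-genes alternative, and with typical backgrounds the two
agree in rank. Old/new/lost target classification is plain set algebra and
conserves counts ($n_{old} + n_{new} = |$mutant set$|$).

# Architecture conservation

Protein coordinates are 1-based inclusive (Pfam convention). A residue is
IDR when it is outside every annotated domain and its disorder score
(supplied as input, e.g. IUPred output) strictly exceeds 0.5. Domains are
matched across orthologs by (family, rank-within-family) after sorting by
position — an alignment-free stand-in for ordering by multiple sequence
alignment, adequate because rank is what the in-order conservation test
consumes; MSA-based matching is out of scope. The ancestral composition
keeps domains present in strictly more than 30% of orthologs, ordered by
mean start position; an ortholog is conserved when its domain family
sequence contains the ancestral list as an in-order subsequence. When every
domain has been lost group-wide the ancestral list is empty and the
conserved fraction is defined as 0 — there is no architecture left to
conserve, and the vacuous alternative (1.0) would reward total loss.

IDR-segment conservation keys the inter-domain segments by position
relative to the ancestral domain order (N-terminal, between consecutive
ancestral domains, C-terminal), restricted to conserved-organization
orthologs. A segment qualifies as IDR when its across-ortholog mean
disorder exceeds 0.5 and its mean length is ≥ 15 residues; per qualifying
segment the package reports mean and standard deviation (sample, $n-1$
denominator — the convention of the numerical environments this analysis
is usually run in) of the disordered-residue counts, and averages the
std/mean ratios. The ratio is scale-invariant, so it compares IDR size
variability across proteins of very different lengths.

The ortholog-group simulator derives orthologs from a template by point
substitutions, IDR-restricted single-residue indels, and whole-domain loss
with probability $p$ per domain; disorder tracks are regenerated low
(0.05–0.35) inside domains and high (0.60–0.95) outside. For a $d$-domain
template the conserved fraction has closed form $(1-p)^d$ at rates where
every domain stays above the 30% presence cutoff; the acceptance checks
recover $p = 0.25$, $d = 2$ over 50 seeds of 20 orthologs within the
binomial 95% interval.

# Numerical choices and problem sizes

* All entry points with randomness require an explicit seed; fixed seeds
  give bit-identical outputs, and the read-level simulator consumes its
  auxiliary randomness (fragment placement, poly(A) lengths, UMIs) *after*
  the molecule stream so count- and read-level outputs stay paired.
* Zero-variance columns propagate as `NA` through correlations instead of
  being dropped silently; reliability over an all-`NA` block is an error.
* Strictness conventions: target threshold (`>`), disorder cutoff (`>`),
  ancestral presence (`>`), replicate read count (`>`), reliability gate
  (`>=`). Each mirrors the wording that defines it ("higher than", "more
  than", ...).
* Validation runs use 2000 genes / 200 targets / $10^6$ reads for the
  statistical checks, 50,000 reads for the exact round trip, and 50 × 20
  orthologs for conservation recovery — sizes at which Monte-Carlo error is
  far smaller than the tested margins while the whole suite runs in well
  under a minute.

# Known limitations

* The quantification assumes 3'-end libraries with the UMI-first read-2
  layout produced by the bundled simulator or an equivalent pre-aligned
  read table; alignment and demultiplexing are upstream concerns.
* The target threshold −2.7 is an empirical background level of one
  dead-enzyme dataset; other enzymes or protocols may need their own
  calibration (pass `threshold_log2`).
* GO enrichment takes the gene-set collection as given: no DAG propagation
  or slim mapping, so results inherit the collection's version.
* Architecture statistics use supplied domain annotations and disorder
  scores; the package neither scans HMMs nor predicts disorder, and domain
  bit-scores / per-domain sequence similarity are out of scope.
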