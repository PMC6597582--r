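---
title: "Calling signal-artifact regions from ChIP-seq input panels"
author: "blacklistr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling signal-artifact regions from ChIP-seq input panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blacklistr)
```

## The model

Artifact ("blacklist") regions are stretches of a reference assembly that
attract anomalously high or unresolvable sequencing signal in *any*
experiment, because the assembly itself misrepresents the underlying
genome. Two mechanisms dominate:

* **Copy-number misrepresentation.** A segment present in $c$ copies in the
  sequenced genome but collapsed to one copy in the reference receives
  roughly $c$-fold the background read density. Nuclear insertions of
  mitochondrial sequence (NUMTs) behave the same way with a very large
  effective $c$, since each cell carries many mitochondrial genomes.
* **Ambiguous sequence.** Duplicated or low-complexity segments cannot host
  uniquely aligned reads; their signal is carried by multimapping reads and
  their unique-mappability is zero.

Because these are properties of the assembly, they are visible in
*input* (non-immunoprecipitated control) samples from any cell type. The
pipeline therefore scores a panel of input samples and looks for bins that
are extreme *in the cross-sample consensus*, not in any single sample.

Per sample $s$ and bin $b$ (1 kb windows, consecutive starts 900 bp apart
so neighbours share 100 bp):

$$\mathrm{depth}_{b,s} = \frac{\#\{\text{read starts in } b\}}{\#\{\text{uniquely mappable positions in } b\}},
\qquad
\mathrm{multi}_{b,s} = \frac{\#\{\text{multimapping read starts in } b\}}{\text{mapped reads in } s} \times 10^6 .$$

A position is uniquely mappable at read length $k$ when its $k$-mer occurs
exactly once in the genome counting both strands — forward occurrences of
the $k$-mer plus forward occurrences of its reverse complement; a
palindromic $k$-mer with one forward occurrence is unique (one locus,
ambiguous strand). Windows containing `N` are unmappable. The computation
is exact, by hashing canonical $k$-mers (lexicographic minimum of $k$-mer
and reverse complement).

Each metric is quantile normalized across samples (rank-mean procedure)
and summarised by the per-bin **median** across samples. The median is the
load-bearing robustness choice: a locus amplified in one sample (a private
CNV) or a failed low-coverage library moves at most one order statistic
and cannot create or destroy consensus signal. Normalization is computed
genome-wide over all bins jointly, with both metrics treated independently.

Calling then proceeds per metric: bins at or above the empirical
99.9 % quantile of the *nonzero* signal seed regions; regions grow across
adjacent bins at or above the 99 % quantile **or** with zero mappable
bases, to a fixed point; regions within 20 kb on one chromosome are
unioned, gap included. Depth-track regions are labelled
`High Signal Region`; multimapping/zero-mappability regions
`Low Mappability`; a locus qualifying under both yields both records
(`collapse = TRUE` unions them). Excluded chromosomes (defaults `chrM`,
`MT`) are pre-filtered from all counting — including the per-million
denominator — and emitted whole as blacklist records.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_size` | 1000 | bases | resolution/noise trade-off at typical input coverage |
| `step` | 900 | bases | adjacent windows share 100 bp (see below) |
| `k` | 36 | bases | common short-read length for mappability |
| `flag_quantile` | 0.999 | — | seeds only the extreme tail (top 0.1 %) |
| `extend_quantile` | 0.99 | — | extension tail (top 1 %); must be ≤ `flag_quantile` |
| `join_distance` | 20000 | bases | artifact loci fragment across unmappable gaps; 20 kb bridges them |
| `exclude_chroms` | `chrM`, `MT` | — | mitochondrial contigs are blacklisted a priori |
| `multimap_mapq_max` | 0 | MAPQ | aligner-reported MAPQ 0 is the conventional multi-hit signal |

"Windows with 100 bp overlap" admits two readings: neighbours sharing
100 bp (step 900) or starts every 100 bp (step 100). We take the literal
reading, step = 900, and expose `step` as a first-class knob; results at
step 100 differ only in boundary granularity since thresholds are
quantile-based and therefore density-invariant.

## Numerical choices

* **Empirical quantiles** are type-7 (linear interpolation between order
  statistics), with flagging by `value >= threshold` so ties at the cutoff
  are all included. For $n$ distinct values this flags the top
  $\lceil n(1-q) \rceil$ bins.
* **Thresholds use the nonzero-signal distribution.** In sparse panels a
  zero-inflated distribution would place high quantiles at 0 and flag
  everything; zero bins can still join regions via the zero-mappability
  extension rule, never as seeds of the depth track.
* **Quantile-normalization ties** within a column receive the mean of the
  reference values over the tied rank range. With ties, exact idempotence
  and cross-column multiset equality hold only up to tie-averaging; both
  are exact in the tie-free case.
* **Median with an even panel** is the mean of the two central order
  statistics (interpolated type-7 quantile at 0.5).
* **Zero-mappability bins** carry `depth = 0` plus a flag rather than
  `NaN`; the flag drives the caller's "no signal due to no mappability"
  extension and seeds the `Low Mappability` track.
* **Reads are counted at their leftmost aligned position** only, in every
  window containing that position; no fragment extension or CIGAR-aware
  spans. This keeps the two metrics exactly as defined above and makes
  counting verifiable against a trivial interval-stabbing oracle.
* **Assembly gaps** need no special-casing: `N` runs have zero
  mappability and are absorbed by the extension rule.

## The synthetic generator

`synthetic_spec()` describes the study conditions;
`simulate_panel()` draws them reproducibly (master seed, one derived
substream per sample). The default spec is a 1 Mb i.i.d. uniform A/C/G/T
chromosome, 20 samples at 0.05 read starts per base (about 50 reads per
kilobase bin, a realistic deep input panel), five 5 kb collapsed repeats
at copy number 50, one 3 kb NUMT-like locus at copy number 100, and one
duplicated 4 kb segment pair. Planted loci are placed left to right with
at least `min_gap` = 30 kb between them (and from the ends) so that
distinct artifacts stay farther apart than the 20 kb join distance and
remain separable events. An optional `cnv` entry amplifies one locus in
one sample only, to exercise the median's robustness.

Reads are start positions plus a fixed length and a multimapping flag — no
sequences are simulated and no aligner runs, because the pipeline consumes
exactly those fields. Duplicated segments do place identical sequence at
two reference loci, so the *mappability* module sees genuine non-unique
sequence; their reads are drawn at background rate per copy, flagged
multimapping, and assigned to a copy uniformly at random.

What the generator deliberately does not emulate: sequencing error,
fragment-length distributions, GC bias, mappability structure of real
assemblies (satellite arrays, segmental-duplication mosaics), or
between-sample library artifacts other than Poisson noise and the optional
CNV. Passing recovery tests on this generator therefore demonstrates the
*algorithmic* behaviour of the pipeline — thresholding, extension,
joining, labelling, robustness of the median — not its calibration on any
real assembly.

## Quantile thresholds and artifact density

The flagging rule presupposes that artifact bins are a small minority:
flagging the top 0.1 % of bins can seed at most one bin in a thousand. On
a real 3 Gb assembly, where exclusion lists cover well under 1 % of the
genome, that assumption holds. On a desk-scale toy genome it easily
fails: the default synthetic spec plants 36 kb of artifact loci in 1 Mb,
about 3.6 % of all bins, so the 99.9 % quantile of the signal lands
*inside* the artifact value cluster and only the most extreme mechanism
(the copy-number-100 NUMT, at twice the collapsed repeats' depth) can
seed. The end-to-end behaviour at these conditions is characteristic and
deterministic: the NUMT is recovered as `High Signal Region`, both copies
of the duplicated pair as `Low Mappability` (seeded by zero-mappability
bins, which bypass the value threshold), no spurious calls anywhere, and
the copy-number-50 repeats remain uncalled. The recovery test suite
asserts exactly this envelope and the repeat-recovery gap is visible
there. Users simulating small genomes who want full recovery should scale
`flag_quantile` to the expected artifact fraction (here, ≤ 0.96) — on
real assemblies the defaults are the published operating point.

## Problem sizes in the test suite

Unit oracles run on genomes up to 10 kb (exhaustive substring-count
mappability checks at $k \in \{3, 10, 36\}$), quantile-normalization
invariants on matrices up to $10^4 \times 20$, merge oracles on 500-bin
grids, and the end-to-end recovery, CNV-robustness and determinism checks
on the full default 1 Mb / 20-sample spec — sizes at which every stage's
brute-force oracle is still exact and the whole suite completes in a few
minutes on one core.

## Known limitations

* Quantile thresholds are density assumptions, not effect-size tests (see
  above); there is no attempt to model the signal distribution.
* Each alignment record is independent: no paired-end awareness, no
  duplicate marking, no CIGAR-aware span.
* Unique mappability is binary; probabilistic/multi-read mappability is
  out of scope.
* The exclusion list is assay-specific by construction: it reflects input
  chromatin signal and is inappropriate for WGS (high depth is not an
  artifact there) or RNA-seq (copy-number corrections should be
  cell-type-specific). Lists are also assembly-specific; lifting a list
  between assemblies is not meaningful.
* Sample grouping is taken as given; deciding which files constitute one
  input dataset (e.g. merging by donor) is upstream data curation.
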