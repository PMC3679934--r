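---
title: "Profiling sequencing errors in pyrosequencing amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sequencing errors in pyrosequencing amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroprofile)
```

## The problem

Flow-based pyrosequencing (454/GS Junior class instruments) reads amplicons
at high coverage but with a characteristic error profile: homopolymer runs —
stretches of identical nucleotides — are called from light intensity, so
their length is the dominant source of insertion and deletion errors, while
substitutions are comparatively rare. For diagnostic amplicon assays such as
HLA exon typing, the practical questions are: how many bases are wrong, of
which kind, where along the read, how reproducible across runs, and how
trustworthy are the instrument's own quality scores?

`pyroprofile` implements that error characterization as a tested pipeline:

1. **simulate** (or load) multi-run amplicon libraries with known ground
   truth,
2. **trim** primers and **align** each read semi-globally to its reference
   amplicon, left-normalizing indels inside homopolymers,
3. **clip** alignments to exon coordinates (only exon sequence is analyzed),
4. **extract** discrepancy events and **classify** them against a truth set
   into true allelic variants, pseudogene side-products, and errors,
5. **aggregate** error rates by type, per-read statistics, cross-run
   reproducibility, positional distributions, homopolymer context and
   quality-score calibration.

## The error and quality model of the generator

The synthetic-data generator is first-class, tested code: it defines the
study conditions under which every downstream claim is verified. Per
amplicon it builds a reference
`primer_f | intron | exon | intron | revcomp(primer_r)`, one allelic
haplotype (heterozygous substitutions at `true_variant_count` exon
positions), and — for one designated locus — a pseudogene haplotype
differing at several positions, co-amplified in `pseudogene_fraction` of
that locus' reads (default 0.25, the order of magnitude reported for HLA-Y
contamination of HLA-A amplicons).

**Indels.** Every base of a homopolymer run of length $L$ is an independent
indel trial with probability $p(L) = r \cdot s^{L-1}$ (`indel_base_rate`
$r$, default $4\times10^{-4}$; `indel_length_slope` $s$, default 2.5,
capped at 0.45 per base). Trials are overcalls with probability
`overcall_fraction` (default 0.65 — pyrosequencing overcalls dominate) and
undercalls otherwise. The *net* over/undercall per run is emitted as one
length-$|k|$ event placed at the run's leftmost base. This canonical left
placement matches the extractor's left-normalization, so injected and
extracted coordinates are directly comparable without an
alignment-ambiguity resolver. Because opposite trials cancel, the expected
*observable* indel bases per run is the mean absolute net of two binomials
— the package's tests enumerate that expectation exactly rather than using
the naive $L\,p(L)$.

**Substitutions.** Substitutions hit reference-derived, non-primer bases
with a cycle-dependent probability $p_{\mathrm{sub}}(c) = \sigma\, w(c)$,
where $\sigma$ is `substitution_rate` (default $5\times10^{-4}$) and the
positional weight $w$ follows the quality profile in error-rate space,
normalized to mean 1 over the primer-free cycles, so the configured rate is
realized exactly on the analyzed part of the read. The substituted base is
uniform over the three alternatives; inserted bases are not substituted
again (a second-order effect at these rates).

**Qualities.** The true quality of a base is the phred transform of its
actual error probability: the positional substitution risk plus the
homopolymer indel risk of the run it sits in. This makes quality scores
*generative* rather than cosmetic: long homopolymers read out at lower
quality (reproducing the negative length/quality correlation), and the
calibration curve has a well-defined ideal line. On top of that,
`error_site_q_penalty` (default 5) is subtracted at injected error sites —
the "quality valley" at erroneous bases — and the result is passed through
a configurable **miscalibration** before clamping to $[0, 40]$. The default
is a step: reported $Q = Q_{\mathrm{true}} + 3$ above $Q30$,
$Q_{\mathrm{true}} - 2$ below (the instrument overestimates its good bases
and underestimates its poor ones); `identity` and constant-offset mappings
are available. The per-cycle profile is piecewise linear — rise from
`q_start` (25) to `q_plateau` (35) over the first `ramp_end` (20) cycles,
flat until `decay_onset` (300 bp), then linear decay to `q_end` (20) — a
parametric stand-in for the measured per-position quality curve, which the
source instrument documents only graphically.

**What the generator does not emulate.** No flowgram/SFF signal model, no
emulsion-PCR duplicates, no chimeras, and a fixed exon-spanning read length
per amplicon (published run reports summarize real read-length
distributions only by medians and averages). Primer bases are
emitted error-free; real primer regions are synthetic oligo sequence, and
the analysis discards them either way. Calibration analysis uses
substitution and insertion labels only — a deleted base has no read
position to label. Passing tests therefore demonstrate correctness of the
*analysis* under a realistic generative model, not instrument realism of
the generator itself.

## Alignment and event extraction

Reads are oriented and primer-trimmed (one mismatch tolerated per primer;
the 5' primer decides strand), then aligned over their full length to the
reference with free end gaps on the reference — the correct shape for a
read contained in a longer amplicon. Scoring is match +2, mismatch −3, gap
open −5, gap extend −2 (a length-$L$ gap costs $5 + 2L$); vendor amplicon
aligners document no scoring scheme, so these conventional values are
package defaults and configurable. The dynamic programming itself is
delegated to `Biostrings::pairwiseAlignment()`; the package decodes its
compact gap/mismatch accessors, left-normalizes indels within homopolymer
runs (shift while the vacated base equals the run base and the flanking
column is a match), clips to the exon interval — insertions at the boundary
survive only if anchored to an in-exon base (left-neighbor rule) — and
merges maximal runs of same-type discrepant columns into events.
Mixed-type adjacent discrepancies stay separate, preserving per-type rate
accounting.

Alignment optimality is verified against a brute-force affine-gap
enumeration on short reads. One consequence of optimal alignment is worth
stating: when two nearby gaps of opposite sign can be re-represented as a
run of substitutions, the affine gap cost makes the aligner prefer the
substitutions. Extracted events are then a different — equally or more
optimal — representation of the same read. The oracle tests treat a read as
alignment-ambiguous exactly when the aligner's score is at least the score
implied by the injected events; on unambiguous reads, extracted events
equal injected events with precision and recall 1.0, and erroneous *bases*
are conserved across representations to within a few percent.

## Classification, rates and reproducibility

Event identity is the key (amplicon, left-aligned reference position, type,
inserted/substituted bases — deletions: length). Keys found in the expected
variant table are `true_variant`, keys among the pseudogene differences of
the affected locus are `pseudogene_product` (side-products of co-amplified
homologous loci are not sequencing errors), everything else is `error`.
The partition is a total function of the key, hence idempotent and
order-independent, and the three classes always sum to the event count.

Rates follow the wrong-bases definition: each event contributes its length,
divided by the total exon bases analyzed; per-type rates sum to the total
by construction. A deletion's "erroneous bases" are the deleted reference
bases. An event's read position is the 1-based position of its first
involved read base (deletions: the left flank), translated to a sequencing
cycle via strand. Reproducible errors are keys present in every run; the
associated fraction is their base count over all erroneous bases, which is
non-increasing in the number of runs intersected. Mean errors per read are
reported both per occurrence and per distinct key — published per-read
error means are not always reconcilable with printed totals, so both
tallies are emitted and neither is asserted against a single literature
value.

Quality aggregation never averages phred values directly: scores are
translated to error rates, averaged, and translated back
(`average_quality()`), which is bounded by the min and max of its inputs
and permutation-invariant. The error-site neighborhood is the
`n_neighbors = 5` read bases nearest the event, excluding the event's own
bases, ties broken upstream — the neighborhood geometry is not uniquely
defined in the literature, so it is a documented, configurable choice, as
is "adjacent to a homopolymer" meaning within `window = 1` base of the run
boundary. Homopolymer association uses a goodness-of-fit chi-square of
error counts per length class against the reference background
distribution, pooling classes with expected counts below 5; the
length/quality correlation is Pearson's $r$ with a two-sided t-test.

## Numerical and design choices

* Coordinates are 1-based closed throughout, the R/Bioconductor
  convention; insertions are anchored at the reference base to their left
  (anchor 0 = before the first base).
* Homopolymer length classes default to $\{1,2,3,4,5,>5\}$ for context
  tables and $\{1,\dots,6,>6\}$ for quality stratification, both
  configurable.
* A deletion's site quality is the error-rate-space mean of its two
  flanking read bases — deletions have no read base of their own and no
  standard convention exists; this choice is symmetric and conservative.
* Degenerate inputs are explicit: empty quality vectors, zero total bases
  and single-run reproducibility are errors; zero-error bins in the
  calibration table yield flagged `NA` empirical qualities rather than
  infinities; zero-variance correlation inputs return `NA` with a warning.
* Generator determinism: one integer seed fixes references, haplotypes,
  and every run (run $k$ reseeds with `seed + 7919k`), so a config plus
  seed reproduces byte-identical FASTQ.
* Exon boundaries are kept out of homopolymer runs by the generator, so
  left-aligned indel coordinates never straddle the clipping boundary.

## Problem sizes used by the test suite

Unit tests run on constructed micro-examples. The study-scale checks use a
two-amplicon, two-run library of 10,000 reads (~1.3 million exon bases) for
parameter recovery and truth-oracle equivalence; calibration recovery uses
single-run libraries of 2,500 reads; the association test's size is checked
over 500 replicates of 500 class draws from the background null. The
acceptance script profiles the default six-run, six-locus library of 3,600
reads end to end. These sizes were chosen so each statistical tolerance
(three binomial standard deviations, or exact enumeration where the
binomial is inappropriate) is decisive.

## Known limitations

* The aligner reports one optimal alignment; co-optimal representations
  are normalized only within homopolymer runs, not globally.
* Calibration recovery is substitution-driven; indel miscalibration is
  visible only indirectly through the run-length quality model.
* The pseudogene model is substitution-only; real paralogs also differ by
  indels.
* The correction hook isolates an external read corrector behind a
  read-set contract; no correction algorithm is implemented here.

## A worked run

```{r, eval = FALSE}
library(pyroprofile)

cfg <- sim_config(seed = 1)
res <- run_pipeline(pipeline_config(simulation = cfg), outdir = "reports")
res$profile
tidy(res$profile)
glance(res$profile)
plot_positional_errors(res$profile$positional)
plot_calibration(res$quality$calibration)
```
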