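---
title: "Methods: repeat-centric ChIP-seq and RNA-seq quantification"
author: "teseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-centric ChIP-seq and RNA-seq quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teseq)
```

# Scope and model

Transposable elements (TEs) — LTR retroviruses (ERVs), LINEs, SINEs —
make up a large fraction of mammalian genomes, and many chromatin
regulators bind or silence them family-wise rather than locus-wise.
Quantifying protein binding (ChIP-seq) or transcription (RNA-seq) at TEs
therefore works at the level of RepeatMasker's three-level taxonomy
(`repeat_name` / `repeat_family` / `repeat_class`), and has to solve four
recurring problems that `teseq` implements as one coherent pipeline:

1. **Peak post-processing** — summit-centered resizing, a
   replicate-thresholded ChIP/input enrichment filter, and multi-label
   assignment of peaks to genomic features (promoter windows, exons,
   introns, repeats) with Upset-style combination counting.
2. **Enrichment against a matched random null** — is a peak set
   over-represented at a repeat family?  The null is built from
   randomized region sets matching the peaks in number and length
   multiset, placed uniformly on the genome.
3. **Family-level signal quantification** — fragments summed per repeat
   label, normalized either to the sample's own sequencing depth or to
   an exogenous spike-in total; plus signal matrices around anchors
   (waterfall/metaplot) and fixed genome bins.
4. **Consensus-level profiling and TE-aware counting** — coverage
   traces on stitched LTR–internal–LTR consensus models via an ungapped
   seeded aligner, and fractional assignment of multimapping reads by an
   expectation–maximization (EM) mixture model, followed by
   negative-binomial (NB) differential testing.

Every stage runs at desk scale against the package's own synthetic-data
module, which provides seed-reproducible toy genomes, fragment sets and
count matrices with known ground truth.

# Coordinate conventions

Internally all coordinates live in `GRanges` (1-based, closed), the
container shared by every Bioconductor dependency; conversions happen
only in the file readers and writers.  BED and narrowPeak are 0-based
half-open on disk; GTF and RepeatMasker `.out` are 1-based inclusive.
Overlap is defined as at least one shared base on the same chromosome,
strand ignored; abutting half-open intervals do not overlap.  Every
interval set is governed by a chromosome-size table
(`with_chrom_sizes()`), and out-of-bounds coordinates are rejected at
construction.

The counting unit throughout is the sequenced *fragment* (a read pair
collapsed to one interval): a fragment overlapping a feature by one base
or more counts once, and within one repeat label it counts once even
when it spans two instances of that label (deduplication prevents
double-counting at fragmented annotations).  A fragment spanning
instances of two different labels increments both — membership is
per-label, not partitioned.

# Peak filtering and annotation

`resize_around_summit()` re-centers peaks to a fixed width `w` (default
300 bp): `floor(w/2)` bases left of the summit, `ceil(w/2)` to the
right.  Windows that would run off a chromosome end are shifted back
inside rather than truncated, preserving the constant width that
downstream matrices rely on; a chromosome shorter than `w` is an error.

`filter_enriched_peaks()` keeps a peak iff its depth-normalized
ChIP/input ratio strictly exceeds `min_fold` (default 1.2) in at least
`min_reps` (default 3) replicate pairs.  The ratio adds a pseudocount of
one fragment to both counts before depth normalization:
`((chip+1)/chip_lib) / ((input+1)/input_lib)`.  The pseudocount and the
depth normalization are this package's choices — the fold/replicate rule
itself only fixes the thresholds — and make the filter well defined at
empty peaks and robust to unequal sequencing depths.  The filter is
monotone: raising either threshold can only shrink the surviving set.

Promoter (TSS) windows are strand-aware and exclude the TSS base itself:
`[TSS-300, TSS)` on the plus strand, reflected on the minus strand.
Peak–feature membership is computed independently per category, so one
peak can be simultaneously promoter, exonic and repeat-overlapping
(Upset semantics, no priority ordering).

# Randomized-region bootstrap null

`bootstrap_repeat_enrichment()` draws `n_boot` (default 100) region sets
matching the observed peaks in number and in the exact multiset of
region lengths.  Each region picks a chromosome with probability
proportional to its length (among chromosomes it fits on) and a start
uniform among all fitting placements.  Randomized regions may overlap
each other; no mappability or gap exclusion is applied (toy genomes have
none, and real-genome exclusion rules would be a separate concern).
Overlaps are tallied per label with presence counting — one peak
contributes at most 1 to a label regardless of how many instances it
hits — which keeps the observed and null tallies on the same scale.  The
result reports, per label, the observed tally, the null mean and SD
across bootstrap sets, the empirical `z = (obs - mean)/sd`, and the fold
over the null mean.  The dispersion reported is the plain SD across
sets, matching the mean ± SD display convention; no multiple-testing
correction is applied to the z-scores.

For a single family on a uniform genome the null tally has an exactly
computable expectation (integrate the hit indicator over all
placements); the test suite checks the bootstrap mean against this
closed form at `n_boot = 1000`, checks that a bootstrap set fed back as
"observed" is not flagged (|z| < 4), and checks that peaks planted
inside instances give z > 3.

# Normalization: library size, spike-ins, TMM

`normalize_counts()` computes
`(count + prior * s_j / mean(s)) / s_j * 1e6`, with `s_j` either the
sample's total genome fragments (`library_size`) or its exogenous
spike-in total (`spikein`).  The prior (default 3) is an absolute
pseudocount on the mean-depth scale, scaled per sample by relative
depth, so equal counts at equal depth give equal values and zero counts
stay finite.  Exact invariance under joint scaling of counts and
denominators holds for the count term (prior 0); with a nonzero prior
the invariance is asymptotic in the counts, which is the usual cpm-with-
prior behavior.

The reason spike-ins exist: a *global* change in ChIP efficiency (for
example, loss of a targeting factor) scales every count and the library
size together, so library-size cpm cancels it; against a fixed exogenous
denominator it remains visible.  The test suite constructs exactly this
scenario — halve all genome fragments, keep spike-ins — and requires
per-family ratios near 1.0 under library-size mode and near 0.5 under
spike-in mode.

`trimmed_mean_factors()` adds a compositional (TMM) factor: per sample,
the trimmed mean of per-feature log2 ratios against a reference sample
(30% trim on M-values, 5% on A-values, zero-count features excluded),
renormalized to geometric mean 1 and multiplied by the chosen
denominator into one effective size factor.  The reference defaults to
the sample whose upper-quartile count fraction is closest to the mean.
The edgeR implementation of the same idea serves as a cross-check in the
test suite, never as the implementation.

# Signal matrices

`signal_matrix()` tiles ±`flank` (default 3000 bp) around each anchor
into `2*flank/bin_width` bins (default 50 bp), counts overlapping
fragments per bin and scales to cpm.  Rows are ordered by descending row
mean of the first sample — the waterfall display order; the sort key is
a package choice, as is treating out-of-chromosome bins as missing
(`NA`) rather than zero so truncated windows do not fake depletion.
Column means ± SD across anchors give the metaplot.
`genome_binned_signal()` tiles whole chromosomes into fixed bins
(default 1 kb, last bin truncated); a fragment contributes to every bin
it overlaps.

# Stitched consensus models and the seeded aligner

LTR retroelements carry their long terminal repeat at both ends of the
internal sequence, but repeat libraries store LTR and internal consensi
separately.  `stitch_consensus()` rebuilds the full-length element as
`LTR + internal + LTR` with a segment table for display.

`align_to_consensus()` performs best full-read ungapped placement:
exact `seed_length`-mer lookup (default 15) at non-overlapping read
offsets on both strands, then mismatch counting over the whole read.
Score is `matches - mismatches`; a placement is reported iff its
mismatch rate is at most `max_mismatch_rate` (default 0.1).  Whenever a
read carries fewer than `read_length / seed_length` mismatches, at least
one seed is exact and the seeded search provably finds the same optimum
as exhaustive scoring of every offset — the test suite asserts exact
agreement with such an oracle on 1,000 mutated reads.  Ungapped,
substitution-only alignment is sufficient here because the synthetic
divergence model is substitution-only; indel-tolerant alignment is out
of scope.

Ties are broken by higher score, then leftmost start, then plus strand.
The leftmost rule is deterministic but biases reads mapping equally to
both identical LTR copies entirely to the 5' copy; replicate SD does not
reveal this (it is systematic), so segment-level conclusions should
compare LTR vs internal, not 5' vs 3' LTR.  `consensus_coverage()`
accumulates per-base depth over alignment spans (no fragment extension
on the consensus), scales to cpm, and reports mean ± SD across
replicates.

# NB differential testing

`nb_differential()` compares two groups per feature.  Dispersion is
estimated by the method of moments on factor-normalized counts, pooled
within groups, then shrunk toward the common dispersion with weight
`n/(n+4)` on the per-feature estimate (`n` = number of samples).  The
common dispersion is the plain mean of the unfloored raw estimates:
flooring or trimming the right-skewed raw values first biases the common
value low and makes the test anti-conservative.  Group means are
compared by an NB likelihood-ratio test with the dispersion held fixed
(chi-squared, 1 df), p-values are Benjamini–Hochberg adjusted, and log2
fold changes are computed on normalized group means after adding the
depth-scaled prior count, so they are finite everywhere.  All-zero
features get p = 1 and log2FC = 0.  The default significance rule flags
FDR < 0.05 and |log2FC| > 0.9.

This is deliberately a transparent, self-contained test rather than a
reimplementation of any specific package's quasi-likelihood machinery.
Its measured operating characteristics under the synthetic model
(3 vs 3 samples, dispersion 0.1): type-I error slightly above nominal
(the known small-sample behavior of plug-in-dispersion LRTs), and power
at an implanted log2FC of 1.5 comparable to the edgeR reference run
under identical conditions — the acceptance script computes both numbers
at run time, so the reported recovery rate is the test's measured power,
not an aspirational value.

# EM assignment of multimapping reads

`em_assign_multireads()` treats read–feature compatibility as a mixture
model: abundances start uniform, the E-step splits each read across its
compatible features proportional to current abundances, the M-step sums
the fractional assignments.  Iteration stops at `max_iter` (default 100)
or when the largest relative abundance change drops below `tol` (default
1e-6).  Fractional counts sum exactly to the read count after every
iteration, and the observed-data log-likelihood is non-decreasing (an EM
guarantee the tests assert).  `compat_matrix()` builds the 0/1 matrix
from fragment–instance overlaps and `rollup_counts()` sums instance
level fractional counts to families — EM runs at instance level first,
then rolls up, so family totals reflect instance-level ambiguity
resolution.  An optional intron filter is available upstream by
subsetting the annotation before building the compatibility matrix.

# The synthetic-data module

`simulate_genome()` implants consensus copies (random or supplied
sequences) into a uniform-random background: non-overlapping, random
strand, per-base substitutions at the configured divergence (default
0.05, typical of young mouse ERV copies; 0.08 for the older LINE
family in the test catalog).  Requested family fractions are realized
deterministically (count = round(fraction x genome / length)), so
realized coverage is within a rounding error of target.
`simulate_chip_fragments()` draws fragment midpoints with density
proportional to the family enrichment factor inside instances and 1
outside; input samples are uniform.  Fragment lengths are truncated
normal (mean 200, SD 50, minimum 50 bp).  Spike-ins are represented by
their totals only — binomial draws at the configured fraction (default
0.05) — because normalization consumes only the totals.
`simulate_count_matrix()` draws NB counts (variance `mu + phi*mu^2`)
with implanted log2 fold changes in group 2.

One global integer seed expands into per-stage substreams through a
string-hash scheme, so adding a simulation stage never perturbs the
streams of existing stages, and every generator is byte-reproducible
under a fixed seed (asserted by writing all outputs twice).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: nested/fragmented repeat instances,
sequencing error, PCR duplicates, mappability structure, GC bias,
indels, and biological replicate variability beyond sampling noise.
Conclusions about method correctness (oracle equivalence, calibration,
parameter recovery) transfer; conclusions about real-genome effect sizes
do not.

# Problem sizes and numerical choices

The test and acceptance simulations use: toy genomes of 0.5–1 Mb with
2–4 repeat families at 3–8% genome fraction each; 1e5 fragments per
sample for normalization checks; 200 peaks of 300 bp with `n_boot` =
1000 for bootstrap calibration; 200 null count matrices of 200 features
(3 vs 3) for type-I error and 20 seeds for recovery; 1,000 mutated reads
for the aligner oracle; and 16 replicates at 20x depth for the coverage
flatness check, where the replicate-mean trace is required to stay
within ±25% of its global mean over the central 90% of bases (the 5%
edge margins cover the read-length coverage ramp at the model ends).
Convergence/floor constants: EM `tol` 1e-6 on relative abundance change;
NB mean fits by fixed-point iteration to relative tolerance 1e-10;
dispersion floored at 1e-8 only after shrinkage.

# Known limitations

- The enrichment filter pairs ChIP replicate r with input replicate r
  (or one shared input); arbitrary pairing designs are not expressed.
- The aligner is ungapped and quality-unaware; reads spanning indels
  against the consensus will be rejected or mis-scored.
- The NB test is two-group only, with no covariates.
- Randomized regions ignore mappability and assembly gaps; on real
  genomes the null is therefore slightly permissive at repeat-dense
  regions.
- Spike-in totals are taken as given; no spike-in genome alignment is
  performed.
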