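---
title: "Discovering an inverted duplication: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering an inverted duplication: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermadup)
```

## The problem

Fibromelanosis (FM) is a dominant dermal-hyperpigmentation trait of the
chicken, caused by a complex structural variant on chromosome 20: two genomic
regions of roughly 129 kb and 172 kb, separated by 417 kb of single-copy
sequence, are each duplicated and the copies joined to one another in
inverted orientation. The first duplicated region contains *EDN3*
(endothelin 3), whose overexpression drives the melanocyte phenotype.
Dissecting a variant like this from genotyping-array and short-read data
requires several cooperating analyses, each individually standard but with
locus-specific wrinkles:

* copy-number scanning of SNP-array Log R ratios (LRR), per individual via
  circular binary segmentation (CBS) and, more sharply, by a group-wise
  carrier-minus-control contrast;
* recognition of paralogous sequence variants (PSVs): fixed differences
  between collapsed duplicate copies that an array reads as constitutive
  heterozygosity in every carrier;
* discordant mate-pair analysis of pooled sequencing libraries (windowed
  depth, depth-normalized fold change, insert-size and strand anomalies);
* combinatorial reasoning over locus architectures constrained by
  junction-PCR evidence, with recombinant offspring used to eliminate
  candidates;
* qPCR quantification of genomic copy number and expression by the
  delta-delta-Ct method.

`dermadup` implements this pipeline end to end. Because the original raw
data are not publicly deposited, the package is exercised entirely on
synthetic data whose generators are first-class, tested code: every
simulation writes a truth record, and every analysis stage is scored against
it.

## The synthetic locus

`build_reference()` simulates the 1,717,001 bp locus
(chr20:10,218,000-11,935,000 in the coordinate frame of the galGal3
assembly) as a uniform random sequence tiled by five blocks: left flank `L`,
first duplication `D1` (10,717,294-10,846,232), single-copy spacer `S`,
second duplication `D2` (11,262,904-11,435,256) and right flank `R`. Using
the published breakpoints as the planted truth makes the printed interval
arithmetic (483 kb, 75 kb, 417 kb) directly testable against the package's
own coordinate helpers.

A handful of bases around the future junction points are adjusted at
construction so that the mutant allele carries an exactly known
microhomology at each junction: none at the junction of the two 5' ends and
a single shared `C` at the junction of the two 3' ends, the configuration
observed in the sequenced junction fragments. The adjustment also forces a
mismatch immediately beyond each planted overlap, so the microhomology is
exact rather than merely a lower bound; recovery of these lengths is what
the junction-refinement tests assert.

`build_fm_allele()` linearizes one of the candidate architectures:

* `N` — `L +D1 +S +D2 R` (wild type);
* `FM_1` — `L +D1 -D2 -S -D1 +D2 R` (spacer inverted between junctions);
* `FM_2` — `L +D1 -D2 +D1 +S +D2 R` (inverted `D2` between two direct `D1`
  copies);
* `FM_3` — `L +D1 +S +D2 -D1 +D2 R` (intact wild-type run, inverted-joined
  copies appended).

All three mutant architectures contain the same six adjacencies — the four
wild-type boundary adjacencies plus the 5'-5' and 3'-3' junctions — and are
therefore indistinguishable by boundary PCR alone, which is exactly the
ambiguity the recombinant-elimination logic resolves.

## The array model

`simulate_array_cohort()` places markers every 6 kb (the density of a 60K
genome-wide chip on this genome) and draws per-marker, per-individual LRR
noise with SD 0.15. Carriers of a duplicated block receive an additive mean
shift at in-block markers: +0.30 for four copies, +0.15 for three. This is
deliberately flatter than the ideal `log2(CN/2)` (+1.0 and +0.58): real
array intensities are strongly compressed, and per-carrier segment means of
roughly +0.12 to +0.27 are what motivated the group-wise contrast in the
first place. Under the additive-noise model the group-wise delta at an
in-duplication marker is Gaussian with mean 0.30 and SD
`0.15 * sqrt(2/12) = 0.061`, so the ±0.1 calling threshold sits more than
three SDs below the carrier mean and 1.6 SDs above the null — informative
but not trivially clean, which is the regime the boundary-accuracy numbers
are meant to probe.

PSV heterozygosity is modeled at the genotype-call level: every carrier is
called `AB` at the five planted PSV markers (two fixed for the reference
allele in wild types, three segregating). Raw intensity clusters are not
simulated. Homozygous carriers additionally share one founder genotype
vector across a planted identity interval whose offsets inside `D1` mirror
the 75 kb shared haplotype; founder genotypes there are homozygous at
non-PSV markers so that no spurious fixed heterozygosity arises. Twelve
carriers is also the smallest group size for which chance all-heterozygous
markers (probability about `0.5^n` per marker) are negligible across ~290
markers.

### Segmentation and region calling

`cbs_segment()` implements CBS with the parameters quoted for the original
segmentation run (10,000 permutations, alpha 0.01, RNG seed 12,345,678): the
statistic is the absolute standardized difference between a circular arc's
mean and its complement's mean, maximized over arcs, with the segment-wide
variance dropped because it is permutation-invariant; the permutation test
terminates early once the exceedance count can no longer reach significance,
which changes no decisions. Accepted arcs must hold at least
`min_markers_per_segment` markers on both sides, though small edge remnants
can remain. On instances small enough for exhaustive least-squares
changepoint search the two methods agree exactly (a property the test suite
enforces), and the O(n^2) kernel is compiled code, as segmentation
implementations in this field usually are.

`call_elevated_regions()` implements the sharper group-wise rule: maximal
runs of at least 5 consecutive markers with delta strictly above 0.1 (a
delta exactly at the threshold counts as below), with qualifying runs merged
when separated by fewer than 5 below-threshold markers. Each boundary is
reported as the midpoint between the outermost in-run marker and its nearest
out-of-run neighbour. The midpoint rule halves the worst-case error of
quoting the outermost marker itself (3 kb versus 6 kb at this spacing) and
is recorded in the output's `method` tag so either convention can be tested.
When every flank marker is correctly classified, the boundary error is
bounded by half the marker spacing; a single mis-classified flank marker
(probability about 5% per flank at these settings) extends a run by one
marker and can push that boundary's error to ~1.5 spacings. That failure
mode is intrinsic to the published settings, not a tuning artifact, and the
boundary-accuracy acceptance check inherits it.

## The pooled-sequencing model

`simulate_matepair_pool()` draws mate pairs uniformly along a template (the
wild-type reference or a mutant allele) with Normal(2,500, 300) inserts and
50 bp reads at 30x per-copy depth, and emits mapped reference coordinates
directly — no base-level reads, no alignment. Mapping ambiguity is out of
scope; the one alignment effect retained is that a read crossing a template
junction has no contiguous reference image and is dropped. A pair whose
reads land in differently oriented or distant template pieces shows exactly
the aberrant implied distance and/or strand pattern the scan looks for.
The era-appropriate mate-pair read length is not part of the published
description; 50 bp is the package default and is configurable.

Depth is counted in 1 kb windows by leftmost read base and normalized per
million mapped reads of the library. The library total is the genome-wide
count implied by the target depth (default genome size 1.05 Gb), not the
in-locus count: the two pools differ in locus length by the 301 kb of extra
sequence in the mutant allele, and normalizing by in-locus totals would
deflate the case pool by that ratio (2 × 1.717/2.018 ≈ 1.70 instead of 2.0
in the duplications). Against a whole genome the locus is a rounding error,
so equal library totals are the realistic regime. When a pair set has no
library total attached — for instance after reading a bare BEDPE file —
`window_depth()` falls back to the in-locus total, in which case normalized
depths sum to one million by construction. The log2 fold change adds a
half-read pseudocount to each window count before normalizing; at ~600
reads per window this is negligible, while still guarding empty windows, and
it preserves exact antisymmetry under swapping the pools.

The candidate-SV rule is applied per window, assigning each pair once to the
window of its leftmost read: if at least 20% of a window's pairs have
mapping distances more than 6 SDs above the library mean (mean and SD taken
over all pairs of the library), the supporting subset is those within
±1,500 bp of the discordant pairs' median distance; the partner window is
placed at their median far-read position, and the inversion flag is raised
on a strict majority of strand-discordant pairs (ties do not flag).
"Mapping distance" is the absolute difference of the two leftmost
coordinates — the published description does not define it, and this is the
simplest convention consistent with it. Windows with fewer than 10 pairs are
skipped to keep the 20% fraction meaningful; that floor is a package
addition. Whether the fraction should count pairs starting in the window or
overlapping it is likewise unstated; the leftmost-read convention is
declared here and in the function documentation.

For reporting, depth-gain regions are called as at least 20 consecutive
windows with log2 fold change at or above 0.8: the published figure shows a
2-fold guide line but no explicit call rule, so the package declares one
with headroom for sampling noise at 30x.

### Junction refinement

`refine_junction()` anchors each end of a junction-spanning fragment on the
reference (either strand, exact `anchor_len`-mer match, default 30),
extends both anchors to maximal exact matches, and reads the junction off
the overlap structure: overlapping matched stretches are microhomology,
a gap between them is inserted sequence. The result is exact and
deterministic, and on random fragments it agrees with a brute-force
maximal-substring search (enforced as a 200-case property test). For the
default allele it reports the planted single-base `C` homology at the 3'
junction and none at the 5' junction, with breakpoints at the planted
coordinates on both sides.

## Rearrangement logic

Architectures are signed block sequences between fixed flanks. The
arrangement space is restricted to copies `{D1: 2, S: 1, D2: 2}`, the copy
state established independently by qPCR and read depth; the published
account depicts but never formalizes this space. `enumerate_arrangements()`
performs exhaustive path enumeration from `L` to `R`, consuming the
adjacency evidence multiset exactly once per adjacency and de-duplicating
under whole-locus reverse complement. Under the six observed adjacencies
exactly three architectures survive — the package's `FM_1`/`FM_2`/`FM_3` —
and dropping either novel junction from the evidence leaves none.

The published drawings of the alternative architectures cannot be recovered
from text, so the package identifies them by their defining properties
rather than by picture: `FM_1` is the unique enumerated architecture whose
spacer is inverted, making a spacer crossover with a wild-type chromosome
inversion-heterozygous (dicentric/acentric loss); `FM_3` is the one whose
wild-type-left recombinant retains both duplications. `crossover_products()`
models a single exchange inside a shared block and conserves total copy
number over the two products whenever the exchange is viable.
`consistent_scenarios()` then encodes the decisive observation — a viable
recombinant with wild-type-left/mutant-right provenance, wild-type phenotype
and normal copy number — under the dominance rule "affected iff the
chromosome carries either novel junction". Only `FM_2` survives; relaxing
the phenotype requirement to mere viability leaves `FM_2` and `FM_3`,
which is the correct weaker conclusion.

In-silico PCR places primers by coordinate on the linearized arrangement
(sequence-level annealing and junction microhomology, at most a single base,
are ignored for product sizing). The bundled synthetic diagnostic set uses
offsets chosen so the four products have the package's reference sizes —
379/280 bp for the 5' assay and 302/159 bp for the 3' assay — and
reproduces the two key qualitative facts: no product for a tandem-duplication
primer pair, and identical band patterns for carriers and homozygotes
because all four wild-type boundaries are retained in the mutant allele.

## qPCR quantification

`simulate_qpcr_ct()` uses the textbook log-linear model
`Ct = intercept - slope_factor * log2(template)`; at 100% efficiency one
template doubling costs one cycle. Copy-number estimation follows the
two-step delta-delta-Ct scheme with a diploid calibrator:
`CN = 2 * 2^-((dCt_sample) - (dCt_calibrator))`, with replicate-wise
recomputation supplying the min/max range. Noiseless recovery is exact:
3.0 for a heterozygote, 4.0 for a duplication homozygote.

Standard-curve QC accepts slopes in [-3.7762, -3.1035] with correlation
above 0.995 and, for simplex/duplex pairs, y-intercepts within 1 cycle.
Efficiency is reported as percent of perfect doubling,
`100 * 10^(-1/slope) / 2`, the convention under which the accepted window
maps to 92-105%; the textbook exponential-phase form
`(10^(-1/slope) - 1) * 100` (84-110% over the same window) is carried as a
secondary field rather than silently substituted.

Relative expression normalizes each sample to a reference gene and each
group to the control group. The confidence interval is a normal-theory
Welch interval on the mean delta-delta-Ct back-transformed through `2^-x`;
the original analysis used proprietary software whose interval construction
is unspecified, so no equivalence is claimed beyond the point estimate.
Two groups are compared by unpaired t-test, more than two by one-way ANOVA,
at the conventional 0.05 level. In the degenerate noiseless case the
t-statistic is undefined and the package reports p = 1 for identical means
and p = 0 otherwise. Undetected targets (missing Ct) are flagged, never
imputed — mirroring genes whose expression is absent from wild-type muscle.

## Orchestration, formats and determinism

`run_fm_pipeline()` chains every stage under one master seed, derives
per-stage seeds from it, scores all results against the truth record, and
reports everything (parameters included) as one JSON-serializable object;
regenerating with the same configuration reproduces the report byte-for-byte
apart from the timestamp. Reported coordinates are 1-based inclusive; the
BED family on disk is 0-based half-open, and the conversion lives in exactly
one layer (`write_bed`/`read_bed` and friends), verified by round-trip
tests. Interval length is `end - start + 1`, a gap is
`next.start - prev.end - 1`, and kilobase figures are rounded to the nearest
integer — the conventions that make the printed 483/75/417 kb figures exact.
A thin Rscript front end (`inst/cli/dermadup.R`) exposes the subcommands
`simulate`, `scan-array`, `scan-pools`, `enumerate`, `qpcr`, `run-all` and
`convert` over these functions, logging to stderr and keeping machine output
separate.

Every generator takes an explicit seed and restores the caller's RNG state;
nothing in the package touches global random state as a side effect.

## Problem sizes and what the tests do and don't show

The default study conditions are the published ones: ~287 markers at 6 kb
spacing, 12 carriers vs 12 wild types, two pools at 30x with 2.5 kb inserts
(~515,000 and ~605,000 pairs). A full pipeline run at these sizes takes a
few seconds; the orchestration unit test scales sequencing depth down to 6x,
which changes nothing structural. The per-individual CBS path is the
slowest component (a few seconds per individual at 10,000 permutations) and
is exercised on one carrier plus small oracle instances.

Passing on this synthetic cohort demonstrates that the algorithms recover
what was planted under the stated noise model — it does not certify
performance on real arrays or real mate-pair libraries. In particular the
generators omit GC waves and spatial artifacts in LRR, B-allele-frequency
information, genotype-calling error (available as an option but off by
default), sequencing error, mappability structure and chimeric pairs.
Support counts for junction features depend on unmodeled mappability and are
treated as qualitative throughout. Quantities from the original study that
depend on its unpublished raw data — per-bird segment tables, the ~400-pair
junction support counts, breed panels, embryonic expression panels — are
covered only by structural analogues, not by numeric reproduction.
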