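---
title: "Methods: detecting and phasing delins from noisy long reads"
author: "delinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and phasing delins from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delinscan)
```

## The problem

A *delins* (complex indel) deletes a reference segment and inserts a different,
roughly equal-length segment at the same locus. On PacBio continuous long reads
(CLR), whose sequencing error rate reaches ~15% and is dominated by spurious
insertions and deletions, a delins is easy to confuse with the error background:
hard per-site filters fail because nearly every column of a CLR alignment
contains some disagreement. `delinscan` addresses this with a *variation
density* approach: evidence is aggregated over a window so that the error
background (a flat ~15% disagreement floor) separates cleanly from variant
regions (where half or more of the covering reads disagree systematically).

## The variation score

For every reference site the pileup records `d`, the number of reads whose
aligned span covers the site, and `u`, the number of those reads carrying an
unmatched base there. The per-site unmatched proportion is `p = u/d` (defined
as 0 at zero depth: absent reads are not evidence of variation). "Unmatched"
aggregates all CIGAR evidence without double counting: an aligned base that
differs from the reference, a site spanned by a deletion op, the site
immediately before an insertion op, and the single aligned site adjacent to a
soft clip. Clipped bases themselves are not aligned to any site and contribute
nothing.

The score at a center site $c$ is a Gaussian-weighted average over the window
$[c - w, c + w]$ (`windows_len` $= w$):

$$\mathrm{Score}_c = \sum_{k=c-w}^{c+w} w_{ck}\, p_{ck}, \qquad
w_{ck} \propto \tfrac{3}{w}\, \varphi\!\left(\tfrac{3(k-c)}{w}\right),$$

with $\varphi$ the standard normal density, i.e. the kernel truncated at three
standard deviations. The raw coefficients sum to the Riemann approximation of
the normal mass on $[-3,3]$ (~0.9974); we renormalize them to sum to exactly 1
so that an all-matched window scores exactly 0 and an all-unmatched window
exactly 1. A flag (`weight_vector(..., renormalize = FALSE)`) restores the raw
coefficients. The score track is then smoothed by a centered moving average
with half-window `smooth_win` and divisor $2\,\mathrm{win}+1$ (truncated
windows at contig edges use the actual site count), and maximal runs of
smoothed score strictly above a threshold $T$ become candidate regions; runs
separated by fewer than `merge_gap` sites are merged. Sites scoring exactly
$T$ break runs (strict inequality).

**Defaults and why.** `windows_len = 50` sites: much smaller than the 500 bp
minimum delins length, so a delins presents as a plateau, yet wide enough to
average out binomial noise at 25x depth (window-mean standard deviation
$\approx 0.01$). `T = 0.35`: the error floor scores $\approx 0.15$ and a
heterozygous delins $\approx 0.4$-$0.5$, so 0.35 sits between them with
several smoothed standard deviations of margin on both sides.
`smooth_win = windows_len` and `merge_gap = 2 * windows_len`. All are exposed
in `pipeline_config()`.

## Classifying candidate regions

Candidate regions are typed as deletion, insertion, delins, or noise with a
one-vs-one SVM ensemble: one radial-basis binary SVM per unordered class pair
($m(m-1)/2 = 6$ models for $m = 4$), majority vote, ties broken by summed
decision-function margin and then by fixed class order. Features are computed
from the CIGAR ops of reads overlapping the region, restricted to in-region
columns: insertion rate, deletion rate, mismatch (substitution) rate, and the
longest run of unmatched sites divided by region length. Deletions show a
continuous deleted block (high del rate, continuity ~1); insertions a large
`I` op; delins both indel evidence and an elevated mismatch rate (aligners
force the inserted fragment against the deleted span, producing a ~75%
mismatch mosaic whose unmatched-site continuity is poor). Region length and
mean depth are reported in the feature record but deliberately excluded from
the SVM input: they are nuisance parameters with respect to the class, and a
model trained at one coverage must generalize to others.

Features are standardized with training-set means/SDs stored inside the
ensemble. Training data come from the simulator with truth labels (regions at
truth SV intervals, plus random background intervals for the noise class);
`ds_train()` regenerates the corpus from a seeded configuration.

## Breakpoints from soft clips

Within each region (padded by `windows_len`), reads soft-clipped on the right
with clip length strictly greater than 50 bp vote for the start breakpoint
(anchor = last aligned base, candidate = anchor + 1, the first deleted base);
left clips vote for the end (anchor − 1). Each candidate set is cleaned with
Tukey fences (values outside $[Q_1 - 1.5\,\mathrm{IQR},\, Q_3 +
1.5\,\mathrm{IQR}]$ removed, quartiles by linear interpolation; at least the
inter-quartile mass always survives) and the arithmetic mean, rounded half-up,
is the estimate. With no usable clips the density-scan region bound is used,
flagged low-confidence. For pure insertions the deleted span is empty and the
call is encoded `end = start - 1`.

## Tracing the origin of inserted sequence

Clipped sequences become artificial reads (optionally written as FASTQ) and
are mapped back to the reference by the built-in exact-anchor aligner: all
maximal exact runs $\ge k$ ($k = 13$) are found via a 2-bit k-mer index and
merged along diagonals; runs within a diagonal band of 30 are chained, and a
chain is a placement when its matched length reaches `min_anchor` (50 bp). Per
iteration the best chain is placed and masked and the remaining flanks are
re-queued, up to `max_iterations = 3` (the clip of a delins-crossing read is
insert *plus* reference flank, so the flank typically places first and the
insert on the second round). The reported source is the placement reaching the
clip-proximal end, projected along its chain diagonal to the segment start;
per-read estimates are combined by median. Chaining exact runs is essential at
15% error: single exact runs of 50 bp essentially never survive (mean exact
run length $\approx 1/0.15 \approx 7$ bp), so a literal "longest continuous
exact match of 50 bp" criterion could never place a source at the error rate
this tool targets.

## Phasing

SNVs (supplied as a VCF or data frame; this package does not call SNVs) are
merged with the SV calls, and every read is scored at every variant it spans
informatively: SNVs by the aligned base (alt allele → 1, reference base → 0,
anything else missing); deletions/delins as alternate when the read clips at a
breakpoint, gaps across at least half the span, or force-aligns through it
with a mismatch-dense span (≥ 40% mismatching columns — this last rule covers
the force-aligned representation noisy-read mappers produce); insertions by a
long anchored `I` op. Alternate-allele frequencies below `het_min = 0.2` or
above `1 - het_min` mark a variant homozygous/noise and exclude it from
phasing.

Read-backed splicing greedily joins consecutive phasable variants co-observed
on at least `min_shared = 2` reads with a strict co-allele majority;
conflicting reads are outvoted. Junctions that cannot be joined are then
re-examined by linkage disequilibrium: for the anterior block $A$ and posterior
block $B$,

$$L = \sum_{i=1}^{m} \sum_{j=1}^{n} lq(i,j)\, p_j,$$

where $lq = p(AB) - p(A)\,p(B)$ is the signed linkage strength computed from
reads informative at both sites (0 when none exist), signed by the candidate
orientation, and $p_j$ is the posterior variant's alternate frequency. Both
orientations (same/flipped) are scored; the junction is spliced with the
better one when $\max L \ge$ `min_L` (default 0), marked `ld_spliced`, and the
scan repeats until no junction changes. Variant pairs farther apart than a
read span have no co-informative reads and contribute exactly 0, so the double
sum is restricted to the junction neighbourhood (`max_pair_dist = 30` kb)
without changing the result. A flip relabels the posterior block's haplotypes
globally; within-block assignments from read-backed splicing are never
altered.

## Evaluation metrics

Detection uses greedy nearest-first one-to-one matching: a call matches an
unmatched truth record when the types agree and both breakpoints are within
`match_tolerance` (100 bases — small against the 500 bp minimum delins
length); precision, recall and f-measure follow. Phasing accuracy compares
each block to truth under the better global flip: disagreement runs of length
1 are mismatch errors; longer runs contribute one switch error per run
boundary interior to the block (a flip persisting to the block end is one
switch). Possible switch positions are $\sum_b (n_b - 1)$ over blocks with at
least two variants; possible mismatch positions are all phased variants. N50
is measured on block reference spans: the span at which the cumulative sorted
span first reaches half the total.

## The simulator and what it does (not) emulate

The simulator generates an i.i.d. uniform A/C/G/T reference (a user FASTA can
be substituted), plants non-overlapping heterozygous SVs (deleted span drawn
from `delins_len_range`; inserted fragment copied from a random reference
locus at 0.9-1.1x the deleted length, its source recorded) at least
`min_sv_gap = 5` kb apart, plus SNVs at `snv_rate` assigned to haplotype 0, 1
or both, and draws reads of length N(15000, 1500) (truncated at 200 bases)
uniformly from both haplotypes until `depth x ref_length` bases, injecting
errors per base at `error_rate` with mix (0.45 insertion, 0.40 deletion,
0.15 substitution) — the CLR regime where spurious indels dominate.

Truth-derived alignments replace an external mapper. Reads crossing a delins
are represented as real noisy-read mappers represent them, as a mixture: 25%
clip at the nearer breakpoint (soft-clip evidence), 50% carry an explicit
`I`+`D` at the locus, 25% force-align the insert against the deleted span as a
mismatch-dense `M` run. Below 1% error the forced class folds into `I`+`D` — a
mapper of clean reads has no reason to accept a ~75%-mismatch segment — which
also keeps the zero-noise guarantee that every `M` run matches the reference
outside planted SNV sites. Pure insertions are emitted as one long `I` (75%)
or a clip (25%); pure deletions always as `D`. Partial inserted fragments at
read ends are always clipped.

What passing tests on this simulator do *not* show: real references have
repeats and low-complexity tracts (insert-source tracing and anchor alignment
are harder there); real aligner behavior at delins varies by mapper and
parameters rather than following a fixed mixture; base qualities are constant;
there are no chimeric reads; error rates are position-independent. The
density-scan defaults were *not* tuned to the simulator's quirks — they follow
the error-floor/plateau separation argument above — but absolute f-measures
on real data will differ.

## Numerical choices and degenerate inputs

- Scores are computed by direct convolution (`stats::filter`), not FFT, so the
  all-zero and all-one limits are exact; values are clamped to $[0,1]$ against
  rounding residue.
- Zero-depth sites score 0; empty candidate-region lists, empty call sets and
  empty variant sets propagate as empty (but valid) outputs end to end.
- The breakpoint mean is rounded half-up; Tukey filtering never empties its
  input; single-element candidate sets pass through unchanged.
- Ties at exactly `T` break score runs; ties in the SVM vote fall back to
  margin sum, then fixed class order, so classification is deterministic.
- Every stage derives its RNG stream from one seed (`derive_seed`), and
  library code restores the caller's `.Random.seed`.

## Design choices where the design was open

- **Zero-noise validation depth 60x.** Only ~25% of crossing reads clip at a
  noiseless delins (the rest align through), and clips split between the two
  breakpoint sides, so 60x yields ~3-4 exact anchors per side — enough for the
  exactness property to be well-posed (Poisson argument).
- **Training corpus.** Balanced truth-labeled regions from seeded simulations,
  ~24-40 per class; with the rate-only feature set this is ample for the
  strongly separated classes.
- **`lq` estimator.** Normalized covariance $D$ rather than $r^2$: secondary
  splicing needs the sign to choose an orientation, and $r^2$ is
  orientation-blind. `p` is the posterior variant's frequency, estimated from
  reads rather than a population panel.
- **Problem sizes in the validation suite.** The packaged checks run the full
  pipeline on 1 Mbp genomes with 20 delins, ten seeded replicates — a
  full-scale 10 Mbp / 100-delins study shrunk tenfold at equal variant
  density, which keeps the whole suite desk-scale while leaving every
  per-variant quantity (depth, read length, error rate, delins length) at its
  full-scale value.

## Known limitations

- Pure insertions are nearly invisible to the density scan (a single anchored
  site), so insertion recall from scanning is poor; the class exists mainly so
  the classifier can separate it from delins at classification time.
- Homozygous SVs are excluded from phasing by the heterozygosity gate; the
  package does not genotype beyond that gate.
- One contig per run; multi-sample pileups, base-quality weighting, inversion
  and translocation classes are out of scope.
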