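---
title: "Detecting copy-number alterations from depth of coverage: model and methods"
author: "depthCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number alterations from depth of coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthCNA)
```

## The problem

When a genome is sequenced with short reads, the number of reads starting
inside a fixed-size window ("bin") is, to first order, proportional to the
copy number of that window. Counting reads in bins tiled along the genome
therefore exposes copy-number alterations (CNAs) — deletions and
amplifications — without requiring a matched normal sample. Two obstacles
make the naive approach unreliable:

1. **Overdispersion.** Under uniform sampling, bin counts would be Poisson.
   Real Illumina libraries show variance well above the mean even after
   correcting known biases, so Poisson-based thresholds call far too many
   false CNAs.
2. **Systematic bias.** Repetitive regions absorb fewer uniquely mapping
   reads (mapability bias), and library preparation favors certain GC
   compositions (GC bias). Bisulfite-treated libraries add a twist: the
   observed base composition depends on the methylation state of each
   cytosine.

`depthCNA` addresses both: an overdispersed count model drives the choice
of bin size and calling thresholds at a controlled false-discovery rate,
corrections remove mapability and (effective) GC bias, circular binary
segmentation delineates regions of constant copy number, and externally
supplied paired-end breakpoints can sharpen segment boundaries below the
bin resolution.

## The count model

Given $n$ uniquely mapping reads on a genome of $g$ bases and a bin size
$b$, the expected reads per diploid bin is $\lambda = n b / g$. Bin counts
are modeled as negative binomial with mean $\mu$ and size
$r = \mu/(d - 1)$, where $d$ is the variance/mean ratio (VMR), so that
$\mathrm{Var} = d\,\mu$. At $d = 1$ the model degenerates to Poisson; the
default $d = 3$ matches the overdispersion typical of Illumina
whole-genome libraries. VMR is a user parameter, not estimated from data.

Copy-number classes 1, 2 and 3 have means $\lambda/2$, $\lambda$ and
$3\lambda/2$, sharing the VMR. A bin with count below an integer threshold
$t_\text{loss}$ is called a loss, above $t_\text{gain}$ a gain, otherwise
neutral (boundary counts are neutral). `optimize_thresholds()` picks the
cuts minimizing the total misclassification mass of the three class
distributions; the achieved FDR is that summed misclassification
probability (expected misclassified bins per bin drawn from each class).
Because all three classes share the negative binomial probability
parameter, their likelihood ratios are monotone in the count; each cut's
misclassification mass is therefore unimodal and is located by bisection
on the sign of the pmf difference, with a local exact scan to resolve
ties. Ties between equally good threshold pairs are broken toward the
pair whose midpoint is closest to $\lambda$, then toward smaller
thresholds — a deterministic rule.

We compute the masses from exact pmfs rather than by sampling: the result
agrees with large-sample simulation to Monte-Carlo error (the test suite
checks this with $10^5$ draws per class via `sample_class_counts()`) and
removes the sampling noise from what is otherwise a deterministic
quantity.

**Bin-size selection.** Larger bins raise $\lambda$ and separate the class
distributions, so the achieved FDR is non-increasing in bin size.
`select_bin_size()` exploits this monotonicity to bisect the grid of bin
sizes (multiples of 100 bp up to 10 Mbp) for the smallest bin meeting the
FDR target; the tests verify bisection against a full linear scan. The
worked example:

```{r}
g <- 47e6 * 55 / 0.85   # genome size implied by 0.85x coverage of 55 bp reads
select_bin_size(n_reads = 47e6, genome_size = g, vmr = 3, fdr_target = 0.01)
```

With 47 million reads at 0.85-fold coverage the model selects a 26.0 kbp
bin at FDR 0.01 ($\lambda \approx 402$).

## Corrections

Corrections are applied in a fixed order: mapability first, then GC
(the GC groups are formed from depths that already incorporate mapability
information). Swapping the order is not supported.

**Mapability** (`mapability_correct()`): each bin's count is multiplied by
the inverse of its mapable fraction. Bins under 25% mapability are masked
rather than corrected — a 4-fold-plus extrapolation does more harm than
good. The correction never decreases a count and is the identity at
mapability 1.

**GC bias** (`gc_correct()`): unmasked bins are grouped by GC fraction in
0.1% increments (configurable; finer grids gain little at typical bin
counts), group mean depths are smoothed by locally weighted regression
(degree 2, span 0.3, weighted by group occupancy), and each bin receives
the additive correction $\mathrm{median}(\text{depth}) - \hat f(\text{gc})$.
Corrected depths are floored at zero and rescaled multiplicatively so the
total unmasked depth is exactly conserved (to $10^{-9}$ relative, asserted
in the tests). With fewer than 10 occupied GC groups or 200 unmasked bins
the fit is unreliable and the identity correction is applied with a
warning.

**Bisulfite libraries** (`effective_gc()`): bisulfite treatment converts
unmethylated cytosines to uracil (sequenced as thymine) while methylated
cytosines are protected. The base composition the sequencer observes — and
hence the GC bias actually experienced by a fragment — therefore depends
on methylation. Given a per-cytosine methylation map (how often
methylation was observed at each reference cytosine), each cytosine
contributes its methylation fraction to the bin's G+C tally; guanines,
unaffected on the read strand, count fully; cytosines absent from the map
contribute the genome-wide mean fraction. A fully methylated genome
reproduces the standard GC exactly, and effective GC is monotone in every
per-cytosine fraction. We deliberately use this reference-strand tally
(rather than averaging the two strands' conversions) because it is the
composition seen by the plus-strand read-out and keeps the fully
methylated and fully unmethylated limits exact; the map's minus-strand
records are accordingly not consulted.

## Segmentation and calling

`cbs_segment()` implements circular binary segmentation: on each interval
it finds the arc $(i, j]$ maximizing the mean-shift statistic

$$T^2 = \frac{(\bar x_\text{arc} - \bar x_\text{rest})^2}
             {s^2\,(1/k + 1/(m-k))},$$

with $s^2$ the interval's overall variance — constant across arcs, as in
standard CBS practice; a within-group pooled variance would reward arcs
trimmed to exclude extreme bins and over-segment flat regions. The split
is accepted when its permutation p-value (1000 permutations, seeded,
deterministic) falls below `alpha = 0.01` and every resulting segment
spans at least `min_width` bins; the procedure recurses until no split is
accepted. The permutation loop stops early once the exceedance count
already forces $p \ge \alpha$ — this changes no decision and keeps deep
recursions fast. Segmentation runs on $\log_2(\text{depth}/\text{median})$
(zeros replaced by half the smallest positive depth), which stabilizes the
variance across copy-number levels.

`min_width` defaults to 2 when $\lambda < 100$ (low coverage, where
resolution is scarce) and 4 otherwise (deep data, where requiring several
consecutive bins suppresses false positives); it can be overridden.

Masked bins are removed before segmentation and coordinates re-expanded
afterwards; a segment may span an interior masked gap. Segments tile the
unmasked extent of each chromosome, and interior gaps are assigned to the
right-hand segment so adjacent segments share boundaries exactly.

`call_segments()` converts segment mean depths to absolute copy number as
$2 \cdot \text{mean} / \lambda_\text{diploid}$. The diploid anchor is the
genome-wide median unmasked depth — robust as long as most of the genome
is diploid; when more than half of the bins land in called segments the
pipeline falls back to the model's expected $\lambda$ (a median anchor
would be dragged by the alterations themselves). Gain/loss flags compare
segment means against the bin-level thresholds, which is conservative:
segment means have smaller variance than single bins.

## Breakpoint refinement

Bin-level segmentation localizes a boundary to within a bin
(tens of kilobases at low coverage); junction coordinates from discordant
read pairs are precise to a few bases. `refine_boundaries()` moves the
boundary between a called (gain/loss) segment and its neighbor to a
supplied breakpoint when **exactly one** breakpoint lies strictly within
half a bin size of it; windows containing zero or several breakpoints are
ambiguous and left alone, as are junctions between two neutral segments
and any move that would invert a segment. Both segments sharing a boundary
move together, so the tiling is preserved, and the operation is
idempotent. Support counts on breakpoints are carried but not thresholded
— with no principled cutoff we treat every supplied breakpoint as equally
credible.

## The simulation harness

`simulate_counts()` generates the study conditions used for validation:
a chromosome-1-sized territory (247 Mbp by default) of diploid bins drawn
from the negative binomial model at the coverage-implied $\lambda$
(VMR 3), with one seeded interval drawn at copy number 3 (or 1).
The generator works at bin level — the validation protocol is defined on
distributions of reads per region, and bin-level draws are the minimal
faithful form — while `simulate_reads()` additionally places each read
uniformly within its bin to exercise the full I/O path. Seeded CNA edges
snap to bin boundaries by default; `snap = FALSE` leaves them off-grid for
refinement studies. Mapability dips and GC-bias curves can be injected to
exercise the correction path.

What the generator does *not* emulate: correlated bias along the genome,
fragment-length effects, mapability structure of real repeats, and
subclonal (non-integer) copy numbers. Passing the harness therefore
demonstrates the statistical machinery under the model's own assumptions,
not performance on any particular real library.

`run_trials()` scores each trial by the validation protocol: a seeded
alteration is *detected* when some gain/loss call matches both of its
edges within one bin size; any call failing the both-ends test is a false
positive; specificity is one minus the fraction of trials with at least
one false positive. Per-trial seeds derive deterministically from the
master seed.

For routine testing we run the harness on an 8 Mbp chromosome with a
2 Mbp seeded gain — at the model-selected bin size this is ~1300 bins per
trial, large enough to exercise segmentation and small enough that
100-trial batteries complete in minutes. At 5-fold coverage the battery
achieves sensitivity and specificity 0.99 (100 trials, seed 20240901; the
test suite asserts at least 0.95); sensitivity is saturated at this alteration
size across 0.5–4-fold coverage, so the coverage trend check allows
binomial Monte-Carlo slack. Residual false positives stem from α-level
false splits accumulated over the recursion — the same multiple-testing
phenomenon any recursive segmentation has — and match the configured
alpha in magnitude.

## Numerical and design notes

- Threshold search is exact (CDF arithmetic), not sampled; `support_max`
  (the $1-10^{-9}$ quantile across classes) bounds mass sums where a
  finite support is needed.
- The bin-size grid step (100 bp) and ceiling (10 Mbp) are configurable;
  the no-solution error reports the best achievable FDR.
- Boundary counts equal to a threshold are neutral; the thresholds
  themselves satisfy $t_\text{loss} < \lambda < t_\text{gain}$ whenever a
  solution exists.
- Reads are assigned to bins by start position (0-based, half-open bins):
  deterministic across read lengths and faithful to unique-start counting.
  Duplicate start positions are retained.
- The mappable genome size used for $\lambda$ excludes territory whose
  mapability falls below the floor; pass `genome_size` explicitly to
  override.
- Per-chromosome work (binning, correction, segmentation) parallelizes
  across workers; permutation streams are seeded per chromosome from the
  master seed and merged in declared chromosome order, so output is
  byte-identical for any worker count.

## Known limitations

- Copy-number classes beyond {1, 2, 3} do not inform threshold setting;
  highly amplified segments still receive correct copy-number estimates
  but the FDR guarantee is formulated on the three-class problem.
- VMR is not estimated from the data; a misspecified VMR shifts the
  effective FDR.
- No matched-normal mode: somatic and germline alterations are not
  distinguished.
- Breakpoint detection itself is out of scope; refinement consumes
  externally supplied junction calls.
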