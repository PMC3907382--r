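---
title: "CNV discovery from two-channel aCGH: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV discovery from two-channel aCGH: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcnv)
library(dplyr)
```

## The measurement model

Array CGH co-hybridizes a test genome (Cy3) and a diploid reference genome
(Cy5) onto a tiling probe array. For a probe covering a locus at `c` copies in
the test sample, the expected log2 intensity ratio is

> E[log2(test / reference)] = log2(c / 2),

so a heterozygous duplication (3 copies) sits at +0.585, a 4-copy gain at +1,
a heterozygous deletion at −1, and diploid loci at 0. Three nuisance
processes sit between that ideal and the scanner output, and the pipeline
removes them in a fixed order:

1. **Spatial artifacts** — smooth intensity trends across the physical array
   surface (hybridization, washing). Removed per channel by `spatial_correct()`,
   a LOESS (locally weighted linear, tricube kernel) surface of log2 intensity
   over the `(row, col)` grid rescaled to the unit square.
2. **Dye bias** — the two fluorophores respond differently, and the difference
   depends on intensity. Removed by `qspline_normalize()`, a monotone cubic
   spline through quantile anchor pairs.
3. **Probe-level noise** — modelled as independent Gaussian noise on the log2
   scale per channel.

Ratios are formed only after both corrections (`to_log2_track()`), then each
chromosome is segmented into constant-mean blocks by exact dynamic programming
(`dp_segment()` / `segment_track()`), and segments become CNV calls under the
stringent retention rule: `|segment mean log2 ratio| >= 0.5` over at least 5
consecutive probes (`call_cnvs()`). Per-sample calls merge across samples into
CNV regions (CNVRs) by transitive ≥ 1 bp overlap (`merge_to_cnvrs()`), which
feed the population summaries (`chromosome_summary()`, `status_summary()`,
`size_bins()`, `label_sharing()`, `common_in_all()`, `genes_overlapping()`).
qPCR validation uses the pure 2^−ΔΔCt form with a reference gene and a
calibrator sample (`ddct_rcn()`, `concordance()`).

## What the simulator emulates — and what it does not

`design_probes()`, `plant_cnvs()`, `simulate_array()` and
`simulate_self_self()` generate the data the pipeline assumes:

* a tiling design at a mean probe spacing of 1650 bp (uniform jitter, default
  ±20%), probes laid row-major onto a near-square array grid;
* planted CNVs with copy numbers drawn from {0, 1, 3, 4} and sizes from a
  truncated lognormal (`meanlog = log(15110)`, `sdlog = 1.3`, truncated to
  6.1–570 kb). Horse aCGH surveys report CNV sizes spanning exactly that range
  with a mean near 43 kb and a median near 15 kb — strongly right-skewed — and
  the truncated lognormal reproduces the range and the mean (≈ 42 kb; its
  median lands near 22 kb because the 6.1 kb lower cut removes the smallest
  draws). A uniform option exists but produces a mean size of ~288 kb, seven
  times the observed value, so it is not the default;
* planted CNVs are kept at least `min_gap = 20` kb apart. Two events separated
  by less than a dozen probe intervals are indistinguishable from one event at
  this probe density, so the generator only plants configurations the design
  can resolve in principle;
* multiplicative lognormal intensity noise (`noise_sd = 0.15` per channel on
  the log2 scale, a typical aCGH ratio dispersion), a monotone power-law dye
  bias on the test channel (`test' = 1.2 * test^0.95`), and a smooth spatial
  gradient (a plane spanning 0.3 log2 units across the array diagonal plus one
  low-frequency sinusoid at a quarter amplitude) added to both channels;
* homozygous deletions (0 copies) are simulated at an effective copy number of
  0.25 (expected ratio −3), representing residual background hybridization;
  real zero-copy loci never yield zero fluorescence;
* a self-self mode: the same DNA in both channels, so every downstream call is
  a false positive by construction.

Features of real arrays the simulator does **not** emulate: position-dependent
probe spacing (real designs skip repeats, with gaps up to ~180 kb), probe-
specific affinities and GC effects, saturation, spatially correlated noise,
mosaicism, and partial-overlap probe signal (a probe is "inside" a CNV iff its
midpoint is — a single unambiguous rule). Passing the recovery benchmark
therefore demonstrates that the *algorithms* behave correctly under the stated
statistical structure, not that real-array sensitivity would be this high.

## Normalization: the two decisions that matter

**Anchors from neutral regions only.** Quantile normalization assumes the two
channels differ only by bias. Probes inside real CNVs violate that: their mass
warps the quantile correspondence and the fitted map shrinks the very signal
being measured — in the limit of a symmetric target, signal present in only
one channel's tail is pulled halfway back toward the other channel.
`qspline_normalize()` therefore estimates its anchors from apparently
neutral probes — raw log2 ratio, smoothed over 5 consecutive probes, within
0.25 of the median — and applies the fitted map to all probes; this is the
invariant-set idea long used in expression-array normalization. The smoothing
is essential, not cosmetic: masking on *unsmoothed* ratios preferentially
discards probes with large noise deviations in either channel, which equalizes
the two channels' apparent spreads and flattens exactly the tail slope the map
must estimate, biasing recovered CNV magnitudes toward zero.

**Anchor range and tail behaviour.** Anchors span probabilities 0.02–0.98
(100 by default). The extreme quantiles are where genuine copy-number signal
lives; bending the spline there shrinks it. Beyond the anchor range the map
continues linearly, with the slope estimated by least squares over the outer
tenth of the anchors (single-interval slopes of empirical quantiles are too
noisy to extrapolate through the tails). For a power-law dye bias — affine on
the log scale — this linear continuation is exact. The default target
distribution is the **reference channel**: the reference genome is diploid by
construction, so it is the natural calibrator, and mapping only the test
channel leaves genuine test-channel signal at full magnitude (a symmetric
geometric-mean target, also available, shrinks it by (1+b)/2 for a power bias
exponent b).

## Segmentation: exact least squares and the choice of k

`dp_segment()` computes, for every `k = 1..k_max`, the global minimum of the
within-segment sum of squared deviations over all partitions of the sequence
into `k` contiguous blocks — prefix-sum SSE evaluation, O(k_max · n²) overall,
validated against exhaustive enumeration. The number of segments is chosen by
minimizing `SSE_k + λ·k·log n`. The penalty weight defaults to

> λ = 2 · (mad(diff(x)) / √2)²,

a BIC-type cost: each extra segment spends two parameters (a level and a
breakpoint), priced at the robustly estimated per-probe noise variance. The
factor matters and was validated on the recovery benchmark: halving it
fragments real CNVs into sub-threshold pieces and floods the calls with
boundary fragments (sensitivity and precision both drop), tripling it merges
short CNVs into their flanks. `k_max` defaults to 10 segments per Mb of
probe-covered sequence — an order of magnitude above realistic CNV density at
1650 bp spacing, so the budget never binds. Ties in the penalized cost prefer
fewer segments; ties inside the DP keep the earliest feasible split point,
making results deterministic.

Numerical notes: values are mean-centred before the DP (SSE and breakpoints
are translation-invariant; the prefix sums stay well conditioned); block SSE
is clamped at zero against rounding; costs are validated against the
brute-force oracle in the test suite.

## Calling, merging, summaries

The retention rule is applied verbatim and the boundary is inclusive: a
segment mean of exactly ±0.5 is called (gain at ≥ 0.5, loss at ≤ −0.5,
unchanged strictly inside). Thresholds apply to the segment mean, not to
individual probes. Calls never overlap within a sample because segments
partition each chromosome.

CNVR merging takes the transitive closure of ≥ 1 bp overlap per chromosome
across samples; book-ended intervals (0 shared bp) do not merge. Coordinates
are 1-based inclusive throughout (`length = end − start + 1`); BED export
converts to 0-based half-open at the boundary and the converters are exact
inverses. CNVR status is gain/loss if members are unanimous, otherwise both.
Sharing is assessed at the overlap-component level: every call in a component
spanning ≥ 2 samples is "shared" with that component's sample count, so an
A–B–C overlap chain marks all three calls as shared among 3 samples even if A
and C are disjoint.

Summary tables round half-up to 2 decimals (conventional table rounding —
base R's round-half-even would print 4.835 as 4.83). The genome-wide CNVR
coverage percentage in the totals row uses the **autosomal** genome length as
denominator: surveys of mares call autosomes only, while assembly tables still
list X. With the bundled reference tables this choice reproduces the printed
0.61% exactly; including X would give 0.57%. Size bins are half-open
`[lo, hi)` in kb, so a region of exactly 50 kb falls in 50–100 kb.

## qPCR validation

`ddct_rcn()` implements the pure 2^−ΔΔCt form (no amplification-efficiency
correction): triplicate Ct values are averaged (triplicates with a range above
0.5 cycles are flagged — standard practice), ΔCt is target minus reference
gene, ΔΔCt is test minus calibrator, and the relative copy number is 2^−ΔΔCt.
Status thresholds default to gain ≥ 1.4 and loss ≤ 0.6 — midpoints between the
diploid ratio 1.0 and single-copy changes (1.5 / 0.5) with margin for assay
noise. `concordance()` scores qPCR status against the array call overlapping
the assay's target region (no overlapping call means "unchanged"); when
several calls overlap, the largest overlap decides.

## Benchmarks and the problem sizes used

`recovery_benchmark()` simulates, per replicate, a 16-chromosome × 5 Mb
genome (80 Mb, ~48,000 probes) carrying 30 planted CNVs, with noise, dye bias
and gradient at their defaults, runs the full pipeline, and scores calls
against truth by reciprocal 50% overlap — our benchmarking convention for
"recovered". Sensitivity is pooled over *callable* truths (≥ 5 covering probe
midpoints and expected |log2 ratio| ≥ 0.5 — events the retention rule could
ever keep); precision is pooled over all calls, scored against all planted
CNVs. The 80 Mb genome keeps the planted CNV load near 1.6% of probes:
quantile normalization assumes a mostly neutral array (real whole-genome
surveys run well below 1%), and the benchmark is meant to test the pipeline in
that regime, not under a CNV load no real genome shows. The test suite asserts
sensitivity and precision of at least 0.95 pooled over 20 replicates, and
`scripts/acceptance.R` recomputes both from a fresh seed; the residual misses
are short 3-copy gains whose segment mean (signal
0.585, threshold 0.5, noise ≈ 0.21/√n per probe-mean) dips below 0.5 — the
stringent threshold deliberately trades single-copy-gain sensitivity for a
zero false-positive rate.

`self_self_benchmark()` runs the full chain on self-self arrays (10 Mb genome,
~6,000 probes per replicate); with the default retention rule every replicate
yields zero calls, while loosening the filters makes calls appear — the zero
comes from the filter, not from luck.

## Degenerate inputs and edge cases

* Chromosomes shorter than the probe spacing get no probes, with a warning.
* A constant (degenerate) channel makes quantile anchors non-monotone;
  normalization falls back to median scaling with a warning.
* `dp_segment` rejects non-finite values and `k_max > n`; `brute_force_segment`
  is guarded at n ≤ 25.
* Homozygous-deletion probes keep positive intensity via the background floor.
* Zero CNVRs produce zero-filled summary rows (mean size 0 by convention).
* All randomness flows through explicit seeds; identical configs give
  byte-identical pipeline outputs.

## Known limitations

* The segmentation penalty is a surrogate: the commercial segMNT algorithm's
  stopping rule is proprietary, so the BIC-type λ here is this package's own
  calibrated choice, exposed as `penalty_lambda`.
* Integer copy numbers are not estimated from ratio magnitude; calls are
  gain/loss only, as in the retention rule.
* The simulator's homogeneous probe spacing understates the patchiness of real
  tiling designs around repeats.
* Sensitivity for heterozygous duplications (3 copies, +0.585) is inherently
  marginal at the 0.5 threshold for short events; this is a property of the
  published thresholds, not of the implementation.
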