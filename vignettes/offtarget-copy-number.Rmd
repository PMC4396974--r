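---
title: "Copy-number inference from off-target reads: models and choices"
author: "offtargetCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number inference from off-target reads: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Targeted sequencing (whole-exome, gene panels, ChIP-seq) enriches selected
regions, but enrichment is only 40–60% efficient: a large share of the
library maps elsewhere. Those off-target reads are approximately uniform
over the genome and their local density is proportional to DNA copy number,
which makes them a better substrate for genome-wide copy-number inference
than the on-target reads, whose density is dominated by heterogeneous bait
efficiency and by the uneven genomic distribution of exons.

The estimator is a binned read-depth model. For bin $i$ of width $L_b$ with
$x_i$ bp masked by enrichment peaks:

* raw depth of coverage $D_i$ = number of reads whose leftmost aligned base
  falls in bin $i$, after quality filtering and peak removal;
* compensated depth $C_i = D_i \cdot L_b / (L_b - x_i)$, restoring the
  expectation lost with the masked territory (a bin with less than 10% of
  its width unmasked is set to missing instead — the multiplier would be
  an extrapolation from almost nothing);
* two multiplicative loess corrections (GC content, then mean
  mappability): $C_i \leftarrow C_i \cdot \mathrm{med}(C) / m(c_i)$ where
  $m$ is a robust loess fit of $C$ on the covariate;
* $\log_2$ ratio to the median of usable autosomal bins; in relative mode
  the reference sample's value is subtracted bin-wise.

Segmentation is circular binary segmentation (CBS): recursively find the
circular arc maximizing a pooled-variance two-sample t-like statistic and
accept the split when its permutation p-value falls below $\alpha$.

## Read filtering

Reads must be mapped, primary, properly paired (SAM FLAG 0x2), non-duplicate
and have mapping quality at least 37; mitochondrial reads are dropped.
Read-category QC (`classify_reads`) assigns every primary record to exactly
one of: low quality, mitochondrial, in peaks, remaining — in that order, so
the counts are exhaustive and sum to the record count. Duplicates and
unmapped records count as low quality; the order of the quality and
duplicate checks is a convention (the categories are reported jointly
anyway).

## Peak detection and masking

Enrichment peaks are called with a single-sample local-Poisson model on the
reference when one is given, otherwise on the sample itself. Each read is
extended to $d$ = 200 bp from its 5′ end; a base with extended coverage $k$
is significant when $P(X \ge k;\ \lambda_{local}) < 10^{-5}$, with
$\lambda_{local} = \max(\lambda_{genome}, \lambda_{5\,kb},
\lambda_{10\,kb})$ (windows centered on the base, clipped at chromosome
ends and normalized by their actual width; the genome rate excludes
mitochondria). Significant bases within 100 bp merge into peaks; peaks
under 50 bp are dropped.

Two deliberate extensions of the basic caller:

* **Flank masking.** Called peaks are widened by one fragment extension
  (200 bp) per side before removal. Sequences flanking an enriched region
  are co-enriched — a fragment overlapping the region places read starts up
  to a fragment length outside it — and the significance ramp at the peak
  edge would otherwise leave that shoulder unmasked. Because peak width
  scales with local coverage, unmasked shoulders leak *copy-number
  dependent* read counts into the bins, which compresses absolute-mode
  deflections toward zero. With the flank, relative and absolute modes
  agree (a property the test suite checks on simulated tumor/normal
  pairs).
* **Precomputed peaks.** A peak BED (e.g. from an external caller) can be
  supplied instead, bypassing the internal caller.

A read overlapping a peak by at least 1 bp is discarded, identically in
sample and reference. Removal is what makes the profile robust: the same
masked territory is compensated away in both, while bait-efficiency
variance — which does not cancel between independent libraries — is removed
rather than modeled.

## Normalization choices

* Corrections are multiplicative ratios to a fitted curve, rescaled to the
  median — the standard read-depth convention; values stay on the count
  scale until the final log2.
* The loess fits (span 0.75, degree 2) use the *symmetric* (Tukey
  biweight) family and are computed on the log2 scale, back-transformed
  for the multiplicative correction. Both choices exist to keep real
  copy-number signal out of the technical-bias curve: with a least-squares
  fit, a megabase-scale amplification concentrated in one GC band flattens
  its own signal; and on the linear count scale a halving (CN 1) is a
  smaller absolute residual than a doubling (CN 4), so robust weights
  reject losses only partially and the fitted curve dips where losses lie —
  on the log scale gains and losses are symmetric outliers. The acceptance
  checks on segment-mean recovery exercise exactly this failure mode.
* Order: GC first, then mappability, following the workflow's phrasing
  order; with multiplicative corrections the order matters little.
* Median normalization uses usable *autosomal* bins only, so sex-chromosome
  copy state cannot shift the baseline, and is computed on the log scale —
  that makes the usable-autosome median of the output exactly 0 for even
  bin counts too.
* Bins are unusable when mean mappability < 0.2, when they touch the
  exclusion list at all (the default tolerance is zero), or when the
  compensated count is zero or missing. Zero-count bins are excluded rather
  than offset by a pseudocount: a fabricated ratio is worse than a missing
  one.
* The exclusion list and the mappability track are user-supplied files; no
  genome-specific data are bundled.

## Segmentation

The split statistic is the two-sample t statistic with pooled variance over
all circular arcs whose arc and non-empty flanking pieces hold at least
`min_width` (2) bins. The reference distribution is permutation-based
(default 10,000 permutations, $\alpha$ = 0.01), seeded and therefore
reproducible; we prefer the exact-at-resolution permutation test over tail
approximations and make the count configurable for speed. Two shortcuts
never change the accept/reject decision: the arc scan stops once any arc
reaches the observed statistic, and permutations stop early once enough
exceedances have accumulated that $p \ge \alpha$ is guaranteed (the
reported p-value for *accepted* splits is always based on the full
permutation count). Mathematically tied arcs (an arc and its complement)
are detected with a relative tolerance of $10^{-10}$ and broken toward the
shorter arc, then the smaller start index, so results are deterministic.
Segment means are arithmetic means of member bins; segment coordinates span
skipped (unusable) bins between members. An optional undo pass merges
adjacent segments whose mean difference is below `undo_sd` times the
profile's diff-based MAD.

With very few bins the permutation p-value is discrete: a perfect two-level
split of 10 values has $p \approx 0.08$ because ~8% of random permutations
are also perfectly separated, so no split can be significant at
$\alpha = 0.01$. This is a property of the test, not a defect; segments of
interest span tens of bins.

## Evaluation statistics

* `mad_diff`: $1.4826 \cdot \mathrm{med}|d - \mathrm{med}(d)| / \sqrt{2}$
  over lag-1 differences $d$ — a per-bin noise sd estimate that ignores
  piecewise-constant signal. The $\sqrt 2$ converts the spread of a
  difference of two bins to a single bin's.
* `signal_to_noise`: |mean of the segment overlapping a query region the
  most| / MAD.
* `segment_concordance`: length-weighted Euclidean distance
  $\sqrt{\sum w_r (a_r - b_r)^2 / \sum w_r}$ and length-weighted Pearson
  correlation (lengths as frequency weights) over the overlap regions of
  two segmentations. The normalized distance form is fixed by the
  requirement that a constant shift $c$ yields distance $c$.
* `array_pseudocounts`: nearest-probe-to-bin-center or mean-of-in-bin-probes
  projection of array intensities onto the bin grid.
* `random_placement_overlap`: permutation null for interval overlap,
  preserving the query length distribution, chromosomes weighted by
  placeable length; the empirical p uses the +1 correction so it is never
  exactly zero.

## The simulator: what it emulates and what it does not

`simulate_capture_experiment` emulates the structure that matters to this
method: bait tiling (120 bp baits every 10 kb) with log-normal per-bait
capture efficiencies (sdlog 0.5) shared between a sample and its reference;
Poisson on-target pair counts per bait ($\theta_{on} \cdot e_b \cdot
CN/2$); an off-target background uniform per bp and proportional to copy
number ($\theta_{off} \cdot CN/2$); proper read pairs with a configurable
low-mapping-quality fraction; and a known piecewise-constant copy-number
truth.

Default rates are chosen as a realistic capture regime: $\theta_{on} = 100$
pairs per bait per diploid copy (WES-scale bait coverage — substantially
lower rates would let the weakest baits fall below peak-caller
significance, which real exomes do not do) and $\theta_{off} = 2\times
10^{-3}$ pairs/bp, i.e. about 80 off-target read starts per 20 kb bin and
an off-target fraction around a tenth of the library, the regime in which
off-target profiling applies. The default study design places a CN=4 and a
CN=1 region of 2 Mb on two 10 Mb chromosomes — small enough that a full
tumor/normal analysis runs in about two minutes on one CPU, large enough
for 2 Mb events to span 100 bins.

The simulated genome's GC runs as a monotone gradient (0.30 to 0.60) along
each chromosome with an isochore-like sinusoidal fluctuation (amplitude
0.05, period 700 kb) superimposed. The fluctuation is deliberate: with a
strictly monotone profile, GC is collinear with genomic position, so any
GC correction can trade off against megabase-scale copy-number signal —
an artifact no real genome exhibits. By default reads carry *no* GC bias;
setting `gc_bias` > 0 thins fragments with acceptance probability
$\propto \exp(\mathrm{gc\_bias} \cdot (GC_{local} - 0.45))$ to exercise
the correction.

Not emulated: sequence-level realism (reads are emitted as aligned records
with their positions; SEQ is not filled in), insert-size distributions,
sequencing error, FFPE damage, homologous co-capture ("orphan peaks"),
subclonality and normal-cell admixture, and reference-genome artifacts
(real mappability structure, assembly gaps). Passing tests therefore show
that the pipeline's arithmetic and segmentation recover truth under the
stated stochastic model — not that it is robust to every artifact of real
capture data.

## Problem sizes used by the test suite

The shipped tests run the full default study (two 10 Mb chromosomes,
~280,000 read pairs) once and reuse it across checks; the replicate
breakpoint-recovery property uses ten tumor/normal pairs on a scaled-down
two-chromosome 3 Mb design with the same per-bp rates, and unit tests use
kilobase-scale hand-built fixtures. These sizes are the package's choice of
a desk-scale experiment; the estimator itself has no size assumptions
beyond "enough usable bins for a loess fit" (30).

## Known limitations

* The peak caller is a simplified single-sample local-Poisson model: no
  fragment-size model building, no duplicate-tag correction, no FDR. For
  real data one may prefer an external caller and pass its BED.
* Coverage is counted by read starts; mate pairs are two (correlated)
  counts. The local-Poisson significance model treats reads as independent,
  so at very low depth paired clumping slightly inflates base-level false
  positives (a few sub-100 bp peaks per 20 Mb of pure background); the
  masked territory involved is negligible and compensated.
* `ontarget` mode (mean per-bp depth on capture regions) inherits bait
  efficiency variance by construction; it exists as the comparator, not as
  a recommended analysis.
* CBS here always tests arcs against permutations; the original's hybrid
  tail approximation and outlier pre-smoothing are not reproduced, so
  segment boundaries on real data may differ in detail from other
  implementations.
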