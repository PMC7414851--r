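---
title: "Methods: window profiling, compartment eigenvectors and PLA counting"
author: "RepliProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window profiling, compartment eigenvectors and PLA counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepliProfiler)
```

RepliProfiler implements two quantitative pipelines around a common
genomic window model, plus seeded generators that produce data with the
same statistical structure so every stage can be validated against a known
ground truth.

## The genomic window model

All genomic statistics are computed on equal-width windows (default 50 kb,
the standard resolution for replication-timing and coarse compartment
analysis). `makeWindows()` tiles each chromosome from position 0 and
**drops the terminal partial window** by default: the TPM and quantile
machinery assume equal-width units, and a sub-width terminal window would
otherwise need a length correction. The number of dropped bases is always
reported. Coordinates are 0-based half-open on disk (BED/bedGraph dialect)
and 1-based closed in memory (the `GRanges` convention); `rtracklayer`
performs the conversion so no off-by-one arithmetic appears in user code.

Score tracks (replication timing as RT = log2(Early/Late), histone-mark
coverage, eigenvectors) are binned by `binTrackMean()` as the
coverage-length-weighted mean of overlapping interval values, which equals
the base-resolution mean for non-overlapping tracks; windows with no
coverage are `NA`, never silently zero, and such windows are excluded from
quantile analyses with a logged count. Tags are binned by
`binTagCounts()` using **fragment-midpoint assignment**: each tag falls in
exactly one window, so `assigned + discarded` equals the input count
exactly and tags-per-million semantics stay exact. Fractional assignment
of boundary-spanning reads was rejected because it breaks that exact
conservation for no measurable benefit at 50-kb resolution.

## Enrichment, selection and quantile profiles

Counts are scaled to TPM (`counts / total * 1e6`; no length term, since
windows are equal width). Enrichment is `log2((chip + c)/(input + c))` on
TPM with a default pseudocount of `c = 1` TPM, which regularizes
zero-coverage windows; `c = 0` is permitted only for strictly positive
tracks. Enriched windows are those with **strictly** positive enrichment.
Matched controls are drawn uniformly without replacement from all retained
windows, matching the enriched set in number (and trivially in window
size); enriched windows are *not* excluded from the pool by default —
exclusion is available via the `exclude` argument but changes the null
from "random genome" to "random non-enriched genome".

Quantile labels (`assignQuantiles()`, default n = 25) sort windows by
score ascending, break ties by genomic order for reproducibility, and cut
into contiguous bins whose sizes differ by at most one (the remainder goes
to the lowest quantiles). Quantile 1 is always the latest-replicating /
most-B end. Per-quantile coverage is summarized with interpolated (type-7)
quartiles and Tukey whiskers (most extreme points within 1.5 IQR of the
hinges), plus the mean. The trend across quantiles is the Spearman rank
correlation between quantile index and quantile mean coverage: +1 for a
factor that rises monotonically toward early/A, -1 toward late/B.

The selected-versus-controls comparison and all condition comparisons use
a two-sided Mann-Whitney rank-sum test (`mannWhitneyU()`). For
`min(n, m) <= 8` without ties the p-value is exact, from the U null
distribution computed by the standard counting recursion; otherwise the
tie-corrected normal approximation with continuity correction is used. The
two branches agree within 0.01 at the crossover, and degenerate all-tied
input yields p = 1. No multiple-testing correction is applied: each figure
panel-style comparison is a single pre-specified test.

## Compartment eigenvector

`compartmentPipeline()` follows the standard A/B compartment computation
on one chromosome at a time (compartment eigenvectors are not comparable
across chromosomes):

1. **Masking.** Bins with fewer than 25% nonzero contacts (configurable),
   including all-zero bins, are removed: Knight-Ruiz balancing is unstable
   on sparse rows.
2. **Knight-Ruiz balancing** (`krBalance()`): a Newton inner-outer
   iteration with a conjugate-gradient inner solve finds `x > 0` with
   `diag(x) M diag(x)` having unit row sums; the residual tolerance
   default is 1e-12, and non-convergence falls back to square-root
   coverage normalization with a warning.
3. **Observed/expected** (`observedOverExpected()`): each entry is divided
   by the mean balanced signal at its genomic distance, removing distance
   decay so that compartment structure dominates the correlations.
4. **Pearson matrix** of O/E rows, then **PC1** of its column-centered
   covariance. The Pearson step is computed on O/E, not on raw balanced
   counts — the convention of the standard tools; this choice is stated
   explicitly because naming a tool does not pin it down. The
   pre-orientation sign is fixed deterministically (largest-magnitude
   loading positive) and a degenerate top-of-spectrum is flagged.
5. **Orientation** (`orientEigenvector()`): the sign is flipped iff the
   correlation with a reference track (RT by default, since A replicates
   early) is negative, so that positive values mean A. When the absolute
   correlation is below 0.05 the orientation is ambiguous and left
   unchanged with a flag.

The pipeline is invariant to global positive scaling of the raw counts,
and on the default synthetic contact matrix it recovers the generating
compartment labels with 100% sign agreement.

## Synthetic data: what it emulates, and what it does not

`simulateGenome()` draws alternating A/B blocks with geometric run lengths
in window units (memoryless, matching the blocky appearance of real
eigenvector tracks) with mean block length 500 kb and an expected A
fraction of 0.5. RT is +1.5 (A) or -1.5 (B) plus Gaussian noise of 0.5 RT
units — a realistic dynamic range for log2(Early/Late) tracks, giving an
RT-compartment correlation of about 0.95. Histone marks are multinomial
tag sets with a 4-fold weight in the favored compartment (H3K4me3 in
A/early, H3K9me3 in B/late). `simulateChipCounts()` distributes a library
multinomially with `p_i` proportional to `exp(beta * rt_i)`: `beta = +1`
gives an early-skewed (DONSON-like) factor, `-1` a late-skewed
(FANCM-like) one, `0` an unbiased Input. Because no window-level effect
size is published for these factors, `beta = +/-1` is a calibration
choice, documented as such: it produces a roughly 20-fold expected
coverage span across the RT range, enough that quantile trends saturate.

`simulateContactMatrix()` Poisson-samples a symmetric matrix with expected
intensity `(|i-j|+1)^(-1)` times `(1 + boost)` for same-compartment pairs
(boost default 1), mirroring the upper triangle so symmetry is exact.
`simulatePlaImages()` renders non-overlapping nuclear disks on a jittered
grid (20 px radius) with per-nucleus Poisson foci (means 4 versus 1 in the
two default conditions, 60 nuclei per condition — the scale at which such
experiments are scored) as 1.5-px Gaussian spots plus 5% read noise.
Within a nucleus, foci are kept at least 8 px apart and 3 sigma + 1 px from
the rim; this is a *fixture guarantee* that makes ground-truth counts
exactly recoverable, chosen so that the intensity valley between two
neighboring spots (~0.06) sits far below the detection floor (0.3).
Every generator consumes one seed; sub-generators derive child seeds
deterministically (`childSeed()`), so extending a pipeline never perturbs
existing streams.

Features of real data deliberately *not* emulated: read-level sequences,
fragment-length and GC biases, mappability gaps, continuous compartment
strength, translocation noise in Hi-C, optical aberrations beyond an
isotropic Gaussian PSF, touching nuclei, and 3-D chromatin structure.
Passing the recovery tests therefore demonstrates the correctness of the
computational chain under the stated generative model, not performance on
real libraries or micrographs.

### A structural limit of the binary compartment model

Because the simulated contact intensity depends on compartment *labels*
only, the computed eigenvector's ordering of windows *within* a
compartment is pure sampling noise, uncorrelated with the RT noise that
drives within-compartment coverage differences. The Spearman trend across
25 eigenvector quantiles is then bounded in expectation by the
between-compartment share of rank variance — about 0.81 for balanced
compartments, and lower when the realized A fraction deviates from 1/2
(with a perfect binary eigenvector we measure 0.753 +/- 0.065 across
seeds). Real eigenvectors are continuous and co-vary with RT inside
compartments, which is why observed eigenvector-quantile profiles in real
data can be steeper than this simulation can produce. The RT-quantile
trend has no such ceiling and saturates at +/-1. We keep the binary model
because it is the stated generative contract of the contact simulator; the
ceiling is documented rather than engineered away.

## PLA quantification

`segmentNuclei()` smooths the DAPI channel (Gaussian, sigma 2 px),
thresholds at Otsu's level with an absolute floor of 0.2 (so a noise-only
image yields zero objects), fills holes, labels connected components and
filters by area. `detectFoci()` band-passes the PLA channel with a white
top-hat (disc radius 5 px), thresholds at `median + 6 * MAD` with a 0.3
floor, labels, and discards components larger than `maxArea` (default
50 px^2) — a large bright blob is not a focus — or smaller than 3 px^2
(single-pixel noise). Centroids are intensity-weighted. These defaults are
this package's own operating point, not values inherited from any
published pipeline configuration. A focus is assigned to the nucleus whose
mask contains its centroid; foci outside all nuclei are excluded, and no
focus is ever counted twice. Quantification is 2-D, on single planes or
maximum-intensity projections; touching nuclei are not separated (the
simulator guarantees separation; a watershed step would be needed for
real confluent fields).

`compareConditions()` reports the fold ratio of mean foci per nucleus and
the Mann-Whitney p-value, labeling p < 0.001 "significant" and p > 0.05
"NS" — the figure-legend convention; the raw p-value is always reported
alongside, so the label convention never hides information.

`registerRounds()` estimates the rigid drift between sequential imaging
rounds: translation at the subpixel-refined peak of the FFT
cross-correlation, rotation by a 1-degree grid search (±15°) with local
refinement, returning the transform that maps round 2 onto round 1 and a
reliability flag when the correlation peak is below 0.2. Recovered
transforms are accurate to well under 0.5 px and 0.5°. `overlapFraction()`
operationalizes colocalization between rounds — the underlying biological
claim has no published statistic, so the definition here is explicit:
greedy nearest-neighbor matching within a radius (default 2 px), with a
permutation null that re-places round-2 foci uniformly within their
parent nuclei; the p-value is the fraction of permutations reaching the
observed match count.

## Numerical choices and degenerate inputs

- KR tolerance 1e-12 on the residual; the balanced row sums agree to
  ~1e-13 relative. Matrices with under 2 retained bins are rejected.
- Zero-variance O/E rows are masked before the Pearson step (warning).
- A flat correlation structure (top two eigenvalues within 1e-6 relative)
  is flagged degenerate; the fixed `eigen()` ordering keeps the output
  deterministic.
- `tpmNormalize()` rejects all-zero samples; `computeEnrichment()` rejects
  mismatched grids.
- Quantile assignment requires at least as many scored windows as
  quantiles.
- All seeded draws run under a temporary RNG state that is restored
  afterwards, so library calls never interfere with user scripts.

## Problem sizes

The bundled demonstration (`runDemo()`) and the validation suite run on a
10-Mb single-chromosome genome (200 windows of 50 kb), 1e6-tag libraries,
a 200-bin contact matrix and 60 nuclei per PLA condition: large enough
that every recovery statistic is far from its decision boundary, small
enough that the complete demonstration finishes in seconds. All analysis
functions are resolution- and genome-size-agnostic; multi-chromosome
grids are handled window-id-wise, with compartment eigenvectors computed
per chromosome.
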