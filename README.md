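# RepliProfiler

Replisomes are not all alike: some accessory factors ride with replication
forks in early-replicating, open (A-compartment) euchromatin, others with
forks in late-replicating, closed (B-compartment) heterochromatin.
RepliProfiler is an R package for the two kinds of quantitative evidence
behind that picture:

1. **Genomic profiling** — relating ChIP-seq enrichment of a factor to
   replication timing (RT) and Hi-C A/B chromatin compartments on a grid
   of equal-width genomic windows.
2. **Image quantification** — counting proximity-ligation-assay (PLA)
   foci per nucleus across conditions, with rigid registration of
   sequential imaging rounds.

It is aimed at genomics/imaging analysts who have binned tracks and
matrices (bedGraph, BED, dense or sparse contact-matrix text, TIFF) and
want the full analysis chain as tested, seeded, reusable functions. A
synthetic-data module generates genomes, ChIP tag counts, contact
matrices and microscopy fields with known ground truth, so the entire
chain is testable without any external download.

## What it computes

On windows of width 50 kb (the default analysis unit):

- **TPM**: `tpm_i = counts_i / sum(counts) * 1e6` (equal-width windows,
  no length term), and **enrichment** `e_i = log2((chip_i + c)/(input_i + c))`
  with pseudocount `c = 1` TPM.
- **Enriched windows**: `e_i > 0` (strict), with matched random controls
  drawn uniformly without replacement, RT distribution summaries
  (median, interpolated quartiles, Tukey whiskers) and a two-sided
  **Mann-Whitney rank-sum test** (exact for `min(n, m) <= 8` without
  ties; tie-corrected normal approximation with continuity correction
  otherwise).
- **Quantile profiles**: windows ranked by RT (or compartment
  eigenvector) and cut into n = 25 equal-count quantiles (quantile 1 =
  latest / most-B); per-quantile TPM distributions and the Spearman
  **trend** between quantile index and mean coverage.
- **A/B compartment eigenvector** from a binned contact matrix:
  Knight-Ruiz balancing, observed/expected by genomic distance, Pearson
  correlation matrix, first principal component, sign oriented so
  positive = A (early-replicating) using RT as reference.
- **PLA foci per nucleus**: DAPI nucleus segmentation (Otsu + area
  filter), top-hat focus detection with a maximum-area filter,
  parent-child assignment by centroid containment, condition comparison
  (fold ratio + Mann-Whitney), FFT-based rigid drift registration
  between sequential rounds, and a permutation test for focus overlap.

## Worked example

Simulate the default 10-Mb study conditions (an early-biased DONSON-like
factor, a late-biased FANCM-like factor, an unbiased input and a
compartment-checkered contact matrix), then run the profile pipeline:

```r
library(RepliProfiler)

gen <- simulateGenome(simGenomeConfig(seed = 1))
rt  <- gen$windows$rt

chip  <- list(donson_like = simulateChipCounts(rt, 1e6, +1, seed = 2),
              fancm_like  = simulateChipCounts(rt, 1e6, -1, seed = 3))
input <- simulateChipCounts(rt, 1e6, 0, seed = 4)
cm    <- simulateContactMatrix(gen$truth$compartment, seed = 5)

res <- runProfile(gen$grid, rt, chip, input, contactMatrix = cm, seed = 1)

res$windows
#> WindowExperiment: 200 windows x 50000 bp, 3 sample(s)
#>   chromosomes: chr1
#>   rt: 200 windows scored; eigenvector: 200 windows scored
#>   samples: donson_like, fancm_like, input
#>   assays: counts, tpm, enrichment

sapply(res$profiles, function(p) sapply(p, `[[`, "trend"))
#>             donson_like fancm_like
#> RT            1.0000000 -1.0000000
#> eigenvector   0.7669231 -0.7830769
```

The early-biased factor's coverage rises perfectly monotonically across
the 25 RT quantiles (Spearman rho = +1), the late-biased factor falls
(rho = -1), and the same signs appear across compartment-eigenvector
quantiles. Enriched windows replicate earlier than matched random
controls:

```r
v <- res$selection$donson_like$violin
c(median_selected = v$selected$median, median_controls = v$controls$median,
  p = v$test$p.value)
#> median_selected median_controls               p
#>    1.686546e+00    1.059575e+00    2.173477e-10
```

The selected windows' median RT (log2(Early/Late)) of 1.69 versus 1.06
for the controls, with Mann-Whitney p ~ 2e-10, is the violin-plot
signature of an early-replicating factor. `runDemo(seed = 1, outDir =
"demo")` runs this plus the PLA pipeline end-to-end and writes a Markdown
report; `runPla()` quantifies image fields, e.g. mean 3.95 vs 1.30 foci
per nucleus (fold ratio 3.0, p ~ 6e-14) for the default 4-vs-1 simulated
conditions.

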