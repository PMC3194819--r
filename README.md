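# ca3sig

Transcriptome signatures and hippocampal MRI texture analysis for
refractory mesial temporal lobe epilepsy (RMTLE).

RMTLE patients split into two clinical phenotypes by their initial
precipitating injury: a history of prolonged febrile seizures (FS) or none
(NFS). `ca3sig` is a tidyverse-native R package for the computational
analyses that characterize this split from surgical specimens:

* **Clinical cohort statistics** — parsing the patient table (yr/mo
  durations, sub-study footnotes) and reporting group means with standard
  errors, plus exact Mann–Whitney comparison of semi-quantitative histology
  grades.
* **SAM differential expression** — the permutation-based significance
  analysis of microarrays for a two-class unpaired design:
  `d_i = (mean_FS − mean_NFS) / (s_i + s0)`, expected order statistics from
  label permutations (exhaustive when feasible), delta chosen at a 5%
  estimated FDR, and selection of genes with `q ≤ 0.05` and linear fold
  change `≥ 3` up-regulated in FS; flag filtering, loess normalization and
  Pearson/complete-linkage clustering around it.
* **Co-expression hub networks** — Spearman link strength between DE-gene
  profiles computed per group, thresholded at `ρ ≥ 0.85` (FS) or
  `0.14 ≤ ρ ≤ 0.70` (NFS), hub ranking by gene–gene link count,
  link-strength histograms, SIF/GraphML export for Cytoscape.
* **GO themes** — hypergeometric overrepresentation of the DE set
  (Benjamini–Hochberg, 5% FDR) and a theme proximity network built from
  Spearman correlations between theme expression centroids, with
  transcriptional modules.
* **MRI texture classification** — per-pixel features over a 9×9 sliding
  window (co-occurrence, run-length, Haar wavelet, fractal, Markov random
  field, Gabor; 150 features by default), class balancing, stratified
  10-fold random-forest cross-validation with Cohen's kappa and ROC AUC.
* **qPCR quantification** — relative standard-curve method with
  reference-gene normalization and FS/NFS fold changes.
* **Synthetic data generators** — seeded generators with known ground truth
  (planted DE genes, latent-factor hub blocks, oriented gratings, planted GO
  terms, dilution series) exercise every stage end to end.

## Worked example

```r
library(ca3sig)

# clinical table: epilepsy onset age by febrile-seizure status
co <- load_cohort_fixture()
cohort_summarize(co, "onset")
#> # A tibble: 3 × 5
#>   group field     n  mean    se
#>   <chr> <chr> <int> <dbl> <dbl>
#> 1 FS    onset     8   7    1.80
#> 2 NFS   onset    15  11.9  1.79
#> 3 all   onset    23  10.2  1.39

# synthetic two-group expression with 50 planted 4-fold genes and a
# 10-gene hub block, at the study design (6 FS vs 12 NFS)
sim <- generate_expression(expression_spec(seed = 42))
fit <- sam_two_class(sim$expression, sim$groups$group, seed = 42)
fit
#> SAM two-class fit (FS vs NFS)
#>   s0 = 0.4709, delta = 0.9253, estimated FDR at delta = 0.0028
#>   50 genes called (target FDR 0.05), sampled permutations (n = 200)

de <- select_de(fit, min_fold = 3)
mean(sim$truth$de_genes %in% de)   # recall of the planted genes
#> [1] 0.92

# FS co-expression network over the selected genes, FS samples only
fs  <- sim$groups$sample[sim$groups$group == "FS"]
rho <- spearman_matrix(sim$expression, genes = de, samples = fs)
net <- threshold_network(rho, lo = 0.85, hi = 1)
net
#> co-expression network: 46 nodes, 22 edges (coefficient in [0.85, 1])
head(hub_degrees(net), 5)
#> # A tibble: 5 × 3
#>   gene  degree  rank
#>   <chr>  <int> <int>
#> 1 g0229      4     1
#> 2 g0851      4     2
#> 3 g0254      3     3
#> 4 g0263      3     4
#> 5 g0295      3     5
```

The FS group means 7 ± 1.8 years (onset) against 11.9 for NFS reproduce the
printed cohort statistics; the SAM fit calls 50 genes at an estimated FDR
below the 5% target and recovers 92% of the planted 4-fold genes after the
3-fold gate; the hub table ranks genes by gene–gene link count in the
high-correlation FS network.

Fitted objects follow broom conventions (`tidy()` for per-gene / per-fold /
per-edge tables, `glance()` for one-row summaries) and have `autoplot()`
methods (SAM quantile plot, hub bar chart, out-of-fold ROC,
standard curve); `plot_link_histogram()` draws the FS/NFS link-strength
distribution.

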