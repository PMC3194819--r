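---
title: "Models and methods behind ca3sig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ca3sig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca3sig)
```

# The scientific setting

Refractory mesial temporal lobe epilepsy (RMTLE) patients divide into those
with a febrile-seizure initial precipitating injury (FS) and those without
(NFS). `ca3sig` implements, as one tested pipeline, the computational
analyses used to characterize that split: SAM differential expression of
hippocampal CA3 transcriptomes (6 FS vs 12 NFS arrays), group-specific
Spearman co-expression networks with hub-degree ranking, GO Biological
Process overrepresentation with theme proximity networks, a pixel-level MRI
texture classifier for dentate-gyrus images, the clinical cohort statistics,
and relative standard-curve qPCR quantification. Synthetic generators with
known ground truth stand in for the study's raw data, so every stage is
exercised against a planted truth.

# Differential expression: two-class SAM

For gene $i$ with group means $\bar x_{i,1}, \bar x_{i,2}$ (log2 scale) and
pooled standard error $s_i$, the statistic is

$$d_i = \frac{\bar x_{i,1} - \bar x_{i,2}}{s_i + s_0}.$$

The fudge factor $s_0$ damps the inflation of $d$ at small $s_i$. It is
chosen as the percentile of $\{s_i\}$ minimizing the coefficient of
variation of the spread of $d$ (median absolute deviation) across ten
quantile windows of $s_i$; with fewer than ten genes the median of $s_i$ is
used. When every $s_i$ equals a common value $s$, any percentile is $s$, so
the choice is exact there.

Significance is calibrated by label permutations: exhaustive enumeration of
group relabellings when $\binom{n}{n_1} \le 10{,}000$ (all 20 relabellings
of a 3v3 design, all 70 of 4v4), otherwise 200 seeded uniform draws — the
study's 6v12 design has 18,564 relabellings and is sampled. Sorted observed
statistics $d_{(i)}$ are compared with the expected order statistics
$\bar d_{(i)}$ (their average over permutations). For a threshold $\delta$,
the upper cutoff is the smallest non-negative $d_{(i)}$ with
$d_{(i)} - \bar d_{(i)} \ge \delta$ and the lower cutoff its mirror image;
genes beyond a cutoff are called.

The estimated FDR at $\delta$ is the **average** number of permuted
statistics beyond the cutoffs divided by the observed call count, capped at
one. The average, rather than the median, of the permuted counts is
deliberate: the median degenerates to zero whenever fewer than half of the
permutations reach the cutoffs, which lets single spurious genes through —
in a pure-null simulation at the study's design the median variant produces
a false call in about half the replicates, while the mean variant keeps the
realized FDR at the nominal level. The median remains available through
`fdr_estimator = "median"`. The reported $\delta$ is the smallest grid value
(the grid being every achievable $|d_{(i)} - \bar d_{(i)}|$) whose estimated
FDR is at or below the 5% target, and each gene's q-value is the smallest
estimated FDR across the $\delta$ at which it is called. A numerical guard
of $10^{-8}$ (relative) at the cutoffs keeps the observed labelling — itself
one of the permutations — counted consistently regardless of floating-point
evaluation order.

Selection follows the study's rule: q at or below the target FDR **and**
linear fold change $2^{\bar x_{i,1} - \bar x_{i,2}} \ge 3$, the boundary
inclusive, up-regulated in FS. Flag filtering (a gene survives when flagged
on at most one array) and loess normalization against the gene-wise median
pseudo-sample precede the test; the one-color loess target is a design
choice, as is the smoother span of 0.4 (the correction must be slow against
the mean-intensity axis but follow array-wide distortions). Hierarchical
clustering of the selected genes uses $1 - r$ (Pearson) distance with
complete linkage; zero-variance profiles get the maximal distance 2 with a
warning, and rows are ordered lexicographically first so the dendrogram is
independent of input order.

# Co-expression networks and hubs

Link strength between two genes is Spearman's $\rho$ (midranks for ties) of
their expression profiles. The two networks share the node set — the
selected DE genes — but are computed from **each group's own samples**: the
FS network keeps links with $\rho \in [0.85, 1]$, the NFS network the band
$[0.14, 0.70]$. Group-specific sample subsets are the only reading under
which the two networks can differ while being "formed by the same genes",
and the distinct thresholds mirror the two correlation regimes of the
original analysis. Thresholding is on signed $\rho$ by default (the study's
intervals are nonnegative and silent on anticorrelation); `absolute = TRUE`
switches to $|\rho|$. Constant profiles yield undefined correlations,
reported as missing and excluded from edges with a warning.

Hubs are ranked by degree, ties broken lexicographically by gene id. The
link-strength histogram counts candidate pairs per $|\rho|$ bin of width
0.1, right-closed with the lowest bin including zero, so counts conserve the
number of defined pairs. Networks export as Cytoscape SIF (isolated nodes as
singleton lines) and GraphML with degree and $\rho$ attributes.

# GO themes

Overrepresentation of the DE set in each annotated term uses the upper-tail
hypergeometric probability with Benjamini–Hochberg adjustment at 5% FDR.
The background defaults to the annotated genes of the platform, the standard
choice for array enrichment; DE genes without annotation are dropped with a
warning, matching the original workflow in which only the GO-annotated
subset of the selected transcripts entered the functional analysis.

Theme proximity operates in the transcriptional expression space: each
significant theme's profile is the per-sample mean of its DE member genes,
and proximity is the Spearman correlation between theme profiles. Edges are
kept at or above a configurable threshold (default 0.5) and transcriptional
modules are the connected components of the thresholded graph, with
average-linkage clustering (cut at height $1-\text{threshold}$) as an
alternative: the original tool's internal decomposition is not documented,
so both readings are offered behind a flag. Modules are renumbered by first
appearance over sorted term ids, making the partition invariant to input
order.

# MRI texture pipeline

Preprocessing: a 3x3 median filter (reflect padding), background
segmentation by Otsu's threshold within the region of interest, and
z-normalization of the in-mask intensities. The whole image is normalized
with the in-mask statistics so windows near the mask boundary stay defined;
the normalization makes features invariant to affine intensity changes.
Gray levels for the co-occurrence and run-length families come from
equal-width quantization of the in-mask range into 64 levels (a standard
compromise between resolution and co-occurrence sparsity), with a 16-level
reduction for a second run-length variant.

Features are computed for every labelled in-mask pixel whose 9x9 window fits
the image (border pixels are skipped; no feature padding). The default bank
totals exactly 150 columns:

| family | composition | count |
|---|---|---|
| co-occurrence | 6 features x 4 distances, angle-averaged | 24 |
| co-occurrence | 6 features x 4 angles at distances 1–2 | 48 |
| run length | 5 features, direction-averaged, 64 and 16 levels | 10 |
| run length | 5 features x 4 directions, 64 levels | 20 |
| first order | mean, variance, entropy | 3 |
| Haar wavelet | 2 levels x 3 detail bands x {mean abs, energy} + approximation | 14 |
| fractal | differential box-counting slope and intercept | 2 |
| Markov random field | 4 neighbour parameters + residual variance | 5 |
| Gabor | 3 frequencies x 4 orientations x {mean magnitude, sd} | 24 |

The composition is a configuration contract (every block is overridable),
not a formula; 150 is the bank size the study reports.

Numerical choices worth knowing:

* **Co-occurrence matrices** are symmetric and normalized; correlation is
  defined as 0 when the marginal variance vanishes (constant window).
* **Run-length** features are short/long-run emphasis, gray-level and
  run-length non-uniformity, and run percentage, per direction and averaged.
* **Wavelet** subbands come from the orthonormal Haar transform with
  edge-replication padding at odd sizes; on even-sided windows the subband
  energies satisfy Parseval exactly. Inside the extractor the windowed
  transform is applied as a precomputed linear operator, which is
  bit-compatible with the direct per-window transform.
* **Fractal dimension** uses differential box counting at grid sizes 2, 3, 4
  with the intensity surface rescaled to the window's own range (hence
  offset invariance); the count is regressed on the per-side box count, so a
  flat surface gives exactly 2.
* **MRF parameters** regress each interior pixel on its symmetric neighbour
  sums (horizontal, vertical, two diagonals) with an intercept; the normal
  equations carry a $10^{-9}$-scaled ridge so perfectly striped or otherwise
  collinear windows stay defined and deterministic, and constant windows
  return zero parameters with a degenerate flag.
* **Gabor** kernels (7x7, $\sigma = 2$, zero-DC) are applied by whole-image
  FFT convolution; because every retained pixel's window contains the full
  support of its response neighbourhood, the global computation equals the
  literal per-window convolution to numerical tolerance.

Classification balances classes by seeded downsampling to the minority
count, then runs stratified 10-fold cross-validation of a random forest
(`ranger`, 100 trees, single-threaded, seeded). Both pooled out-of-fold
metrics and per-fold means are reported, since the study's wording ("mean
output of each turn") is ambiguous between the two; on balanced synthetic
data they coincide to three decimals. Cohen's kappa is
$(p_o - p_e)/(1 - p_e)$ on the pooled confusion matrix and the ROC AUC is
computed from out-of-fold class probabilities.

# Synthetic data: what it emulates, and what it does not

The expression generator produces log2-scale intensities with per-gene
baselines $\mathcal N(8, 1.5^2)$, residual noise $\sigma = 0.5$ (a typical
residual spread for log2 array data), 6 FS and 12 NFS samples, and 50
planted DE genes at 4-fold — comfortably past the 3-fold gate, as the
study's calls (all at or above 3-fold) were. Hub blocks add a shared latent
factor (loading 2.0, i.e. four times the noise scale, giving population
Spearman about 0.94) to block genes **within the FS samples only**, centred
across those samples: centring leaves the planted group-mean difference
untouched — the noise-free limit recovers the planted fold exactly, blocks
included — while preserving the co-variation that makes the FS network dense
at high $\rho$ and the NFS network sparse. What is *not* modelled: probe
effects, intensity-dependent bias (the normalization tests synthesize their
own distortions), correlated background genes, or any GO graph structure —
the annotation generator plants overrepresented terms directly, so
enrichment tests validate the statistics, not a biological annotation.

The texture generator produces oriented sinusoidal gratings (default: same
frequency and contrast, orientations 0 and 90 degrees, Gaussian pixel noise)
in a dark frame that Otsu segmentation removes, with per-pixel labels. Its
GLCM/Gabor signatures are analytically predictable, which the feature tests
exploit. It does not model MRI physics, scanner noise, partial-volume
effects, or hippocampal anatomy, so the pipeline's near-perfect accuracy on
gratings is a correctness check of the machinery, not a claim about the
printed real-data accuracies (90%/84%/90%), which require the original
scans and are out of scope.

The clinical table ships as a packaged CSV exactly as printed, including the
one footnote inconsistency (the MRI footnote marks 9 NFS rows while the text
reports 8); the fixture preserves the table and the package surfaces both
counts rather than resolving the discrepancy.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so the
full suite completes in a couple of minutes on one core: SAM oracle checks
on 3v3 and 4v4 toys with exhaustive permutations; a 100-replicate pure-null
simulation at 200 genes, 6v12; DE recovery at the generator defaults (1,000
genes); hub recovery over 50 seeded simulations with 50 FS samples (the
large-sample regime in which within-block sample correlations concentrate
above the 0.85 threshold); and a two-image texture run of roughly 28,000
labelled pixels through the full 150-feature bank and 10-fold forest.

# qPCR

Standard curves are ordinary least squares of Ct on $\log_{10}$ quantity;
efficiency is $10^{-1/\text{slope}}$, so a perfect doubling assay spaces
10-fold dilutions by $1/\log_{10} 2 \approx 3.32$ cycles. Unknowns are
averaged over triplicates before inversion (no outlier-replicate rejection),
normalized by the reference gene's quantity in the same sample, and
summarized as the FS/NFS ratio of group means. Samples lacking a reference
measurement are excluded with a warning. The fold change is invariant to a
global rescaling of quantities, so the standards' units are arbitrary.

# Known limitations

* The study's printed network figures (870/4,186 and 518/4,186 links, the
  Table 2 hub degrees, the Fig 3 module memberships) depend on the deposited
  array data and a 2010-era annotation; they are not reproducible from
  synthetic data and are deliberately not asserted anywhere.
* Sampled (non-exhaustive) permutations make q-values Monte-Carlo quantities
  at the study's 6v12 design; the stored seed makes them reproducible.
* The Mann–Whitney comparison of histology grades is validated on synthetic
  grades only, as the per-case grades are not printed numerically.
* Multi-class texture tasks report one-vs-rest AUC; the study's three tasks
  are treated as binary pixel labellings.
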