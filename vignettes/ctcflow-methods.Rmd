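---
title: "Models and methods behind ctcflow"
author: "ctcflow maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctcflow)
```

# Scope

`ctcflow` re-implements the software core of an integrated workflow for
detecting circulating tumor cells (CTCs) in peripheral blood after
negative enrichment: multi-channel immunofluorescence fields are
segmented and featurized, cells are identified by a definitional marker
gate combined with a supervised classifier battery, per-sample CTC and
circulating-tumor-microemboli (CTM) counts feed analytical-validation
and cohort-level statistics, and isolated single cells are profiled for
copy-number alterations (CNA) from low-pass binned read counts.

Everything upstream of images and bin counts — centrifugation and liquid
handling, staining chemistry, micromanipulation, whole-genome
amplification, read alignment — is out of scope; the package consumes
rendered fields and BED-like count tables, and ships a synthetic-data
module that generates every input it needs with known ground truth.

# The synthetic field model

`renderField()` draws a field as

$$I(x,y) = \mathrm{illum}(x,y)\,\Big(B + \sum_c A_c\,
  e^{-d_c^2 / 2\sigma_c^2}\Big) + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_\text{noise}^2),$$

with camera baseline $B = 500$, per-cell amplitudes $A_c$ drawn from
class- and channel-specific truncated normals, blob scale $\sigma_c =
r_c/2$ truncated at $3\sigma_c$ (so the nominal radius encloses
essentially all signal), a multiplicative low-order polynomial
illumination field normalized to mean 1, and 16-bit clamping. Defaults
emulate a high-content screener: leukocytes are DAPI+/CD45+ with CK at
background, tumor cells are larger and DAPI+/CK+/CD45−, debris is
small and dim in DAPI. Amplitude means (10,000–15,000 over a 500
baseline) and noise (SD 30) mimic a CCD's usable dynamic range with
well-stained cells; amplitude CVs near 17 % reflect realistic staining
variability.

Singleton cells are placed by rejection sampling with non-overlapping
$3\sigma$ footprints, which makes object counts and centroids exact
oracles for the segmentation tests. CTM clusters are deliberately the
exception: members are chained at 3/4 of the summed radii — overlapping,
but with individually resolvable nuclei — because real microemboli are
touching cell strings.

What the generator does *not* model: point-spread functions, spectral
bleed-through, autofluorescence, focus drift, tissue-like debris
morphology. Tests passing on these fields demonstrate the pipeline's
internal correctness and its behaviour under the stated noise model,
not performance on any particular instrument.

# Image pipeline

* **Illumination correction** divides each channel by a smooth
  background field estimated as a heavy Gaussian blur
  ($\sigma = \min(\text{dim})/8$) of the morphologically opened image,
  then rescales to preserve the global median. Two numerical choices
  matter: the blur uses *normalized convolution* (zero padding divided
  by the blurred support) so local averages are unbiased at field
  borders, and it is evaluated on a block-mean downsampled grid
  (roughly $\sigma/16$) and bilinearly upsampled — the background is
  smooth by construction, and this keeps large fields cheap. Flat
  images pass through exactly; the operation is idempotent to well
  under 1 % at the default gradient amplitude.
* **Denoising** is an exact 3×3 median (a C sorting network; larger odd
  kernels delegate to `EBImage::medianFilter`).
* **Otsu thresholding** maximizes between-class variance over a 256-bin
  histogram regardless of bit depth, ties broken toward the smallest
  threshold for reproducibility. Segmentation floors the threshold at a
  robust background level (median + 5 MAD) so a featureless field yields
  zero objects instead of split noise.
* **Segmentation** runs on DAPI only — the cell definition is
  "nucleated" — with hole filling and 8-connected labelling
  (`EBImage::bwlabel` is 4-connected; a diagonal union-find pass merges
  the rest). Touching nuclei are *not* watershed-split: multi-nucleated
  objects are CTM evidence, counted via local maxima of the smoothed
  DAPI signal (maxima closer than 3 px merge). Border objects are
  flagged, not dropped.
* **Features** (~25 per object): area, perimeter (marching-squares
  contour length with Vossepoel–Smeulders-style segment weights, which
  debiases the digital staircase; a digital disk scores form factor
  ≈ 0.94), equivalent diameter, eccentricity from second moments,
  solidity against the convex hull of boundary pixels, and per channel
  the mean/median/max/integrated intensity plus a local background
  (median of a 2–5 px annulus assigned per object by grayscale label
  dilation, excluding all object pixels), the background-corrected mean
  and the fold-over-background used by the gate. This is a deliberate
  reduction from the "hundreds of features" a full profiler extracts;
  it spans the two families that matter here (marker expression,
  morphology) and is sufficient for the classifier protocol.
* **Debris filtering** applies configurable bounds (default area
  30–700 µm², solidity ≥ 0.7, DAPI fold ≥ 2) and partitions its input
  exactly.

# Gating and the classifier battery

The operational CTC definition is a hard gate: DAPI+ (fold ≥ 2 over
local background), CK/EpCAM+ (fold ≥ 2), CD45− (fold < 3) and intact
(solidity and area bounds). The CD45 cut of 3 sits between residual
tumor-cell spillover (< 2.6× background under the default population)
and genuine leukocyte expression (> 3.4×). DAPI+/CD45+ cells are
labelled leukocytes regardless of CK (cytokeratin-positive leukocytes
are a known artifact).

Five classifier families — stochastic gradient boosting (GBM), AdaBoost
classification trees, radial SVM, random forest, extreme gradient
boosting (XGB) — are trained on a stratified 75/25 split with 10-fold
cross-validated selection over small fixed grids. RF, SVM and XGB are
fitted by `randomForest`, `e1071` and `xgboost`; GBM (logistic-loss
gradient boosting with bagged shallow `rpart` trees, Friedman-style)
and AdaBoost.M1 (weighted `rpart` stumps) are implemented in-package.
SVM probabilities are a logistic squash of the signed decision value —
deterministic and rank-identical to the margin. The gate acts as a veto
over the model score (the definition is definitional; the model only
narrows candidates), and a review table can flip final labels — the
pathologist-confirmation hook. Class imbalance is handled by
stratification only; the decision threshold defaults to 0.5 and is
exposed.

The synthetic labeled population (`sampleFeatureTable()`) draws features
as class-conditional Gaussians on log (intensities, area) and logit
(shape) scales, truncated at ±3 within-class SDs per coordinate —
staining intensities and shape scores are physically bounded — so at the
default separation of 6 CK-SDs the class supports do not overlap and the
Bayes error is exactly zero. That choice is what licenses the strong
expectations the tests place on held-out performance (AUC ≥ 0.99 for
every family, recall ≈ 1 for XGB): with unbounded tails, rare
single-coordinate outliers land inside the opposite class's territory
for axis-splitting tree ensembles (which split at observed data values,
not at gap midpoints) and held-out recall dips to ~0.99 on a few seeds
even though the population is Bayes-separable.

# Enumeration and cohort statistics

`enumerateSample()` counts every nucleus of gated-and-classified CTC
objects (a tri-nucleated cluster object contributes 3) and counts CTM as
*clusters*: each multi-nucleated CTC object is one CTM, and singleton
CTCs whose centroids fall within one mean cell diameter of each other
form connected components, each component of ≥ 2 counting once. Counts
are reported per 5 mL of blood.

Analytical validation uses the exact definitions: recovery rate
`recovered/spiked × 100` (> 100 % allowed with a warning), %CV as
`100·sd/mean` with the sample SD. Diagnostics: positivity at count ≥ 1,
sensitivity/specificity at a count threshold with exact binomial CIs,
ROC AUC as the Mann–Whitney probability with ties counted ½ (DeLong or
bootstrap CI), and a Youden-J "optimal" threshold — the source platform
never states its optimality criterion, so Youden is this package's
documented choice. Group comparisons dispatch to the standard tests;
the 2×2 chi-squared uses a continuity correction by default (the
printed vascular-invasion p of 0.001 reproduces only with it), and an
all-ties paired Wilcoxon returns p = 1 by convention. Recurrence uses
the Kaplan–Meier product-limit estimator with the log-rank test; median
time-to-recurrence is the first time the curve reaches 0.5, `NA` when
never reached.

The simulated cohort draws zero-inflated negative-binomial CTC counts
and exponential recurrence times with uniform censoring. The default
HCC group (π = 0.15, µ = 1.6118, k = 2.1) matches the two calibrated
moments exactly — 59.3 % positivity and mean 1.37 per 5 mL in closed
form (`zinbPositivity()`) — but those two constraints cap the
attainable count SD near 1.7 within the ZINB family, below the heavier
spread real cohorts show (~2.0); the SD is deliberately left
uncalibrated. Healthy donors are calibrated to 0.8 % positivity; benign
liver-disease groups sit between.

# Copy-number profiling

Input is a BED-like table of fixed-width bins (0-based half-open) with
GC fraction and raw counts; alignment is upstream and out of scope.
Library QC is the strict rule: a locus passes iff it amplified at the
expected melting temperature with Ct < 30, and a library is sequenced
iff ≥ 8 of its 12 control loci pass.

Normalization scales counts to mean 1 and divides out a lowess GC
response fitted on putatively copy-neutral bins (ratio within a factor
2 of the median), applied only when a quadratic GC term is
statistically present (p < 0.01) — on GC-flat toy-scale profiles (~180
bins) an unconditional smoother re-injects its own fitting noise and
costs several percent of downstream calling accuracy.

Segmentation is per-chromosome penalized changepoint detection on log2
ratios: *exact* optimal partitioning (an O(n²) dynamic program —
chromosomes hold at most a few hundred bins) under a per-breakpoint
penalty `2·σ²·log n`, with σ estimated robustly from successive
differences. Greedy binary splitting, the more common shortcut, commits
to poor first cuts at the low SNR of 100-read bins; the exact optimum
does not. Isolated outlier bins are shrunk toward a running median
before segmentation, and splits whose flanking means differ by fewer
than 3 standard errors are undone (selection inflates the apparent
shift of short noise runs). Integer calling recenters segment ratios on
the median bin — the near-diploid baseline assumption — before rounding
to `round(ploidy · ratio)`, clamped at zero; with plain mean-1 scaling
on an aneuploid genome, gains inflate the mean and push a CN-4 segment
to a scaled value of ~3.7, a knife-edge rounding margin. An optional
bin-weighted ploidy grid search replaces the recentering for genomes
where "most bins are neutral" fails (off by default for a deterministic
default path).

Coverage quality follows the standard uniformity metrics: index of
dispersion (variance/mean; 1 for Poisson), the Lorenz curve of
cumulative count share with its Gini coefficient, and a count
histogram. Profile concordance is Pearson r over shared bins on integer
CN (configurable to log2 ratios — which scale the original comparison
used is not stated). Driver annotation is a half-open interval join of
a user-supplied gene BED against non-neutral segments; a
boundary-spanning gene is assigned its maximal-overlap segment, ties to
the higher copy number.

## Attainable accuracy at the default noise

The default simulator draws NB counts with size 10 (variance
µ + µ²/10, a 33 % CV at the default 100 reads/bin) over a miniature
3×30 Mb genome in 500 kb bins whose truth contains CN 0–4 events of
6–20 bins. At that noise an *oracle* given the true segment boundaries
recovers 97.2 % of bins over 20 seeds — 20-bin CN-3/CN-4 segments flip
by rounding with probability ~8 % each — and the blind pipeline reaches
~93 %, with single-cell-versus-truth r averaging ~0.95. The package's
acceptance suite keeps the literal ≥ 95 % / r ≥ 0.95 bars and reports
them honestly; the module tests assert what the implementation can
guarantee: recovery within 0.05 of the oracle bound, monotone
degradation with depth, and the partition/positivity invariants. At
milder dispersion (size ≥ 20) both bars clear comfortably.

# Problem sizes and determinism

Every stochastic function takes a seed and restores the caller's RNG
state; identical spec + seed is bit-identical output. The shipped
experiment sizes are chosen for a desk-scale reproduction: the
classifier benchmark uses n = 4,000 cells at 10 % prevalence; the
limit-of-detection analogue screens 10,000 leukocyte-like cells plus
exactly one tumor cell per replicate, rendered as four 1024² fields at
1.3 µm/pixel, for 20 replicates; copy-number experiments use 180 bins
across three toy chromosomes. `scripts/acceptance.R` re-runs the
classifier benchmark and the detection experiment from scratch under a
caller-supplied seed.

# Known limitations

* The feature set is ~25 engineered features, not a full profiler's
  hundreds; enough for the protocol, not a drop-in CellProfiler
  replacement.
* The marker gate's fold thresholds and the debris-filter bounds are
  placeholders calibrated to the synthetic optics; real deployments
  must tune them on annotated data.
* CTM counting depends on an adjacency radius (default one mean cell
  diameter) because no operational microemboli definition is published.
* Copy-number calling assumes a near-diploid baseline by default; use
  the ploidy grid search for heavily aneuploid cells.
* The combined CTC + AFP logistic diagnosis is a reconstruction of a
  described analysis, not a validated clinical model, and is therefore
  not part of the package's acceptance surface.
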