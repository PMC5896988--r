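---
title: "Quantifying germ-cell proliferation and apoptosis in testis sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germ-cell proliferation and apoptosis in testis sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germquant)
```

## The measurement problem

During the first wave of mouse spermatogenesis, germ-cell loss phenotypes
(such as the Sertoli cell-only testis produced by germline deletion of
*Uxt*) have to be separated into their possible causes: failed
proliferation, apoptosis, or failed differentiation. Two kinds of
quantification support that dissection:

* **Dual-channel immunofluorescence.** Sections are co-stained for TRA98
  (a nuclear antigen of germ cells, imaged in green) and KI-67 (a nuclear
  protein expressed in cycling cells and absent in G~0~, imaged in red).
  The fraction of germ-cell nuclei positive for KI-67 estimates the
  fraction of germ cells that have entered the cell cycle. Because KI-67
  also labels cycling somatic cells, red signal may only be measured
  inside TRA98-positive nuclei.
* **Manual counts on immunohistochemistry.** Positive cells per
  seminiferous-tubule cross-section (for markers such as PLZF, C-KIT,
  STRA8), and the frequency of tubules containing at least one cleaved
  caspase-3-positive (apoptotic) cell. These produce per-tubule count
  tables and per-replicate frequency tables that are compared across
  genotypes with unpaired Student's t-tests and chi-square tests.

`germquant` implements both computations, together with a seeded synthetic
image generator that provides exact ground truth, so every stage of the
image pipeline is testable without access to micrographs.

## The image pipeline

### Segmentation of germ-cell nuclei

1. **Otsu threshold** on the green channel. For a 256-bin intensity
   histogram with class probabilities $\omega_0(t) = P(I \le t)$ and
   $\omega_1(t) = 1 - \omega_0(t)$ and class means $\mu_0(t), \mu_1(t)$,
   the threshold maximizes the between-class variance
   $\sigma_b^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2$.
   Foreground is *strictly greater* than the threshold, so a constant
   image yields an empty foreground; when several thresholds tie, the
   smallest maximizer is returned. Both choices make the operation
   deterministic and testable against an exhaustive 256-threshold sweep.
2. **Border removal.** Every 8-connected foreground component touching
   the first or last row or column is discarded: a truncated nucleus
   would bias area, axis, and intensity measures.
3. **Watershed separation.** Touching nuclei are split by marker-based
   watershed on the negated Euclidean distance transform of the mask.
   Markers are local maxima of the distance transform; the
   `min_marker_sep` parameter (default 7.5 px, 1.5 times the smallest
   simulated semi-axis) sets the neighborhood radius within which only one
   marker survives, preventing an elongated nucleus from being split by
   the secondary maxima of its own ridge. The watershed labels partition
   the foreground exactly: no pixel is lost or duplicated.
4. **Minimum-area filter** (default 15 px) drops speckle regions that
   survive thresholding in noisy images; set it to 0 for exact
   truth-recovery experiments.

The distance transform, watershed flooding and base component labeling
come from Bioconductor's EBImage; 8-connectivity is obtained by merging
diagonally adjacent 4-components.

### Per-nucleus KI-67 measures

For each segmented nucleus, six measures are computed **over exactly the
labeled pixels** of the red channel: area, maximum red intensity, sum of
red intensities, mean red intensity, major-axis length, and coverage
fraction. The major axis is the standard morphometric convention — the
ellipse with the same normalized second central moments as the region,
length $4\sqrt{\lambda_{\max}}$ of the population covariance of pixel
centers (a single pixel therefore has length 0; no quantization
correction is added). Coverage is the fraction of nuclear pixels whose
red intensity strictly exceeds a *global* Otsu threshold of the red
raster: one threshold per field, not per nucleus, so that a dim nucleus
cannot manufacture its own permissive cutoff. Area is reported in pixels;
classification is scale-consistent within a dataset, so calibration to
microns is unnecessary.

### Classification

KI-67(+) vs KI-67(−) calls come from a logistic regression over all six
measures. Manually labeled nuclei are split by a seeded, stratified
`split_plan()` whose defaults are a 96-cell balanced training set
(48/48), a 42-cell balanced test set (21/21), and an 88-cell all-positive
second test set; an inventory that cannot supply the requested counts is
an error, never silently shrunk. Features are standardized to center 0
and (population) spread 1 on the training set, and the fit uses
iteratively reweighted least squares with a small ridge penalty
(`penalty = 1e-3` per training observation, intercept unpenalized).
The penalty keeps the optimum finite when classes are linearly separable
— the common case for clean fluorescence — while being numerically
negligible otherwise (the fit agrees with `glm()` to five decimals on
overlapping classes). Scaling the penalty per observation makes the fit
exactly invariant under duplicating the training set. The decision rule
is `probability >= 0.5`, with the boundary resolved deterministically to
"positive"; accuracies are displayed with half-away-from-zero rounding to
two decimals.

### Aggregation and comparison

Per-field counts are summed per animal and the percent positive is
recomputed from pooled counts — never the mean of field percentages,
which would weight small fields as heavily as large ones. Genotypes are
compared by an uncorrected Pearson chi-square on the pooled 2x2
positive/negative table. Replicates with fewer than three fields trigger
a warning, mirroring the convention of at least three non-overlapping
fields per section and 400–2600 nuclei per animal.

## The synthetic-data generator

`generate_field()` renders elliptical nuclei into two 8-bit channels and
records exactly what it rendered. Design points:

* **Nuclei are ellipses**, semi-axes uniform in 5–10 px at the default
  512 x 512 field (10–20 px diameters, matching nuclei at 20x
  magnification with a typical camera). Placement is rejection sampling
  with a conservative center-distance test and a retry cap; an
  overcrowded specification errors rather than silently overlapping.
* **Somatic nuclei receive red signal but (by default) no green**, so the
  restriction of feature extraction to the germ mask is testable: corrupt
  the red channel outside the mask and no feature may change.
* **Touching pairs** (default probability 0.05) are placed in deliberate
  contact for the watershed to separate; **edge nuclei** (default 0.1)
  cross the border for the edge filter to remove. Ground truth records
  border contact from the rendered pixels, not the intended placement.
* **Red paint** covers a contiguous random sub-region of each nucleus
  whose pixel count matches the drawn coverage: 0.40–0.90 of the nuclear
  area for KI-67-positive cells, 0–0.08 for negative cells. Paint
  intensity is 170–230 (positive) vs 120–160 (negative) on a background
  of 8. The two paint ranges are deliberately clustered with a small gap:
  the global red Otsu threshold then falls between background and paint
  (about 26), so *all* rendered paint is detectable and the measured
  coverage estimates the truth coverage to within pixel quantization. If
  negative paint were rendered much dimmer, the red threshold would land
  inside the paint modes and the truth `coverage` field would no longer
  be the quantity the coverage measure estimates.
* **Noise** is additive Gaussian (default sd 4), rounded and clipped to
  [0, 255]. An 8-bit depth is assumed throughout. Poisson shot noise,
  illumination gradients, point-spread blur, tissue architecture (lumens,
  Sertoli cytoplasm), and 3-D structure are deliberately not modeled.
* **Determinism**: one master seed is split deterministically per field,
  so identical `(spec, seed)` input gives bit-identical rasters and
  truth.

Passing the synthetic-recovery tests therefore shows that the pipeline's
logic is correct under idealized imaging; it does not certify performance
on real sections, where focus, staining variability and optics dominate.

`generate_tubule_table()` likewise emulates manual counting: per-tubule
positives are Poisson, and a configurable fraction of sections are
oblique with lengths drawn in circular-diameter units.

## Counting statistics

* **Oblique sections**: one circular-tubule diameter of measured length
  counts as one tubule; partial diameters floor, with a minimum of one —
  an observed section cannot count zero times. Floor-with-minimum is the
  conservative deterministic reading of the diameter-equivalent rule.
* **Per-tubule means** average circular cross-sections (warning below 40
  sections); oblique sections can optionally contribute with their
  diameter-equivalent weight.
* **Frequency pooling** sums numerators and denominators across
  replicates; percentages display at two decimals, half-away-from-zero.
  On the bundled reference table (`caspase3_frequencies()`) the pooled
  percentages are 3.77/5.00 (5dpp), 8.25/11.85 (6dpp) and 11.65/18.22
  (7dpp) for WT/KO, and the pooled chi-squares give p = 0.450, 0.095 and
  0.0014: only the 7dpp difference is significant.
* **Tests**: unpaired equal-variance Student's t (two-tailed, pooled
  variance, `df = nA + nB - 2`); Pearson chi-square without continuity
  correction (a `correct` flag exposes Yates); goodness of fit uses
  `sum((O - E)^2 / E)` with the expected counts taken *as given* — they
  are not rescaled to the observed total, which matters when expecteds
  come from an external segregation model. On the bundled cross counts
  (`mendelian_cross_counts()`) the statistic is 1203/15.5 = 77.61 on 3
  degrees of freedom.

## Numerical and design choices

* Pixel coordinates are R-native: 1-based, row/column, origin at the
  top-left pixel. Truth tables, centroids and CSVs all share this
  convention.
* 8-connectivity throughout for foreground components; watershed regions
  are connected by construction.
* The red threshold is global per field (see above); coverage uses the
  same strict inequality as binarization.
* Problem sizes in the test-suite recovery experiments: 320 x 320 or
  512 x 512 fields, 40–140 nuclei per field, 20 seeds for recovery
  checks, 20 three-field replicates for the bias check, 2000 simulations
  for chi-square calibration. These sizes give Monte-Carlo errors well
  below the asserted tolerances while keeping the suite quick.

## Known limitations

* When a touching pair of discordant nuclei (one positive, one negative)
  is merged by an imperfect watershed split, the merged region's pooled
  coverage tends to fall on the positive side of the decision boundary.
  Under default conditions this inflates the pooled percent positive by
  well under one percentage point (the recovery-bias metric in the
  acceptance script measures it directly), but it is a real, directional
  effect.
* The chi-square comparisons are asymptotic; with pooled counts in the
  hundreds this is unproblematic (the type-I calibration metric confirms
  a rejection rate near 0.05), but very sparse tables would need an
  exact test, which the package does not provide.
* The classifier is a single logistic regression by design; no
  cross-validation, calibration or alternative models are included.
* The generator's idealizations listed above bound what synthetic
  validation can claim about real micrographs.
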