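---
title: "Nuclear morphometry and nested model selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and nested model selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomorph)
```

`nucleomorph` classifies thyroid tumors into PTC-like and non-PTC-like from
H&E tiles by a three-stage pipeline: nucleus instance masks (supplied, or a
watershed baseline for synthetic data) are post-processed by a per-image
median-area filter; each surviving nucleus is described by 36 morphometric
features; features are pooled per patient and a classifier is chosen by
stratified nested cross-validation. This vignette records the model, its
assumptions, and every numerically consequential design choice.

## Conventions and assumptions

Images are 8-bit RGB arrays (H × W × 3, intensities 0–255); label maps are
integer matrices with 0 background. All coordinates are row-major, 0-based
pixel indices, and centroids are real-valued (row, col) pairs — one
convention everywhere avoids off-by-one errors in the crowding radii. The
pipeline assumes a working resolution of 0.23 µm/px (a 40× acquisition);
`harmonize_resolution()` rescales manifests declared at other resolutions by
the ratio with cubic-spline interpolation (nearest-neighbour for label maps)
before anything downstream runs, because morphometry in pixel units is only
comparable across images at one resolution. Rescaled intensities are clipped
to [0, 255] and rounded back to 8-bit; whether the original workflow clipped
or re-quantized is not documented anywhere we could find, and rounding back
to the input depth is the conservative choice.

## Segmentation post-processing

The median instance area *m* is computed **once per image** over the
pre-filter population; every instance with area > 2*m* or area < 0.5*m* is
removed. Both inequalities are strict, so an instance at exactly 200% or 50%
of the median survives; "larger than"/"smaller than" is read literally.
Because *m* is frozen before any removal, re-running the filter on its own
output removes nothing further. Border-touching nuclei are *not* removed by
default — the size rule is the intended mechanism for partially visible
nuclei — but `filter_by_size(..., drop_border = TRUE)` exists for users who
want the stricter behavior. With an even instance count the median is the
mean of the two middle areas.

The bundled `segment_baseline()` (grayscale → Otsu threshold → hole filling
→ distance transform → marker watershed, specks under 15 px discarded) is
plumbing for the synthetic fixtures: it is deterministic and adequate for
ellipse-like synthetic nuclei, and it is not claimed adequate for real H&E,
where a trained instance segmenter should supply the label maps.

## The 36 features

**Color (23).** Channel means and population standard deviations over the
masked pixels for red, green, blue, and ITU-R 709 luminance
(0.2125 R + 0.7154 G + 0.0721 B, kept real-valued). Ring-zone ratios
partition the mask into border, middle, and center zones of equal pixel
count (±1) by tertiles of the Euclidean distance-to-boundary transform; ties
are broken by sorting on (distance, row, col), so the partition is
deterministic; the per-channel ratios are border/middle and border/center,
`NA` when the denominator zone has zero mean or when the mask has fewer than
3 pixels. A pale center (chromatin clearing) drives border/center above 1 in
the hematoxylin-dominated channels. GLCM texture uses distance 1 px, the
four principal directions averaged, 256 gray levels, symmetric and
normalized matrices; pairs that touch an out-of-mask pixel are discarded so
background texture never contaminates a nucleus. On a single-valued crop the
correlation denominator vanishes and the feature is defined as 0 (the
no-linear-structure value). Entropy is base-2 over the 256-bin masked
histogram. All GLCM parameters are the common defaults and configurable in
code.

**Shape (4).** Area is the mask pixel count. The perimeter is the
contour-weighted estimator of Benkrid & Crookes (border pixels coded by a
3 × 3 neighbourhood convolution; weights 1, √2, (1+√2)/2), which is unbiased
enough on digital disks that a radius-10 disk measures within a few percent
of 2πr. Eccentricity comes from the ellipse with matched second central
moments (0 for a disk; a degenerate one-pixel mask gives 0 by convention).
Solidity is mask area over convex-hull pixel area, where hull membership is
evaluated for pixel centers with boundary points included; masks with fewer
than three pixels get solidity 1.

**Spatial (9).** The image's mean equivalent-disk radius
r_mean = (1/n) Σ √(Aₖ/π) is computed from the **post-filter** nuclei of that
image — "the image" is the aggregation unit because crowding is a local
density property of the visible field, and using a per-patient radius would
mix magnifications of biology across tiles. Crowding counts other nuclei
with centroid distance ≤ x · r_mean (inclusive boundary, self excluded) for
x ∈ {3, 5, 7, 9, 15, 20, 25, 30}; no edge correction is applied, which
matches the intended use on tiles that are large relative to r_mean (on
small crops the counts near borders are biased low, a known limitation).
`nn_distance` is `NA` on single-nucleus images and that `NA` is excluded
per-feature at aggregation.

## Aggregation

Nuclei of all images of a patient are pooled into a single sample before
taking the mean and the **population** standard deviation (divide by n) of
each feature: pooling across images weights every nucleus equally, whereas
averaging per image first would up-weight sparse images — the two differ
whenever image nucleus counts differ, which the test suite demonstrates with
a hand-computed counterexample. Population normalization keeps the standard
deviation defined (0) for a single-nucleus patient; a sample sd would be
`NA` there. Patients with zero nuclei are dropped with a warning; `n_nuclei`
is carried as metadata and is never one of the 72 classifier inputs.

## Preprocessing, selection, classification

The quantile transform maps each feature through the training fold's
empirical CDF to a uniform target (at most 1000 quantiles, linear
interpolation between them, clamped at the training range); standard scaling
centers and scales with training-fold statistics, with a zero-variance
feature centered only. Application order is quantile → scale, and every
statistic is fitted on the outer-training portion alone.

χ² selection uses the non-negative-count form of the statistic (class-wise
feature sums vs. expectation under class priors). Because standard scaling
produces negatives, the χ² scores are computed on a non-negative *view* of
the training fold — the quantile-transformed values when that step is
enabled, otherwise a training-fold min–max map to [0, 1] — while the
classifier still sees the configured preprocessing. Sequential forward
selection greedily adds the feature that maximizes the base classifier's
cross-validated accuracy; ties (in selection and in the hyperparameter grid)
are broken by canonical feature/grid order so every run is reproducible.

Six classifiers are wrapped behind one interface (SVC via `e1071`, a
hand-rolled distance-weighted KNN, Gaussian naive Bayes via `e1071` with a
1e-9 variance floor, `rpart` decision trees, ridge logistic regression via
`glmnet` with λ = 1/(C·n) mapping the conventional C grid, and `ranger`
random forests). Decision scores are oriented so larger = more PTC-like:
signed SVM decision values, class-1 probabilities elsewhere. The shipped
hyperparameter grids are deliberately modest, representative stand-ins — the
binding contract is the nested-CV mechanics, not grid contents — and every
grid is overridable in `pipeline_config()`.

Nested CV uses 5 stratified outer folds and 4 stratified inner folds
(patients shuffled within class and dealt cyclically, so every fold's class
counts are within one patient of proportional). Only classifier
hyperparameters are tuned inside; preprocessing, selector, and classifier
choice are fixed per configuration, accepting the documented trade-off that
comparing configurations happens *across* runs. `baseline_config()` is the
optimization-disabled reference: SVC with library defaults, scaling only,
no selection, and — under the same seed — outer folds identical to any tuned
run, so the two are directly comparable. One top-level seed derives all fold
and model seeds through a splitmix-style integer hash, keeping streams
independent and every derived seed under 2³¹.

Metrics follow the standard definitions (Cohen's κ = (p₀ − pₑ)/(1 − pₑ);
trapezoid AUC over the score-swept ROC; κ and AUC are `NA` when only one
class is observed). `majority_vote()` implements the pessimistic tie rule
for multi-image cases: an exact 50–50 split returns the class opposite to
the truth, so ties never flatter the classifier.

## Expert-agreement analysis

The per-case rating cᵢ = max(cᵢⁿ, cᵢᵖ)/(cᵢⁿ + cᵢᵖ) is symmetric in the two
counts and lies in [0.5, 1]. Label derivation: re-reviewed cases are
thresholded at <13 (non-PTC-like) and >15 (PTC-like) positive re-review
scores with the closed interval 13–15 excluded — the published rule names
only the endpoints 13 and 15, and excluding the full interval is the only
reading under which a hypothetical count of 14 is defined; other cases take
the majority vote, with exact ties excluded. Threshold evaluation uses the
inclusive comparison cᵢ ≥ t, matching the "equal or greater" usage in the
source analyses; subsets are therefore nested and their sizes non-increasing
in t. Distribution accuracy — max class fraction of the subset — is the
floor any classifier must beat there. Percentages are reported to one
decimal, round-half-up.

## The synthetic generator

Nuclei are area-preserving ellipses (axis ratio uniform in a preset range)
whose boundary radius is modulated by harmonics 2–6 with total relative
amplitude `boundary_irregularity`; low-order harmonics produce the lobulated
outlines that depress solidity and raise perimeter the way irregular nuclear
membranes do. Intensity is a hematoxylin-purple base color brightened toward
the centroid by the `center_clearing` factor (≥1), emulating chromatin
clearing; Gaussian noise (sd 6 intensity units) is added on an eosin-pink
background. Placement is a clustered point process (cluster membership with
probability `cluster_intensity`, positions dispersed around cluster centers,
minimum centroid spacing 1.9 r_mean); later nuclei occlude earlier ones on
contested pixels and the ground-truth label map records the visible region.
Panel votes are beta-binomial: a per-case rater probability is drawn around
`vote_prob` = 0.85 with concentration 30 — chosen so most synthetic panels
are decisive while a minority land near the tie region, emulating borderline
cases — and as the concentration and panel size grow every cᵢ converges to
max(p, 1 − p).

The class presets are the study conditions: PTC-like nuclei have 1.5× the
mean radius (10.5 vs 7 px at 0.23 µm/px, i.e. ≈2.4 vs 1.6 µm — the low end
of real nuclear radii, keeping images small), boundary irregularity 0.22 vs
0.05, and center clearing 1.6 vs 1.1. These margins are ≥2 within-class
standard deviations on area and solidity, so the end-to-end recovery check
expects near-perfect classification; with identical presets for both classes
the pipeline must fall back to chance. What the generator does **not**
emulate: stain variation, scanner artifacts, out-of-focus regions, stromal
texture, overlapping nuclei chains, or the long-tailed morphology of real
tumors. Passing the synthetic recovery test therefore demonstrates that the
pipeline's plumbing is correct and leak-free — not that the feature set
reaches any particular accuracy on clinical cohorts.

## Problem sizes and runtime choices

The shipped checks run on deliberately desk-scale problems: 128 × 128 px
tiles with 12–18 nuclei, 2 images per patient, 40 patients for the
end-to-end recovery run, 20 label permutations for the null check, and an
SVC grid of 24 combinations. These sizes keep the whole suite in tens of
seconds while leaving every code path (watershed splitting, size filtering,
ring tertiles, GLCM masking, inner-loop tuning) exercised; all of them scale
up through `generator_config()` and `pipeline_config()` without code
changes.

One empirical subtlety the null checks respect: cross-validated permutation
nulls on *cluster-structured* features center below chance, because a
cluster's training-fold label majority is anti-correlated with its held-out
remainder (finite-population sampling). The suite therefore checks
two-sided chance agreement on signal-free features, and one-sided
no-fabricated-skill on the structured pipeline output.

## Known limitations

- The baseline segmenter is for fixtures; real H&E needs a trained instance
  segmenter upstream.
- Crowding has no border correction; small tiles bias it low.
- The exact composition of the 23 color features reconstructs the published
  ingredient list (channel statistics, ring ratios, GLCM properties,
  entropy); the 23/4/9 counts and the canonical order in
  `nucleus_feature_names()` are the binding contract.
- Hyperparameter grids are representative stand-ins, not a reproduction of
  any specific study's supplementary grids.
- Aggregation keeps only mean and standard deviation; higher moments of the
  per-patient feature distributions are deliberately out of scope.
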