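---
title: "Quantitative tissue-map analysis for NSCLC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative tissue-map analysis for NSCLC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemaps)
```

## What this package computes

Modern segmentation models for non-small cell lung cancer (NSCLC) produce
pixel-wise tissue maps of whole-slide images: every pixel of an H&E scan is
assigned to one of eleven tissue classes (epithelial tumor, tumor stroma,
necrotic debris, mucin, tertiary lymphoid structures, benign lung
parenchyma, non-tumor stroma, bronchial mucosa, blood, peribronchial
glands, cartilage) or to slide background. `tissuemaps` is the
quantification layer that turns such label rasters into clinically
interpretable numbers:

* exact per-class area profiles of a slide or region;
* per-class Dice agreement against annotated ground truth;
* LUAD-vs-LUSC subtype calls from area percentages inside the tumor,
  with a borderline zone and a mucin fraction;
* four explainable prognostic parameters — TLS tumor density (TLS-TD),
  necrosis tumor density (NECR-TD), their ratio (T/NR), and a cumulative
  three-level prognostic group (T+NR, PG1–PG3) — together with
  optimal-cutpoint survival stratification (Kaplan–Meier, log-rank, Cox).

The trained neural segmenter itself is out of scope: the package treats the
segmenter as a pluggable callable and ships two deterministic stand-ins so
the whole harness can be exercised and tested end to end. A synthetic
mask-and-cohort generator with known ground truth makes every stage
testable at desk scale.

## The data model

A `tissue_mask` is an integer label raster plus a `class_legend` (class id,
name, group) and a resolution in microns per pixel (MPP). The platform
geometry assumes inference at MPP 1.0 — roughly 10x magnification — with
512 px tiles; both are configurable. Legends require ids contiguous from 0
and exactly one background class, so raster validation is a range check.
The legend's `group` column partitions classes into the *tumor region*
(epithelial tumor, tumor stroma, necrosis, mucin), *benign* tissue and
*background*; background is excluded from every density denominator.

At annotation time a finer 14-class scheme is used in which the connective
compartment is split into connective stroma, fat, muscle and vessels;
`merge_connective_classes()` collapses these four into the single STROMA
class and reproduces the 11-class scheme used everywhere else.

## Tiling and stitching

`plan_grid()` covers a raster with non-overlapping tiles of at most 512 px
per side; edge tiles are ragged rather than padded. `run_inference()`
applies the segmenter per tile and places the outputs verbatim — no
post-filtering, smoothing or morphological cleanup after stitching. For any
deterministic per-pixel segmenter, tiled application is therefore
bit-identical to whole-image application, and the tests assert exactly
that. An optional overlap-and-center-crop mode exists for segmenters with
receptive fields, but it is off by default because the default contract is
the simplest behavior consistent with no inference-time post-processing.
Label rasters are rescaled between resolutions with nearest-neighbor
sampling only; any interpolation would fabricate class ids.

## Dice evaluation

`dice_scores()` computes, per class, `2|T∩P| / (|T|+|P|)` between truth and
prediction, optionally restricted to an annotated region so unannotated
pixels can never influence a score. A class absent from both masks has no
defined Dice and is reported `NA` — not 0 and not 1 — and is excluded from
the macro average; scoring absent classes 1.0 would inflate averages on
sparsely annotated validation sets. Because "overall" can also be read
pixel-pooled, `glance()` reports both `macro_dice` (mean over defined
classes) and `pooled_dice` (micro average `2ΣI / Σ(T+P)`).

## Subtyping from area percentages

The subtype model assigns LUAD/LUSC labels only inside pixels the main mask
calls epithelial tumor; `classify_slide()` therefore tallies
`pct_luad = 100·|LUAD| / (|LUAD|+|LUSC|)` over that support and calls the
argmax. Subtype labels falling outside the tumor support are ignored, never
reassigned. Slides whose winning percentage lies in the closed interval
[40%, 60%] are flagged borderline — in practice poorly differentiated
tumors that need immunohistochemistry — and an exact 50/50 tie is called
LUAD with a warning plus the borderline flag, a deterministic rule whose
only job is to route such slides to human review. Case-level calls pool raw
pixel counts across slides (area weighting) rather than averaging slide
percentages, which makes the case call invariant to how the tumor was split
across blocks. The mucin fraction
`100·mucin / (mucin + tumor + tumor stroma)` is tallied from the subtype
labels within the main mask's tumor region and reported without a
diagnostic threshold.

## Prognostic parameters

Tissue objects are connected components of the TLS or necrosis class,
extracted with 8-neighborhood connectivity by default (4 available). No
size filtering of any kind is applied: single-pixel components count. Each
object is then qualified against the tumor region:

* **intratumoral** if any object pixel touches the tumor region
  (center distance ≤ √2 under 8-connectivity);
* **peritumoral** if its minimum boundary distance is at most the
  "immediate peritumoral" threshold, 250 µm by default;
* **non-tumor-associated** otherwise — excluded from all densities.

Two details are worth making explicit. First, when qualifying objects of a
class that is itself part of the tumor region (necrosis), the reference
region excludes that class; otherwise every necrosis object would qualify
against itself. Necrosis inside the tumor bed is still captured through
adjacency to tumor and tumor stroma. Second, the density denominators use
tumor + *tumor* stroma, not all stroma: both parameters are tumor
densities.

The parameters are then

* `TLS-TD = qualified TLS area / (tumor + tumor-stroma area)`,
* `NECR-TD = tumor-associated necrosis area / (tumor + tumor-stroma area)`,
* `T/NR = qualified TLS area / tumor-associated necrosis area`, with no
  further normalization; it is undefined (`NA`) when the tumor has no
  associated necrosis, and such cases are excluded from T/NR stratification
  while remaining in TLS-TD, NECR-TD and the cumulative group.

Ratios are identical in px² and µm², so pixel areas are used internally.
Any display upscaling (×1,000 or ×100, convenient for plotting densities of
order 10⁻³) is applied in plots only, never to stored values. A mask
without tumor yields an explicit non-evaluable outcome rather than an
error.

The cumulative T+NR score combines the dichotomized densities: PG1 for TLS
high / necrosis low (both favorable), PG3 for TLS low / necrosis high (both
adverse), PG2 for the two mixed combinations. The mapping of the two mixed
combinations into one middle group is the natural reading of a three-level
classifier built from one protective and one adverse marker; it is a design
choice of this package, made explicit here because a four-level variant
would also have been conceivable.

## Optimal-cutpoint stratification

`find_optimal_cutoff()` scans candidate cutoffs at the empirical
percentiles 10–90 in steps of 2.5 and picks the candidate maximizing the
two-group log-rank statistic, subject to each group holding at least 10% of
the cohort (and at least two cases). The full per-candidate trace is
returned so the multiplicity of the scan is auditable; no correction is
applied across the grid, by design — users who want maximally-selected-rank
corrections can apply them to the trace. Exact ties in the statistic break
to the smallest cutoff. One cutoff per parameter is computed on the primary
endpoint and reused for all endpoints, which bounds multiplicity and keeps
the groups comparable across endpoints.

Kaplan–Meier and the log-rank test are implemented natively (the scan calls
the log-rank statistic dozens of times; the implementation is checked
against an explicit risk-table oracle and against the standard survival
machinery in the tests). Tied event times use the standard pooled
risk-table (hypergeometric variance) treatment. Cox models delegate to the
partial-likelihood fitter of the `survival` package with Efron tie
handling; multivariate models contain one prognostic parameter plus the pT
and pN categories, dummy-encoded against their first level since an
ordinal encoding was not clearly specified by convention.

A practical caveat the package's own simulations quantify: with a planted
threshold effect (hazard ratio 3) at n = 200, the argmax of the log-rank
scan concentrates near the true cutpoint but carries sampling noise of one
to two grid steps; recovery sharpens with cohort size and is exact at the
grid resolution by n ≈ 2000. Cutpoints estimated on small cohorts should be
read with that granularity in mind.

## The synthetic generator

`generate_mask()` emulates the geometry the quantification layer consumes,
not the appearance of H&E tissue: a central tumor nodule drawn from a
thresholded smooth Gaussian random field (with a tumor-stroma subdivision),
necrosis and mucin discs carved inside it, TLS discs placed intratumorally,
peritumorally (within the qualification distance, never touching) or
distant (beyond it), and a benign surround partitioned into lung
parenchyma, stroma and background. Planted fractions are expressed relative
to the final tumor + tumor-stroma area, so `f_tls` and `f_necrosis` *are*
the ground-truth TLS-TD and NECR-TD; the distant TLS share is planted on
top and must be excluded by qualification. Placement categories are emitted
as ground truth, so object qualification can be tested without a second
oracle. Everything is a pure function of (spec, seed).

Defaults: 1024² px canvas at MPP 1.0, 35% tumor area with a 40% stroma
share, `f_necrosis` 0.05, `f_tls` 0.02, `f_mucin` 0.01, TLS mix
50/30/20 intratumoral/peritumoral/distant, disc radii 4–10 px. These sit at
the magnitudes seen on real slides (densities of order 10⁻³–10⁻¹) while
keeping a single mask computable in seconds.

`generate_cohort()` draws per-case densities from log-normal distributions
(TLS-TD of order 2×10⁻³, NECR-TD of order 3×10⁻², with 10% of cases
necrosis-free so T/NR is exercised as undefined) and event times from a
proportional-hazards model whose log-hazard is linear in the densities.
Because raw densities are of order 10⁻³, effect sizes are parameterized as
hazard ratios per standard deviation of the density (defaults: 0.5 for
TLS-TD, protective; 2.0 for NECR-TD, adverse; baseline hazard 0.01/month,
30% censoring plus a 120-month administrative cap). pT and pN categories
are sampled with a positive association to necrosis density.
`simulate_threshold_cohort()` plants a pure threshold effect instead — the
generative model under which cutpoint recovery is well-defined.

What the generator does **not** emulate: stain appearance, nuclei, texture,
tile-boundary artifacts, scanner variation, or the spatial correlation
structure of real tumor microenvironments. Passing tests therefore
demonstrate that the quantification machinery is exact and self-consistent
on rasters with known truth — they do not certify segmentation accuracy on
real slides, which depends on the trained model plugged into the harness.

## Numerical and degenerate-input choices

* Rasters are validated against the legend on construction; class ids are
  8-bit on disk (PNG/TIFF, single channel, value = id).
* Dice with empty supports: `NA`, excluded from macro averages.
* Subtype calls with no evaluable tumor: explicit `"no_tumor"` outcome.
* T/NR without necrosis: `NA`, case excluded from T/NR dichotomization
  only.
* Masks without tumor: non-evaluable prognostic scores, not errors.
* Cutoff scan with all-identical values, no events, or unsatisfiable group
  sizes: a stratification error (these cohorts cannot be dichotomized).
* Cox fits refuse constant covariates and surface non-convergence as
  errors with the underlying message.
* Distances are exact Euclidean (distance transform), in pixel units scaled
  by MPP.

## Problem sizes used by the test-suite

The suite runs entirely on synthetic data: oracle-equivalence checks use
hundreds of random rasters up to 64² and cohorts up to n = 50;
planted-recovery checks use one 1024² mask and 50 cohorts of n = 200;
pipeline checks use bundles of 3–24 slides at 96² px. These sizes were
chosen so the whole suite runs in well under a minute per module while
leaving the recovery tolerances (10% relative on planted densities)
comfortably dominated by discretization rather than sample size.

## Known limitations

* The package quantifies masks; it does not segment images. All accuracy
  claims about real slides are conditional on the upstream segmenter.
* "Immediate peritumoral" has no universally agreed numeric definition;
  250 µm is a configurable default, logged in every output.
* The optimal-cutpoint procedure is maximally selected and therefore
  optimistic if its p-value is read at face value; the trace is exported
  so corrected inference can be layered on.
* Case-level pooling assumes slides of a case are exchangeable samples of
  the same tumor; macro-dissected or multi-tumor cases violate that.
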