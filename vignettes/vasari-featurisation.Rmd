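---
title: "Deterministic VASARI featurisation from lesion masks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic VASARI featurisation from lesion masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasarify)
```

## The problem

The VASARI lexicon (Visually AcceSAble Rembrandt Images) codes the imaging
appearance of adult gliomas as ~25 controlled features: where the tumour
sits, how much of it enhances or is necrotic, whether it touches the
ventricles or crosses the midline, and so on. Scored by eye, these features
are slow to produce and only moderately reproducible between readers.
`vasarify` derives a 15-feature subset purely from a multi-channel lesion
segmentation held in a common template space — no source MRI intensities
are ever read, so fully anonymised masks suffice. Everything is voxel
geometry: atlas overlap counts, connected components, hole filling,
Euclidean distance transforms. Identical inputs give byte-identical
reports.

The package also carries the machinery around the engine: agreement
statistics with equity stratification, a workforce/cost simulation, a
survival regression stage, and a phantom generator that makes the whole
pipeline testable without patient data.

## Inputs and coding

A `label_volume` holds a 3D array of compartment codes — 0 background, 1
nonenhancing tumour (NET), 2 perilesional signal change (PS), 3 enhancing
tumour (ET) — plus voxel spacing, a voxel-to-world affine and a
template-space tag. BraTS-coded files (`{0,1,2,4}`) are remapped on load;
unknown codes are an error, never silently dropped. An `atlas_set` is a
named collection of binary region masks on the same grid, each tagged with
laterality and, optionally, the VASARI location category it contributes
to; the contact features additionally need three roles: `ventricles`,
`cortex` and a `deep_wm` set (corpus callosum, internal capsule,
brainstem). Grids must match exactly (shape, and affine within 1e-4);
the package never resamples — registration belongs upstream.

The midsagittal plane is the template's world plane x = 0 under the
affine. Symmetric template space makes this well defined; for synthetic
grids the default affine centres the grid on that plane.

## The feature operators

* **F1 location / F2 side.** Computed on the *tumour core* (ET plus NET;
  PS excluded — perilesional signal is deliberately not allowed to drag
  the epicentre). F1 is the location category of the region with maximal
  core overlap; regions without a location mapping (ventricles, cortex)
  do not compete. F2 compares core voxels strictly left and right of the
  midplane: the minority hemisphere holding at least `center_fraction`
  (default 0.4) of off-plane core voxels — or a midline-tagged winning
  region — gives `center/bilateral`, otherwise the majority side wins.
* **F4–F7, F14 proportions.** The whole lesion is ET + NET + PS. Necrosis
  is *defined* as NET lying in cavities fully enclosed by ET (3D hole
  fill of the ET mask, minus ET, intersected with NET); the residual NET
  is the F6 compartment. This is the only geometry-consistent reading of
  "proportion of necrosis" from a three-label mask, and the raw block of
  every report records the counts it was derived from. Fractions are
  binned as `0%`, `<5%` (0 < f ≤ 0.05), `6-33%` (≤ 1/3), `34-67%`
  (≤ 2/3), `68-95%` (≤ 0.95), `>95%`, with `100%` reserved for exact
  equality in voxel counts; boundaries are right-closed. F4 enhancement
  quality is `none` without ET, `mild` below an ET fraction of
  `f4_mild_threshold` (default 0.05), else `marked` — the threshold is a
  config-visible choice, since a mask alone carries no intensity notion
  of "mild".
* **F9 focality.** 26-connected core components, discarding those under
  `min_component_voxels` (10). One component: focal. Several inside one
  connected component of the whole lesion (cores bridged by PS):
  multifocal. Otherwise multicentric.
* **F11 enhancing-margin thickness.** No ET: `n/a`. An ET mask without
  any enclosed cavity: `solid` (there is no rim to measure). Otherwise
  thickness = 2 × mean Euclidean distance-transform value over the
  medial rim voxels (local maxima of the transform within ET), minus
  half a voxel as a boundary correction: the transform reaches the
  centre of the first voxel *beyond* the rim, while the discrete medial
  plateau sits slightly inside the true medial surface; on rasterised
  spherical shells of known width (2–5 voxels) the net bias is half a
  voxel, and the corrected estimate tracks the analytic width to within
  0.2 voxels. Median and 95th-percentile variants are selectable
  (`thickness_stat`). Thin below 3 mm, thick at or above. The operator
  requires near-isotropic voxels (5% tolerance) and errors otherwise
  rather than silently measuring anisotropic distances.
* **F19–F21 contact.** Ependymal invasion: core dilated by
  `contact_radius` voxels (1, i.e. face contact) meets the ventricular
  mask. Cortical / deep-white-matter involvement: core overlap with the
  cortex / deep-WM set of at least `min_overlap_voxels` (10). The voxel
  thresholds buy robustness to single-voxel segmentation noise.
* **F22/F23 midline crossing.** For NET (including enclosed necrosis) and
  ET respectively: true iff one 26-connected component holds at least
  `min_cross_voxels` (5) strictly on each side of the midplane — two
  separate per-hemisphere components do not count as crossing.
* **F24 satellites.** ET components ranked by size; a non-dominant
  component is a satellite iff it has at least `min_satellite_voxels`
  (10) and lies outside the dominant lesion's core-plus-PS envelope
  (a different whole-lesion connected component).

Empty input is legal everywhere: categorical features report `n/a`,
booleans report `FALSE`, volumes are zero. There is no VASARI code for a
lesion-free scan, so the convention is explicit rather than implicit.

All component analyses use 26-connectivity (6 is selectable); the
complement operations (hole fill) use the complementary 6-connectivity,
the standard pairing for 3D masks.

## Agreement metrics

`dice()` is 2|A∩B|/(|A|+|B|), defined as 1 when both masks are empty so
that lesion-free compartments score agreement-on-absence instead of 0/0.
`cohen_kappa()` uses the disagreement form 1 − Σw·O / Σw·E with linear
weights |i−j|/(k−1) over the *declared* ordered category list for ordinal
(non-Boolean) features and 0/1 weights otherwise; identical constant
ratings give κ = 1 flagged `degenerate-identical`, and non-identical
ratings with zero expected disagreement give a flagged `NA` rather than a
crash. Note that linear weights are invariant under widening the declared
range (all weights rescale together); the declared list matters for code
validation and margin handling, not the value. `balanced_accuracy()` is
mean per-class recall over classes present in the truth vector.
`equity_stratification()` crosses sex with age decades ([20,30) … [80,90),
closed-open) and reports any stratum under `min_cases` (2) as
`insufficient` instead of a number. Mean agreement across features is
reported as an unweighted mean and labelled as such.

## The workforce simulation

`simulate_cohort()` forecasts three years (52-week years) of weekly
multidisciplinary-team caseloads at 40 centres, five iterations: each
week draws a caseload from the discrete uniform [30, 75] (the historical
range), a consultant hourly rate uniformly from the salary table, and
per-case featurisation times from uniform distributions for three arms —
radiologist (bounds matched to the observed 317.46 ± 96.89 s via
a = μ − σ√3, b = μ + σ√3, since only mean and spread are known),
engine (3.03 ± 0.59 s) and engine-plus-segmentation (15.47 ± 1.56 s).
Engine running cost is hours × power (kW) × tariff (£/kWh). The salary
table, power draw and tariff shipped as defaults are *illustrative*
placeholders in plausible UK ranges, not published figures; any real
costing must override them in the config. Arms are compared by a paired
two-sided Wilcoxon signed-rank test on per-iteration national totals — a
rank-based choice that stays honest at five iterations. Every trajectory
is reproducible from one seed; the expected per-centre cumulative
caseload is 156 × 52.5 = 8190 with SD ≈ 166, which the simulation
recovers.

## The survival stage

`encode_vasari_design()` turns a cohort report table into numbers:
ordinal features as integer scores under the declared category order,
booleans as 0/1, and the categorical location one-hot with the most
frequent location as reference (the encoding is a stated choice — nothing
in the lexicon fixes one). `vif_filter()` iteratively removes the
highest-VIF column while any VIF = 1/(1−R²) exceeds 10, breaking ties
(including perfectly collinear pairs) by keeping the earlier column.
`fit_os_model()` then fits OS ~ 1 + features by ordinary least squares —
deliberately linear, with no train/test split: at cohorts of order 100 a
flexible model would mostly fit noise. Age and sex can be added as
ordinary columns of the design if wanted; they are off by default.

## Phantoms: what they do and do not show

`make_toy_atlas()` builds a mirror-symmetric box brain (even grids ≥ 48³)
with eight lobar octants, insulae, thalami, internal capsules, corpus
callosum, brainstem, midline ventricles and a two-voxel cortical shell —
all pairwise disjoint. `make_phantom()` rasterises concentric-sphere foci
(necrotic NET core ≤ enhancing shell ≤ perilesional shell, voxel-centre
inclusion, innermost compartment winning where foci overlap) plus
ET-only satellite foci. Each spec *declares* its ground-truth report, and
the generator verifies the declaration by featurising the phantom at
generation time — a fixture that cannot realise its declared truth is a
loud error, not a flaky test. The shipped gallery of 16 specs covers
every feature family: all reachable proportion bins, thin/thick/solid
rims, the three focality classes, each contact and crossing flag, and
degenerate (empty, PS-only) lesions.

Phantoms are geometric idealisations. They exercise the engine's logic
exhaustively, but they do not emulate irregular lesion shapes, partial
volume effects, registration error or rater perception; a green phantom
suite certifies the mathematics, not clinical agreement with
radiologists, which on real data is bounded by genuine ambiguity between
nonenhancing tumour and oedema.

Synthetic rater tables perturb a reference rating by ±1 ordinal step
(clipped) at a controlled rate, so expected agreement falls monotonically
with the rate; the synthetic survival cohort generates OS from a stated
linear model with Gaussian noise truncated at zero, so coefficient
recovery is checkable.

## Problem sizes and numerical choices

The test suite runs the full gallery on 64³ grids, the brute-force oracle
sweep on 100 random grids of 8–13 voxels per axis (sizes where exhaustive
pairwise-distance and BFS references stay exact and fast), thickness
checks on 40³ shells, 1000 random rating pairs for the metric closed
forms, 200-repeat Monte Carlo convergence for the caseload mean, and a
100-case synthetic survival cohort. Distance transforms are exact
(separable squared-distance transform with anisotropic spacing support);
component labelling is scan-order deterministic, and ties everywhere
(location overlap, dominant ET component, VIF removal) break by first
occurrence so that reruns are byte-identical.

## Known limitations

* Ten of the 25 lexicon features (eloquence, cysts, T1/FLAIR ratio,
  margin definition, haemorrhage, diffusion, pial invasion, calvarial
  remodelling, among others) need intensities or sequences a mask cannot
  supply and are out of scope by design.
* The necrosis construction, the F4 threshold, the thickness statistic
  and the contact radii are reasoned conventions exposed in
  `vasari_params()`, not canonical values — the lexicon itself does not
  pin them down for mask-only derivation.
* No confidence intervals accompany κ, and the workforce comparison at
  five iterations has limited resolution (the smallest attainable
  Wilcoxon p is bounded by the iteration count).
* Monetary outputs are only as real as the user-supplied salary table and
  tariff.
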