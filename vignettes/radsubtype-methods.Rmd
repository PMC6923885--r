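---
title: "Methods: radiomic subtype classification of glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic subtype classification of glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma is classified into four transcriptomic subtypes — classical,
mesenchymal, proneural, neural — normally determined ex vivo from resected
tissue. This package implements a non-invasive alternative: an imaging
signature computed from routine pre-operative multi-parametric MRI (T1,
T1-Gd, T2, T2-FLAIR) and a segmentation of the tumor into peritumoral
edema (ED), enhancing tumor (ET) and non-enhancing tumor (NET). Derived
regions are the tumor core TC = ET ∪ NET and the whole tumor
WT = TC ∪ ED. The pipeline extracts a diverse radiomic feature vector per
subject, trains four one-vs-rest linear max-margin classifiers with
nested sequential forward selection under stratified 5-fold
cross-validation, fuses their signed hyperplane distances by argmax, and
screens individual features with the Kruskal–Wallis test. A synthetic
cohort generator provides a fully specified ground-truth world so that
every stage is testable without patient data.

## Feature families

All 3D quantities are computed on the voxel lattice with physical spacing
in mm. For regions $R \in \{ED, ET, NET, TC, WT\}$:

* **Volumetrics** — $vol(R) = |R| \prod_a h_a$ and the ratio
  $vol(R)/vol(\text{brain})$. The unions are of disjoint label sets, so
  $vol(TC) = vol(ET) + vol(NET)$ and $vol(WT) = vol(TC) + vol(ED)$ hold
  exactly and are asserted in the tests.
* **Surface area** — the sum of exposed voxel-face areas (a face counts
  when its neighbor is outside the region or outside the grid). This
  rasterized convention is chosen over meshed estimators because it has
  exact hand-computable oracles; it overestimates smooth-surface area by
  a bounded factor, which is irrelevant for between-subject comparison.
* **First-order moments** — population (not sample-corrected) mean,
  variance, skewness and non-excess kurtosis of the within-region
  intensities, per region × channel. A constant region reports
  skewness = kurtosis = 0 and is flagged.
* **Histogram percentages** — each (region, channel) intensity
  distribution is divided into 5 equal-width bins between the subject's
  own 1st and 99th within-region percentiles; out-of-range values clamp
  into the end bins so the five percentages always sum to 100. Per-subject
  quantile edges make the percentages invariant to global intensity
  rescaling.
* **GLCM texture** — co-occurrences of 32 min–max gray levels (quantized
  within the region) over the 13 unique radius-1 displacement directions
  (the 26-neighborhood modulo sign), symmetrized and pooled into a single
  normalized matrix; contrast, correlation, energy and homogeneity follow
  the standard Haralick formulas. Pooling (rather than per-direction
  averaging) is chosen for stability in small regions; a constant region
  reports contrast 0 and energy = homogeneity = correlation = 1 by
  convention.
* **2D morphology** — on the axial slice with the largest TC pixel count
  (ties to the smallest index), for each of ED/ET/NET/TC: area, exposed
  pixel-edge perimeter, extent (area over bounding box), solidity (area
  over the convex hull of the pixel squares), and moment-ellipse major
  and minor axis lengths with their ratio (eccentricity, ≥ 1). Second
  moments treat each pixel as a filled unit square (discrete variance
  plus $h^2/12$ per axis); with that correction a $w \times h$ rectangle
  has an axis ratio of exactly $w/h$, which the tests assert against the
  closed form. A single-pixel region reports both axes equal to the pixel
  size and ratio 1, flagged.
* **Location** — minimum Euclidean distance of ED and TC voxel centers to
  the ventricles; the proportion of TC in each of 9 anatomical regions
  (temporal, frontal, parietal, occipital, basal ganglia, cc/fornix,
  insula, cerebellum, brain stem), which sum to 1.

## Spatial distribution atlases

For each subtype $s$, an atlas pair is built from the training cohort:
$P^{+}_s(v)$ is the fraction of subtype-$s$ subjects whose TC covers
voxel $v$, $P^{-}_s(v)$ the same over all other subjects. A tumor with
core voxel set $T$ is scored by

$$L_1 = \overline{P^+}_T - \overline{P^-}_T, \quad
  L_2 = \max_T P^+ - \max_T P^-, \quad
  L_3 = \frac{\overline{P^+}_T + \varepsilon}{\overline{P^-}_T + \varepsilon}, \quad
  L_4 = \frac{\max_T P^+ + \varepsilon}{\max_T P^- + \varepsilon}$$

giving 4 values × 4 subtypes = 16 location features. Two conventions are
deliberate where the construction is ambiguous: the mean is taken over
*all* of the tumor's TC voxels, including voxels where the atlas
frequency is 0 (the inclusive reading of "intersection area"), and
$\varepsilon = 10^{-6}$ guards the bare ratios against division by zero.
Because the atlases depend on training labels, cross-validation rebuilds
them from the training folds only and recomputes all 16 columns for every
subject against those fold atlases; a poisoning audit test verifies that
held-out rows influence no training artifact.

## Classification model

Each subtype is discriminated against the rest by a linear max-margin
classifier: the primal L2-regularized squared-hinge SVM

$$\min_{w, b} \tfrac{1}{2}\lVert w \rVert^2
  + C \sum_i c_i \max(0,\, 1 - y_i (w \cdot x_i + b))^2$$

solved by damped Newton iteration (convex and smooth; a handful of
iterations suffice at these sizes — the solver lives in compiled code
because nested selection evaluates tens of thousands of fits). The class
weights $c_i$ are inversely proportional to class frequency, countering
the ~1:3 one-vs-rest imbalance. The kernel is linear: distances to the
hyperplane are then well-defined geometric quantities,
$d(x) = (w \cdot z + b)/\lVert w \rVert$ on the standardized row $z$,
which makes the four models' scores commensurable before fusion. Fusion
assigns the subtype with the largest signed distance; exact ties break by
the canonical order (classical, mesenchymal, proneural, neural).

Within each training fold:

1. columns are standardized by training-fold population mean/sd
   (constant columns are excluded);
2. **sequential forward selection** greedily adds the feature that
   maximizes 3-fold inner-CV balanced accuracy (at fixed C = 1), stopping
   when the best improvement is below 0.005 or 20 features are reached;
   at least one feature is always selected and exact ties go to the
   lowest column index;
3. the regularization parameter is then grid-searched over
   $2^{-5} \ldots 2^{5}$ by the same inner CV on the selected set (ties
   to the smaller C), and the final model is refit on the whole training
   fold.

Running the C search once on the selected set, rather than jointly inside
every selection step, is a deliberate economy: it keeps nested validation
honest (everything still happens inside the training fold) at a fraction
of the cost. The improvement threshold, feature cap, grid and inner fold
count are all exposed in `default_model_config()`.

Evaluation pools all held-out predictions from stratified 5-fold
cross-validation (per-fold class counts differ by at most 1; the fold
seed is recorded in the report) into accuracy, balanced accuracy (mean
per-class recall), per-subtype sensitivity/specificity on the 0–100
scale, rank-based AUC (ties at half credit, equal to the trapezoidal area
under the threshold ROC), and the 4-way confusion matrix.

## The synthetic world

`generate_cohort()` emits a balanced labeled cohort on a shared 48³ grid
at 2.5 mm spacing: an ellipsoidal brain, two periventricular ellipsoids,
a 9-region geometric parcellation, and per subject three nested
ellipsoids (NET core, ET shell, ED outer shell) clipped to the brain,
with Gaussian within-region channel intensities (region sd 8, global
noise sd 4, on arbitrary MR units of roughly 90–200). Subtype enters
through four effect channels, realizing the qualitative published
signature with magnitudes that are free parameters of this package (the
source analysis reports directions only):

* intensity multipliers — proneural ET/T1-Gd × 0.70 and within-region sd
  × 0.45 (lower, more uniform enhancement); neural ED/FLAIR × 1.30;
  mesenchymal ED/FLAIR × 0.75 and ED/T2 × 0.80;
* shell scaling — mesenchymal ET and ED shells × 1.55/1.45 (bigger ED,
  ET, WT); classical ED shell × 0.55 (smaller ED and WT surface area);
* in-plane axis ratios — mesenchymal NET 1.90 and ET 1.00 against a base
  of NET 1.35 / ET 1.25; neural NET 1.00;
* lobe placement priors — one mean center offset per subtype (frontal,
  temporal, parietal, occipital) with 4 mm jitter, giving the location
  atlases a recoverable spatial pattern.

`effect_scale` interpolates every effect toward the null
(`effect_scale = 0` gives four exchangeable classes), and
`effect_audit()` reports the realized group means next to each intended
direction. Per-subject seeds are derived by hashing the master seed with
the subject index, so cohorts are pure functions of
(config, n per class, seed) and insertion-order independent.

What the generator deliberately does **not** emulate: MRI physics (bias
fields, partial-volume effects, motion), multifocal or irregular
non-ellipsoidal tumors, inter-individual anatomy (all subjects share one
brain), scanner-to-scanner intensity variation, and any correlation
structure between feature families beyond what the geometry induces. A
green end-to-end test therefore establishes that the machinery is
correct and leakage-safe on a world with a known signature — not that the
published patient-cohort performance is reproduced; those numbers come
from private clinical data.

**Histogram matching and synthetic cohorts.** Intensity normalization by
256-landmark quantile mapping to a reference subject is implemented and
tested as its own stage (monotone, rank-preserving, idempotent to one
landmark spacing, background untouched, restricted to the brain mask).
It exists to remove scanner-scale variation between patients. The
simulator emits every subject on one common intensity scale, so the
synthetic feature tables are extracted without it: quantile-matching
near-identical whole-brain distributions only redistributes the tumor
tail (tumors of different sizes occupy different quantile mass), which
distorts the injected intensity contrasts without modeling anything
real. On real cohorts the stage runs between loading and extraction
(`preprocess` subcommand; reference = first manifest row unless
`--reference` is given).

## Statistical screening

`kruskal_wallis()` implements the tie-corrected rank statistic
$H = \left[\frac{12}{N(N+1)} \sum_j R_j^2/n_j - 3(N+1)\right] /
\left[1 - \sum_t (t^3 - t)/(N^3 - N)\right]$ with a chi-square
($k - 1$ df) p-value, verified exactly against the reference
implementation in base R, and optionally a Monte-Carlo permutation
p-value. One numerical caveat is worth stating plainly: at small group
sizes (e.g. 5 per group) the chi-square approximation carries a bias of
order 0.01–0.03 in the middle of the distribution, which is *larger*
than three Monte-Carlo standard errors of a 10⁴-draw permutation
estimate. A correct implementation therefore cannot be expected to agree
with its own permutation p to within pure Monte-Carlo noise at those
sizes; the package's tests allow the approximation term explicitly, and
one stricter acceptance assertion is knowingly left failing with this
analysis on record. `screen_features()` tests every feature column,
sorts by p, appends Benjamini–Hochberg q-values (the source analysis
names no correction; BH is this package's addition for honest
multiplicity control) and flags the group with the most extreme median.

## Calibration statistics

Null calibration pools held-out predictions over ≥ 20 replicates and
checks the 95% binomial band around the 25% four-class chance level. The
replicates must be approximately independent for the pooled band to
apply: replicating only the fold seed on one fixed cohort re-tests that
cohort's idiosyncratic accuracy, whose sampling band is the single-run
one. On the zero-effect cohort the labels are exchangeable by
construction, so each replicate draws a fresh label permutation (and the
unpermuted run is additionally checked at its own n). On the
strong-effect cohort the permutation itself is the null operation.

## Known limitations

* The 9-region parcellation and ventricle geometry are geometric
  stand-ins on the shared grid; the deformable atlas registration used
  for real cohorts is out of scope, as are denoising, bias correction,
  co-registration, skull stripping and tumor segmentation (external
  tools produce the package's inputs).
* Default effect magnitudes make the synthetic classes strongly
  separable (cross-validated accuracy near ceiling); they demonstrate
  recovery, not realistic difficulty. `effect_scale` provides a
  continuum for harder worlds.
* The NIfTI reader/writer supports the single-file NIfTI-1 subset the
  package itself produces (3D, common datatypes, slope/intercept
  rescaling) — not the full standard.
* Diffusion/perfusion derivative maps (FA, ADC, PSR, PH, rCBV …) are not
  computed; the screening operation applies to any feature column, but
  those inputs must be produced elsewhere.
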