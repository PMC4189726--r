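---
title: "Threshold-based LGE quantification: models, conventions and phantom design"
author: "lgequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based LGE quantification: models, conventions and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgequant)
```

## The problem

Late gadolinium enhancement (LGE) on inversion-recovery cardiac MR marks
focal myocardial fibrosis.  In hypertrophic cardiomyopathy (HCM) the
enhancement is patchy and non-uniform — dispersed faint interstitial
fibrosis interleaved with small dense scar islands — which makes manual
planimetry an unreliable reference and makes the choice of a
signal-intensity (SI) threshold consequential.  `lgequant` implements the
standard semi-automated threshold operators, a reproducible surrogate of
expert threshold adjustment, study-level quantification, and the
Bland-Altman/ICC machinery used to compare methods, together with a
synthetic phantom generator with known ground truth on which the whole
pipeline can be exercised end to end.

## Segmentation operators

All operators act on the myocardial pixels of one short-axis slice, defined
by user-supplied endocardial/epicardial contours (minus any exclusion
polygons), and all masks are "SI strictly greater than the threshold":

* **STRM k** (signal threshold versus reference mean): threshold
  $\mu_{ref} + k\,\sigma_{ref}$ from a remote-myocardium reference ROI;
  $k \in \{2,\dots,6\}$ are the standard operators.  The SD estimator
  defaults to the population form (denominator $n$); the commercial tools
  this family mirrors do not document their estimator, so it is
  configurable (`sdEstimator = "sample"`).
* **FWHM**: threshold $= \tfrac12 \max(\text{SI})$ over an
  enhancement-core ROI that contains the brightest visible enhancement.
  Whether deployed implementations use max/2 or the midpoint between core
  max and min is not standardized; max/2 is the default and
  `fwhmMode = "half_range"` selects the alternative.
* **OAT** (Otsu auto-threshold): maximizes the between-class variance of
  the myocardial SI histogram.  Integer-valued images use exact integer
  bins (up to 4096 levels); continuous images use 1024 equal-width bins
  over the observed myocardial range.  Ties break toward the lowest
  maximizing threshold.  Note that on an effectively unimodal histogram
  (little or no enhancement) Otsu degenerates to splitting the dominant
  mode near its center — a known failure mode that this package makes no
  attempt to patch, because quantifying it is part of the point.
* **MANUAL**: a reproducible stand-in for the expert's slide-bar
  adjustment.  The threshold is swept from 0 upward over all distinct
  myocardial SI values and the value maximizing Dice overlap with the
  target mask (phantom ground truth, or an expert mask) is returned, ties
  broken toward the lower threshold.  Dice is the declared
  operationalization of "visually matching" the identified enhancement; an
  exhaustive sweep makes the choice exactly reproducible.

Slices flagged LGE-negative contribute zero LGE under every operator,
mirroring per-slice visual adjudication.  No component-size post-filter is
applied by default; `applyPostprocessing()` exposes one explicitly
(8-connectivity in-plane, never across slices).

## Geometric conventions

Contours live in continuous image coordinates where pixel $(r, c)$ has its
center at $(r, c)$ and covers $[r-\tfrac12, r+\tfrac12) \times
[c-\tfrac12, c+\tfrac12)$.  A pixel belongs to a polygon iff its center is
inside under the even-odd rule; centers exactly on a boundary are resolved
by a fixed half-open comparison, so rasterization is deterministic and
orientation-independent.  The myocardium mask is
(epi) AND NOT (endo) AND NOT (exclusions), with the endocardial hole left
open.

## Quantification

Per-slice LGE area is pixel count times pixel area (mm^2); per-study
volume is $\sum_i \text{area}_i \times \text{thickness}$ — thickness only,
not thickness plus gap, following the per-slice area-times-thickness
formula; `includeGap = TRUE` adds the gap for sensitivity analyses.  Mass
uses the standard myocardial density 1.05 g/ml (configurable).  The LV-mass
denominator of %LV is computed from the same LGE-series contours; cohorts
that derive LV mass from a separate cine series will differ by that
protocol choice.

## Agreement statistics

Bland-Altman reports mean difference and the 95% limits-of-agreement
halfwidth $1.96 \times SD_{n-1}$ of the paired differences, in the
"mean ± halfwidth" convention; the sign convention is method − reference,
so positive means overestimation.  The ICC is the two-way random-effects,
absolute-agreement, single-measure form (Shrout–Fleiss ICC(2,1)), computed
from the mean-squares decomposition; it is the appropriate variant when a
method is compared against an absolute reference standard.  Method ranking
sorts by |mean difference| with ties broken by higher ICC.  LGE-negative
subjects (legitimately zero for every method) are included in patient-level
comparisons by default (`includeNegatives`).

## The synthetic phantom

`generatePhantom()` builds short-axis studies with known per-pixel truth.
Geometry defaults: 96×96 px at 1.4 mm, six slices of 8 mm with a 2 mm gap,
epicardial/endocardial radii 28/16 px at mid-ventricle with apical/basal
taper — LV mass ≈ 150–170 g and wall thickness ≈ 17–20 mm, i.e. a
hypertrophic ventricle.  68% of generated subjects are LGE-positive.

The lesion model is the load-bearing design decision.  Each lesion is a
Gaussian-bump blob truncated to a log-normal target area (median 80 px ≈
1.6 cm², clipped to 12–220 px, Poisson mean 1.3 lesions per slice in
positive studies).  Its intensity profile has two parts:

* a **graded border zone** (94% of lesion pixels): intensities start at a
  floor of 122 SI units — about 2.2 noise-SDs above remote myocardium,
  i.e. the faintest enhancement one would call visually apparent — and
  decay exponentially upward with scale 10 SI units, so most enhancement
  is faint and the histogram density of lesion pixels falls smoothly and
  steeply across the 2–6 SD threshold band;
* a small **dense core** (6%): a linear ramp up to the 280 SI peak, so the
  maximum is carried by a compact bright island, as the FWHM reference
  rule presumes.

Remote myocardium sits at 100 SI with Rician noise of σ = 10 (SNR 10), a
bright blood pool fills the cavity, and a smooth multiplicative shading
field of amplitude ±10% emulates surface-coil inhomogeneity.  An early
single-level border-zone variant was tried and discarded: one intermediate
intensity concentrates the lesion histogram between two adjacent STRM
thresholds and cannot simultaneously produce the three qualitative regimes
the operators are known for (FWHM underestimation, STRM2/OAT
overestimation, reproducibility improving with k).  The decaying-border
model produces all three at once, for the same reason real HCM cohorts do:
enhancement mass is concentrated just above the visibility floor.

Reference regions are auto-derived from the truth, mirroring clinical
practice: the remote ROI is a modest (~2 cm²) annular sector inside the
largest lesion-free arc; the core ROI is a small disk containing the
maximum-SI lesion pixel.  `simulateObserver()` perturbs only these ROIs —
rotating the remote sector along the ring, translating and rescaling both —
while contours and images stay fixed, which is how reproducibility
sub-studies isolate the threshold techniques themselves.  An invalid draw
(remote ROI touching a lesion, core ROI missing it) is resampled with
geometrically shrinking perturbation.

What the phantom does **not** emulate: papillary muscles and trabeculation,
partial-volume blood-pool contamination at the endocardial border, motion
or TI-misadjustment artifacts, through-plane lesion continuity, and any
fitted cohort intensity distribution (no per-patient data are available to
fit; the parameters above are declared, not estimated).  Passing phantom
experiments therefore demonstrates internal consistency of the operators
and the *direction* of their biases under a realistic intensity model, not
clinical accuracy on real images.

## Numerical choices and degenerate inputs

* STRM requires ≥ 2 remote-ROI myocardial pixels (SD undefined otherwise);
  an ROI disjoint from the myocardium is an error, as is a constant-valued
  myocardium for Otsu.
* The manual sweep of an empty target returns a threshold above the
  myocardial maximum (zero LGE) and flags it rather than erroring, since
  LGE-negative slices are a routine input.
* Otsu bin-edge ties and manual-sweep Dice ties both resolve toward the
  lower threshold, so reruns are bit-identical.
* All randomness flows through explicit seeds (`withr::with_seed`); no
  function reads or leaves hidden global RNG state.  Experiment runners
  derive per-study child seeds deterministically and keep them below 2^31.

## Problem sizes

The shipped experiments use 30 phantom studies of six 96×96 slices for the
accuracy and reproducibility runs, 50 reduced-size phantoms (64×64, three
slices) for the nesting sweep, and n = 2000 for ICC parameter recovery —
sizes at which every directional result above is stable across seeds while
a full run stays in the minutes range on one core.

## Known limitations

* The manual-sweep reference optimizes Dice against a *known* target; a
  human expert optimizes a perceptual criterion against an unknown one.
  Agreement with the sweep is therefore an upper bound on agreement with
  an expert.
* With Gaussian/Rician remote noise plus smooth coil shading, the
  Dice-optimal manual threshold settles near 2.2–2.4 noise-SDs above
  remote, so the operator closest to the manual reference on these
  phantoms is STRM2 (small positive bias) rather than STRM3 (moderate
  negative bias), even though every bias *direction* matches the known
  clinical pattern.  Real myocardium has heavier-tailed remote intensity
  distributions (partial volume, trabeculation, imperfect nulling) that
  push the expert operating point toward 3 SD; the phantom does not model
  those tails, and spreading the lesion border-zone decay far enough to
  compensate destabilizes the Otsu-overestimation and
  reproducibility-ordering regimes.  This is the one quantitative respect
  in which the phantom knowingly departs from clinical behavior.
* ICC variants other than ICC(2,1) (consistency forms, multi-rater k > 2
  average-measure forms) are not implemented.
* Only magnitude-reconstructed images are modeled; phase-sensitive
  reconstructions are out of scope.
* NIfTI is the supported image container (with a JSON contour/geometry
  sidecar); DICOM series must be converted upstream.
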