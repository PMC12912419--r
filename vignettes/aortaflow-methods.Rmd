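---
title: "Methods: aortic morphometry and prognostic modelling in aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aortic morphometry and prognostic modelling in aortaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aortaflow` implements two coupled layers: a morphometry layer that turns a
non-contrast chest CT volume plus a binary thoracic-aorta segmentation into
three biomarkers (maximum orthogonal diameter, volume, calcification
burden), and a prognostic layer that relates those biomarkers to
cardiovascular mortality with cause-specific survival models. Because the
screening CTs such an analysis targets are access-restricted, both layers
are exercised against a synthetic-data layer with exact ground truth. This
vignette records the models, the parameter choices, and what the synthetic
evidence does and does not establish.

## Image model and working resolution

Volumes are axis-aligned scalar grids in Hounsfield units with per-axis
spacing in millimetres, using the voxel-center convention
(`position = origin + (index − 1) · spacing`). All measurements are taken at
a working resolution of **1.5 × 1.5 × 3 mm**; `resample_volume()` brings
arbitrary inputs there by trilinear interpolation (masks are interpolated as
{0, 1} fields and re-binarized at 0.5). Resampling first and measuring
second keeps the measurement operating point independent of the scanner's
acquisition grid.

## Centerline

The centerline is defined as the curve through the tube that stays
equidistant from the boundary within each orthogonal cross-section. It is
recovered discretely:

1. keep the largest 26-connected foreground component (a cavity inside the
   foreground raises a topology error; masks with fewer than 100 foreground
   voxels, or nowhere thicker than two voxels, are rejected as degenerate);
2. compute the exact anisotropic Euclidean distance transform in mm
   (separable squared min-convolution);
3. find the tube ends by a two-pass farthest-point geodesic search on the
   foreground voxel graph. The raw geodesic extreme of a tube is an
   end-face *rim* voxel, so each endpoint is refined to the centroid of the
   near-extreme region (within one diagonal voxel step of the maximum
   geodesic distance), snapped to the nearest foreground voxel — this lands
   on the medial end-face center;
4. take the shortest path between the endpoints with edge weight
   `step_length / (boundary_distance + 0.1 mm)²`, which pulls the path onto
   the medial axis while remaining deterministic;
5. smooth with a moving average (window 5 voxels), resample at 1 mm arc
   length, and form tangents by central differences over a ±3-sample
   baseline. The wider tangent baseline suppresses residual voxel-path
   wiggle that would otherwise tilt the orthogonal measurement plane.

On straight-cylinder phantoms the recovered path is collinear with the
analytic axis to within half a voxel, and on half-torus phantoms the arc
length matches `πR` within a few percent (the path spans face center to
face center, so a half-slice per end is genuinely absent).

## Maximum orthogonal diameter

At each centerline sample (after trimming `end_trim_mm = 10` mm from both
ends, which otherwise contribute oblique end-cap chords), chords are cast
through the sample point in the plane orthogonal to the local tangent at
1° increments over 180°. A chord's length is the contiguous in-mask extent
through the point, obtained by marching the trilinearly interpolated mask
in 0.25 mm steps (inside ⇔ value ≥ 0.5) with linear sub-step refinement of
the boundary crossing. The per-point diameter is the longest chord and the
reported value is the global maximum in cm. The chord-through-the-point
construction (rather than, say, the Feret diameter of the cross-section
polygon) matches the definition of the diameter as the distance between
opposite mask edges through the centerline.

Two discretization effects are worth knowing. First, the 0.5-level surface
of a binarized mask is only determined to about half a voxel, and taking a
maximum over 180 angles preferentially selects positive excursions, so
diameters carry a positive bias of roughly half an in-plane voxel
(≈ 0.08 cm at the working resolution). Second, wherever the measurement
plane contains the through-plane axis (e.g. the apex of an aortic arch),
the same mechanism operates at the 3 mm slice spacing, and diameters there
can read up to ~1.5 mm per side above the continuous truth. Both effects
are properties of measuring a discrete mask, not of the estimator; the
cylinder and tapered-cone acceptance tests bound the in-plane case at
±0.15 cm.

## Volume and calcification burden

Volume is exact arithmetic: foreground count × voxel volume / 1000 (ml).

Calcification burden smooths the **full HU volume** with a Gaussian kernel
of FWHM 3 mm (σ = FWHM / (2√(2 ln 2)), isotropic in mm and therefore
anisotropic in voxels), then counts in-mask voxels with smoothed value
≥ 130 HU and reports their volume in mm³. Smoothing precedes masking; the
kernel is truncated at 4σ with edge-renormalized rows. The ≥ (rather than
strict >) comparison at exactly 130 HU was chosen as the inclusive reading
of the conventional calcium threshold; the difference is measure-zero for
continuous noise. The implementation is validated against an independent
direct-convolution oracle on a 0.5 mm grid (agreement within 10%; exact
zero on blob-free phantoms).

Quality control marks a measurement implausible iff diameter < 2.0 cm or
volume < 70 ml (strict `<`, so boundary values pass), or any feature is
non-finite.

## Synthetic phantoms

Phantoms sweep a (possibly linearly tapering) lumen radius along an
analytic curve: straight cylinder, half-torus arc, or a "candy cane"
(ascending limb + half-torus arch + descending limb) that mimics thoracic
aortic geometry while avoiding branch handling. The mask contains every
voxel whose center lies within the local radius of the curve, with flat end
caps; the grid is auto-sized with a ≥ 2-voxel margin and offset by half a
voxel so the tube sits at a generic sub-voxel position rather than the
degenerate exactly-aligned one. Images are background −950 HU, lumen
40 HU, with spherical wall calcifications (centers on the lumen surface,
painted only inside the mask, HU > 130 enforced) and seeded iid Gaussian
noise. Ground truth — centerline, arc length, 2·max r, swept volume (closed
form, Pappus for bends), and the analytic in-mask half-volume per blob — is
computed from the specification, never from the grid.

## Synthetic cohorts

`cohort_spec()` encodes a heavy-smoker screening cohort of default size
24,770: age ~ Normal(61.4, 5.0) truncated to 55–74 y, 40.8% female,
BMI ~ Normal(27.9, 5.0), race 91.4/4.2/4.4%, 47.9% current smokers
(the complement of former smokers; the generator simply exposes the
proportion as a parameter), pack-years ~ Normal(56, 24) truncated at 30,
diabetes 9.7%, hypertension 35.1%, heart disease 12.9%, stroke 2.8%.
Features follow the cohort anchors: diameter ~ N(3.6, 0.4) cm built as
`3.45 + 0.02·(age − 61.4) + 0.25·male + N(0, 0.36)` (mild age/sex
structure with the target marginal); volume linear in diameter
(`−145 + 100·diameter + N(0, 34)` ml, targeting N(215, 52)); calcium
log-normal targeting mean 1326 / sd 2208 mm³ with a 0.06 per-year age
effect on the log scale and the residual σ reduced so the total marginal is
preserved. An Agatston-like coronary calcium score, correlated with aortic
calcium and zero-inflated, is attached to ~56% of subjects (the remainder
missing by design).

Survival uses two independent exponential cause-specific hazards,
`h_c(x) = h0_c · exp(β_cᵀ x)` on centered design columns, with
administrative censoring Uniform(6.0, 6.9) years (hard cap 8 y) — a
deliberate simplification of staggered enrolment that reproduces a ~6.4 y
median follow-up. Other-cause death is generated as a competing event and
treated as censoring in every CVD analysis, i.e. the cause-specific Cox
convention. The default log-hazard coefficients are moderate,
epidemiologically signed effects (e.g. 0.09/y age, 0.55 male, 0.60 per log
unit of calcium for CVD; smoking weighted more heavily for other-cause
death); they are stand-ins with the right ordering and magnitude, not
estimates. `calibrate_baseline_hazards()` adjusts the two baselines by
alternating bisection on Monte-Carlo event fractions (fixed internal seed,
80,000 subjects, tolerance 0.1 percentage points; the two targets couple
only weakly at these event rates, so three alternating rounds suffice) —
the default targets are 1.8% CVD and 7.0% all-cause mortality.

What the generator does **not** emulate: real segmentation-failure modes,
anatomy around the aorta, staggered entry and loss to follow-up,
non-proportional hazards, measurement error correlated between features,
and race- or comorbidity-specific feature distributions. Passing tests
therefore establish the correctness of the estimators and pipeline
plumbing under a known data-generating process, not clinical validity on
real screening data.

## Statistical layer

Model fitting is delegated to the `survival` package behind a stable
module surface: Efron tie handling by default (Breslow available),
Newton iterations to a 1e-9 gradient tolerance, at most 100 iterations;
monotone-likelihood/separation diagnostics are captured as flags on the
fit rather than as warnings. Wald 95% CIs are `exp(coef ± 1.96·se)`.
Missing-covariate subjects are excluded listwise. Categorization follows
fixed conventions: diameter dichotomized at 4.5 cm (4.0 cm for the
dilatation sensitivity analysis); volume by rank-based median split
(lowest ⌊n/2⌋ ranks low, ties broken by stable subject order) or a fixed
210 ml cut; calcium by fixed 270/1050 mm³ cutoffs (lower-inclusive upper
groups) or empirical rank tertiles with remainder subjects allocated to
the lowest-index groups; coronary calcium by Agatston categories
0 / 1–99 / 100–399 / ≥ 400 (the conventional cutpoints, configurable since
category definitions vary across studies).

Harrell's c is computed by `survival::concordance` (higher score = higher
risk) with its asymptotic U-statistic variance; the package's own
O(n²) pair enumeration serves as an exact oracle in tests. `compare_c()`
tests `c_a − c_b` using the paired covariance of the two concordance
estimates from the same subjects — an infinitesimal-jackknife variance that
stands in for the dedicated two-c-statistic comparison estimator, which is
not reproduced here; it is an approximation of the same asymptotic
quantity. Nested models are compared by the likelihood-ratio statistic
`2·Δloglik ~ χ²(Δdf)`.

In simulation studies, hazard-ratio estimates are pooled across replicates
on the log scale (geometric mean): the Cox estimator is asymptotically
unbiased for log HR, so arithmetic averaging of exponentiated coefficients
would add a spurious `exp(se²/2)` inflation.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
desk scale: phantoms of 10–18 mm radius on grids of ≲ 300k voxels;
hazard-ratio recovery on cohorts of 24,770 subjects pooled over 60–100
seeded replicates; coverage checks over 200 replicates of 2,000 subjects;
the calibrated-cohort checks over ~10 cohorts. Every stochastic component
takes an explicit integer seed and restores the global RNG state on exit,
so cohort generation and the pipeline report are bit-reproducible for a
fixed seed; no function reads or leaves global RNG state behind.

## Known limitations

* Diameters on bent segments measured through the 3 mm axis can read up to
  ~1.5 mm per side high (discrete-mask maximum bias, above).
* The centerline spans face center to face center and so omits roughly half
  a tube radius of arc at each anatomical end; the 10 mm end trim for the
  diameter search makes this immaterial for the reported maximum.
* The confounding structure available in the simulator is linear-Gaussian
  in the propensity; it cannot represent, e.g., threshold-driven
  confounding.
* The per-segment analysis (ascending / arch / descending) is out of scope;
  features summarize the whole thoracic aorta.
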