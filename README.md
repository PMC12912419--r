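# aortaflow

Thoracic aortic disease is usually summarized in clinical practice by a
single number — the maximum aortic diameter — even though routine
non-contrast chest CT contains far richer prognostic information.
`aortaflow` is an R package for quantifying three thoracic aortic biomarkers
from a CT volume paired with a binary aorta segmentation, and for modelling
their prognostic value for cardiovascular (CVD) mortality in screening-scale
cohorts of heavy smokers:

1. **Maximum diameter** (cm): the longest chord through the aortic
   centerline measured in the plane orthogonal to the local tangent,
   `D = max_s max_θ chord(s, θ)`.
2. **Aortic volume** (ml): voxel count of the segmentation times the voxel
   volume.
3. **Calcification burden** (mm³): volume of voxels inside the segmentation
   with smoothed attenuation ≥ 130 HU, after Gaussian smoothing with a
   3 mm full width at half maximum (σ = FWHM / (2√(2 ln 2))).

The prognostic layer treats CVD death as the event of a cause-specific Cox
proportional-hazards model, `h(t | x) = h₀(t) · exp(βᵀx)`, with other-cause
death handled as censoring; it provides Kaplan–Meier curves with pairwise
Holm-adjusted log-rank tests, univariable and covariate-adjusted hazard
ratios for categorized features (diameter ≥ 4.5 cm, volume median split,
calcium tertiles at 270/1050 mm³ or empirical), Harrell's c-index with a
paired comparison test between markers, nested-model likelihood-ratio
tests, and a calcium-tertile × coronary-calcium reclassification table.

Because the underlying screening images are access-restricted, the package
ships a first-class synthetic-data module: curved-tube CT phantoms
(cylinder, half-torus arc, "candy cane" arch) with exact analytic ground
truth for the centerline, diameter, volume and wall calcifications, and
simulated screening cohorts (default n = 24,770) whose covariate marginals,
feature distributions, cause-specific hazards and administrative censoring
are fully parameterized and calibratable to target mortality fractions.
Every stage of the pipeline is therefore testable end to end against known
truth.

## Worked example

Measure a noisy calcified phantom against its analytic truth:

```r
library(aortaflow)

ph <- generate_phantom(phantom_spec(
  "straight_cylinder", lumen_radius_mm = 18, segment_length_mm = 100,
  calcifications = list(list(position = 0.5, radius_mm = 4, hu = 700)),
  noise_sd_hu = 15, seed = 7))
measure_aorta(ph$volume, ph$mask, resample = FALSE)
#> <aortic_features> max diameter 3.72 cm, volume 99.8 ml, calcium 176 mm^3, QC pass
ph$truth
#> diameter 3.6 cm, volume 101.8 ml, calcium 134 mm^3 (in-mask half-blob)
```

The diameter and volume recover the analytic truth at the working
resolution (1.5 × 1.5 × 3 mm); the calcium figure is the smoothed-and-
thresholded burden, which exceeds the pre-smoothing analytic blob half
volume because the 3 mm kernel spreads the blob across neighbouring voxels
that remain above 130 HU.

Simulate a calibrated cohort and analyse it:

```r
spec   <- calibrate_baseline_hazards(cohort_spec(seed = 1))   # 1.8% CVD, 7% all-cause
cohort <- generate_cohort(spec)
cc     <- categorize_features(cohort,
            analysis_config(calcium_cutoffs_mm3 = "data_tertiles"))

cox_fit(cc, "calcium_tertile")
#> <survival_fit> endpoint=cvd, n=24770, events=446, ties=efron
#>                       HR  lower  upper p
#> calcium_tertileT2 2.1675 1.5869 2.9605 0
#> calcium_tertileT3 4.7038 3.5400 6.2501 0

harrell_c(cc, cc$aortic_calcium_mm3)
#> <cindex> c=0.6866 [0.6622, 0.7110], usable pairs 1.05006e+07

compare_c(cc, cc$aortic_calcium_mm3, cc$max_diameter_cm)$p
#> 0.001
```

Read: subjects in the top calcium tertile die of CVD at ~4.7 times the rate
of the bottom tertile; calcium discriminates CVD death markedly better than
the maximum diameter (Δc = 0.058, p = 0.001) — the qualitative pattern the
package's survival simulator was designed to emulate.

A thin command-line front end (`exec/aortaflow`) exposes the same stages as
subcommands: `run`, `measure`, `simulate-phantoms`, `simulate-cohort`,
`analyze`, `fixtures`.

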