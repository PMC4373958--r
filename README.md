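# virtualqa

Virtual delivery quality assurance (QA) for radiotherapy, end to end and with
known ground truth. The package rebuilds, as an open simulation, the QA chain
used with cylindrical diode arrays and dose-reconstruction software: a
voxelized cylindrical phantom with a target and two organs-at-risk, five-field
conformal plans for target diameters of 1–9 cm, a synthetic 1,386-diode
helical detector with controllable measurement error models, 2D and 3D gamma
analysis, back-projection of per-beam diode discrepancies into a perturbed
("predicted") 3D dose, DVH metrics, and the replicated experiment with its
statistics (t-test, one-way ANOVA, Pearson correlation).

It is written for medical-physics and QA-methods researchers who want a fully
specified, testable reference chain: every synthetic measurement has a known
truth, so the behavior of gamma criteria, reconstruction and DVH metrics can
be validated rather than assumed.

## The core quantities

**Gamma index** (global normalization): for an evaluation point `p` with dose
`De(p)` against a reference field `Dr`,

    gamma(p) = min over |r - p| <= R of
               sqrt( |r - p|^2 / dta^2  +  (Dr(r) - De(p))^2 / (tol * Dnorm)^2 )

with criteria 3%/3 mm and 2%/2 mm, `Dnorm` the maximum of the planned 3D dose,
and a 5% low-dose threshold. `gamma <= 1` passes; the passing rate is the
percentage of evaluable points that pass. The 2D variant runs on the unwrapped
detector cylinder (arc length × z, periodic in angle); the 3D variant runs on
voxel grids restricted to ROI masks. A brute-force oracle validates the
engine.

**Dose reconstruction**: per beam, relative diode errors `measured/planned - 1`
are interpolated into smooth error surfaces on the entry and exit hemispheres
of the detector cylinder, then back-projected multiplicatively along each
beam with a depth-linear entry/exit blend. Zero errors reproduce the planned
dose bit for bit; a uniform injected error is recovered exactly.

**DVH metrics**: voxel-counting cumulative DVHs; Dmean, D50, D95 (largest
dose covering the stated volume fraction, interpolated between 1 cGy bins);
dose deviation `100 * |a - b| / b`.

## Worked example

```r
library(virtualqa)

grid <- make_grid(spacing_mm = c(2, 2, 2))      # 2 mm fast profile
rois <- roi_set(grid, 50)                       # 5 cm target + OARs
plan <- compose_plan(50, 600, grid, rois = rois)
#> <qa_plan> target 50 mm, prescription 600 cGy, 5 beams, norm factor 1502

geo <- build_geometry()
#> <qa_diode_geometry> 1386 diodes (66 cols x 21 rows), R = 105 mm, angular pitch 5.45 deg
planned <- sample_dose_at_diodes(plan, geo)

# measurement with a +2% calibration offset, the field-size-dependent diode
# response and 0.5% reading noise
em <- error_model(global_scale = 0.02, noise_sd = 0.005, seed = 42)
meas <- simulate_measurement(planned, plan, em, replicate = 1)

gamma_map_diode(meas, plan$total_dose, geo, gamma_criteria(3, 3))
#> <qa_gamma> 3%/3mm: 336 evaluable points, passing rate 100.00%

perturbed <- reconstruct_dose(plan, meas, planned)
dose_deviation_pct(predicted_isocenter(perturbed),
                   isocenter_dose(plan$total_dose))
#> [1] 0.9704  # +2% global and ~-1% field-size response nearly cancel

dvh_metrics(perturbed, rois$target, 600)$mean_pct
#> [1] 110.6   # % of prescription

gamma_map_grid(perturbed, plan$total_dose, gamma_criteria(2, 2),
               roi = rois$adjacent)
#> <qa_gamma> 2%/2mm: 12100 evaluable points, passing rate 100.00%
```

The isocenter deviation shows the two error mechanisms interacting: the +2%
calibration offset is partly cancelled by the diode field-size response,
which is about −1% for this plan's 5.5 cm equivalent square. The 100% passing
rates are the expected outcome for ~1% errors under 3%-of-maximum criteria.

## The analysis workflow

The study itself lives in numbered scripts under `analysis/`, thin drivers
over the package functions that write their tables under `results/`:

```sh
Rscript analysis/01_phantom_and_plans.R    # ROI volumes, plan coverage summary
Rscript analysis/02_experiment.R           # full 5 sizes x 3 replicates study
Rscript analysis/03_error_mechanisms.R     # isolated error mechanisms
```

`02_experiment.R` produces machine-readable analogs of a QA study's report
tables: isocenter dose deviations, 2D diode and 3D ROI passing rates per
gamma criteria, planned-vs-predicted DVH metrics with t-tests, DVH deviations
with ANOVA across target sizes, and deviation-vs-passing-rate correlations.

## Package layout

- `R/` — grid and ROI construction, planner, detector simulator, gamma
  engine, reconstruction, DVH metrics, experiment driver and statistics
- `src/` — the C++ gamma search kernel (Rcpp)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/virtual-delivery-qa.Rmd` — models, assumptions, numerical
  choices and limitations
- `analysis/`, `scripts/` — the study drivers described above
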