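---
title: "Virtual delivery QA with a helical diode array: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual delivery QA with a helical diode array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualqa)
```

## What this package models

Before a radiotherapy plan is delivered to a patient, delivery quality
assurance (QA) verifies that the machine actually produces the planned dose.
A common workflow measures each beam with a cylindrical diode array, compares
measured to planned dose with the gamma index, back-projects the per-beam
discrepancies into the planned 3D dose to obtain a "predicted" delivered
dose, and finally compares dose-volume-histogram (DVH) metrics of the
predicted and planned distributions.

`virtualqa` implements that entire chain as an open, testable simulation: a
voxelized cylindrical phantom with a target and two organs-at-risk (OARs),
five-field conformal plans over a range of target sizes, a synthetic
1,386-diode helical detector with controllable measurement error models, a
gamma engine (2D on the detector surface, 3D on voxel grids), a documented
dose-perturbation reconstruction, DVH metrics, and the statistical
comparisons (t-test, one-way ANOVA, Pearson correlation) that a QA study
reports. Because the measurement is synthetic, every downstream quantity has
a known ground truth, which is what the test suite exercises.

## Phantom, ROIs and coordinate conventions

The phantom is a homogeneous water cylinder inside a 26.5 × 26.5 × 27.0 cm
box, voxelized on a regular grid (1 mm spacing by default; the analyses and
tests use a 2 mm fast profile, see "Problem sizes" below). The isocenter is
the physical origin and lies on a voxel center; x and y span the axial
plane and z is the cranio-caudal axis.

Three ROIs are built per target size $d \in \{1, 3, 5, 7, 9\}$ cm, all 5 cm
long and coaxial with z:

* **target** — a cylinder of diameter $d$;
* **adjacent OAR** — a 1 cm thick annulus directly around the target (the
  high-dose-gradient region);
* **peripheral OAR** — a 1 cm thick rim annulus of fixed geometry (outer
  diameter 21 cm, matching the detector cylinder), identical for every
  target size (the low-dose region).

A voxel belongs to an ROI iff its **center** is inside the shape
(boundary-inclusive; no partial-volume weighting). The annulus uses the
half-open radial interval $(r_{in}, r_{in} + t]$ so that target and adjacent
OAR are exactly disjoint. Mask volumes therefore differ from
$\pi r^2 L$ only through lattice discretization; for the 1 cm target the
12 integer lattice points that lie exactly on the $r = 5$ mm circle put the
discretized volume about 3% above the analytic value, a known property of
the contouring rule (tests pin the exact lattice counts).

## The beam model

A commissioned pencil-beam engine is out of scope; the planner instead uses
a smooth closed-form model with a realistic dose topology:

$$D(v) \;=\; F(u, w)\; \cdot\; \mathrm{PDD}(z_d)\; \cdot\;
\left(\frac{\mathrm{SAD}}{\mathrm{SAD} + z_d - d_{max}}\right)^2$$

* **Fluence** $F$: the beam's-eye-view (BEV) aperture — the parallel
  projection of the target, dilated isotropically by the 3 mm MLC margin and
  clipped to the 10 × 10 cm field limit — convolved with a 2D Gaussian of
  $\sigma = 3$ mm (penumbra).
* **Depth dose**: rises linearly from 0.5 at the surface to 1.0 at
  $d_{max} = 15$ mm, then decays as $e^{-\mu (z_d - d_{max})}$ with
  $\mu = 0.005\,\mathrm{mm}^{-1}$.
* **Inverse square**: SAD = 1000 mm.

Depth $z_d$ is measured along the beam axis from the entry point on the
**curved cylindrical phantom surface** (radius = half the in-plane grid
extent), and the dose is zero outside that cylinder. A box-shaped entry
surface was considered and rejected: the box is not rotation-invariant, so
the five per-beam doses of an axially symmetric target would not be
congruent under the 72° gantry rotations — a symmetry the cylindrical
detector phantom physically has and the test suite asserts.

All model parameters live in one `beam_model()` block so tests can pin them.
They are model constants chosen once for realism (a 6 MV-like attenuation
and penumbra), not fitted quantities.

### Plans and normalization

Each plan uses five static fields at gantry 0/72/144/216/288° with equal
weights (the study does not state weights) and a size-matched prescription
of 200–1000 cGy. The summed dose is scaled so that **D95 of the target
equals the prescription** (coverage normalization, computed from the exact
voxel percentile). The original study reports a planned D95 of ≈ 99.3% of
prescription despite a 95%-coverage goal; its exact treatment-planning
normalization is unrecoverable, so this package normalizes to D95 = 100%
and says so. Plans run hot at the isocenter (≈ 110–120% of prescription),
as conformal plans do.

## The synthetic detector

The detector is a single staggered helical lattice: 66 angular columns × 21
axial rows = 1,386 diodes on a cylinder of 21 cm diameter and length, 10 mm
pitch along both the helix arc and the axis, 360/66 = 5.4545° between
columns. Consecutive columns are offset axially by pitch/66, so following
the angle the lattice advances one pitch per revolution — a genuine helix
that satisfies every stated count/pitch/size constraint. (Commercial arrays
interleave two such grids; a single helix reproduces the published
constraints and keeps the lattice analytically invertible.)

The planned reference reading is the trilinear interpolation of each
per-beam planned dose at each diode position; the composite is the per-beam
sum, exactly.

### The measurement error model

`simulate_measurement()` produces a replicate reading per beam $b$ and diode
$i$:

$$m_{ib} = D_b(p_i - s)\cdot (1 + g)\cdot f(\mathrm{sq}_b) \cdot
(1 + \varepsilon_{ib}), \qquad \varepsilon_{ib} \sim N(0, \sigma_n)$$

* **Rigid setup shift** $s$: readings re-sample the planned dose at the
  shifted positions.
* **Global calibration scale** $g$.
* **Field-size diode response** $f$: piecewise-linear through the published
  calibration points (−1.1% at a 5 × 5 cm equivalent square, +1.3% at
  25 × 25 cm), linearly extrapolated outside, applied per beam via the
  aperture's equivalent square $2ab/(a+b)$. Entry and exit readings get the
  same factor (the simplest model that reproduces the mechanism; whether
  the physical effect differs between entry and exit is unknown).
* **Reading noise** $\varepsilon$: multiplicative, independent per diode ×
  beam × replicate. The default $\sigma_n = 0.5\%$ is a typical short-term
  delivery/diode reproducibility figure and gives replicate spreads of the
  same order as the published tables; it was chosen once as the study
  condition, not tuned.

Replicate $r$ of a measurement uses RNG seed `em$seed + r`; the experiment
driver gives target size $i$ the base seed `seed + 1000 (i − 1)` so sizes
are decorrelated. With the whole error model off, the simulated reading is
bit-identical to the planned reference, which anchors the clean-chain
identity tests.

The deterministic part of the error model applied at the dose-grid level
(`delivered_dose()`) is the ground-truth delivered dose; sampling it at the
isocenter is the ion-chamber analog, with one multiplicative noise draw per
replicate to emulate repeated chamber readings.

Note one deliberate consequence of the published calibration line: all five
plans have equivalent squares of only 2.5–7 cm, where the response is −1.4%
to −0.9% — below both gamma criteria under global normalization. The
mechanism (monotone error growth with field size) is reproduced exactly, but
it does not by itself push passing rates below 100%; the magnitudes of the
published physical rates also contain machine-delivery effects that a desk
simulation cannot reproduce, so the package's claims about them are
property-based (ordering and monotonicity), not numerical.

## The gamma engine

For evaluation point $p$ with dose $D_e(p)$ against reference field $D_r$:

$$\gamma(p) = \min_{|r - p| \le R}
\sqrt{\frac{|r-p|^2}{\delta^2} + \frac{(D_r(r) - D_e(p))^2}{(\tau\, D_{norm})^2}}$$

with DTA $\delta$ (3 or 2 mm), dose tolerance $\tau$ (3% or 2%) of the
**global normalization dose** $D_{norm}$, and a 5% low-dose threshold
applied to the reference dose at the evaluation point. Numerical choices:

* search ball $R = 3\delta$ (refused if smaller), reference interpolated
  trilinearly on a fine step of $\delta/3$ (a step above the DTA is refused
  as undersampled, never silently degraded);
* offsets are scanned in order of increasing distance with an early exit
  once the distance term alone exceeds the running minimum (the hot loop is
  C++);
* $\gamma \le 1$ passes (boundary inclusive); the passing rate is computed
  only over evaluable points, and an empty evaluable set is an explicit
  error, never 0% or 100%;
* 2D diode gamma lives on the unwrapped cylinder surface (arc length × z)
  with periodic angular wrap; a surface offset looks the reference up at the
  corresponding 3D cylinder point. $D_{norm}$ defaults to the maximum of the
  planned 3D dose (the global convention of the emulated software) and is
  configurable — e.g. the maximum planned diode reading, the scale on which
  a uniform local error of 4% can actually trip a 3%-of-maximum criterion
  in this geometry (entry diodes sit at ~28 mm depth and read only ~45% of
  the 3D maximum, which lies at the isocenter where five beams overlap).

A brute-force oracle (`brute_force_gamma_point()`, plain vectorized R with
its own offset enumeration and interpolation) validates the engine; at the
engine's own fine step the two agree exactly, and the suite asserts
agreement within 0.02 on 200 random points of a smooth random field for both
criteria. Lattice gamma is an upper bound of the continuum value with a
first-order step dependence; consequently, pointwise comparisons *across*
criteria (whose lattices differ) carry an offset of up to ~0.2 for sub-1
values even though the continuum identity is
$\gamma_{3/3} = \tfrac{2}{3}\gamma_{2/2}$. Pass/fail status and passing
rates are unaffected in practice and are what the invariants assert.

## Dose reconstruction (the perturbation analog)

The commercial planned-dose-perturbation workflow is proprietary; this
package implements an openly documented analog and claims no equivalence to
it:

1. **Per-beam sparse errors**: $e_i = m_{ib}/D_{ib} - 1$ at every diode with
   planned per-beam dose above an exclusion floor (1% of the beam's diode
   maximum — ratios below it are unstable; excluded diodes are counted, not
   NaN). Diodes split into the beam's entry and exit hemispheres by the sign
   of the position·direction dot product.
2. **Smooth error surfaces**: per hemisphere, the sparse errors are
   interpolated over the unwrapped cylinder surface. The staggered helix is
   a perfect rectangular lattice in sheared coordinates
   $(\alpha, \rho) = (s/\text{arc pitch},\ (z - \text{stagger}(\alpha))/\text{pitch})$,
   so bilinear interpolation there is exact at the diodes, bounded by the
   sparse value range, exact for fields linear in $(s, z)$, periodic in the
   angle, and clamps to nearest values outside the lattice span. (A
   triangulated barycentric scheme was the design alternative; the sheared
   bilinear has the same guarantees with no triangulation machinery.)
   Lattice slots without a retained value inherit the nearest retained
   error before interpolation.
3. **Back-projection**: for voxel $v$ and beam $b$, the ray along the beam
   through $v$ pierces the detector cylinder at an entry and an exit point;
   the voxel error is the depth-linear blend
   $e_b(v) = (1-w)\,e_{entry} + w\,e_{exit}$ with $w$ the fractional depth
   along the chord (the blend exponent of the commercial tool is unknown;
   linear is the declared assumption). Each per-beam dose is scaled
   multiplicatively by $1 + e_b(v)$ — multiplicative propagation preserves
   non-negativity and matches the ratio-style deviation metrics — and the
   total is re-assembled with the plan normalization. Voxels outside the
   detector cylinder take the nearest-surface error.

Zero errors reproduce the planned dose bit for bit; a uniform injected
scale $s$ is recovered in the isocenter and target mean dose to well within
0.1% for $|s| \le 4\%$; an error confined to one beam only perturbs that
beam's dose shadow.

## DVH metrics and deviations

Cumulative DVHs use exact voxel counting (no partial-volume weighting) on
1 cGy bins. $D_x$ is the largest dose whose volume fraction is still at
least $x\%$, linearly interpolated between bin edges (the emulated planning
system's convention is unstated; this one is documented and monotone). The
scalar metrics are the ROI mean dose, D50 for all ROIs and D95 for the
target, each also expressed as % of prescription, and the deviation metric
is $100\,|a - b|/b$ (absolute value — signs are discarded). Scaling
equivariance is exact when the bin width is scaled with the dose; at fixed
bin width the binning contributes at most one bin of discretization, which
is how the tests phrase their tolerances.

## The replicated experiment and its statistics

`run_experiment()` chains everything per size and replicate and aggregates
machine-readable analogs of the study's Tables 2–7: isocenter deviations,
2D and 3D passing rates per criteria (and per ROI), planned-vs-predicted
DVH metrics, DVH deviations, and Pearson correlations between DVH deviation
and the ROI's 3D passing rate over all size × replicate cells. Statistical
conventions, chosen where the study is silent: pooled-variance two-sided
t-test (a Welch flag exists), one-way fixed-effects ANOVA across sizes,
two-tailed Pearson p from the t transform, significance at 0.05, no
multiple-testing correction (the study applies none). Degenerate inputs are
guarded: all-identical groups give F = 0, p = 1; zero-variance equal-mean
samples give t = 0, p = 1; a constant correlation input is an error, which
the report converts to an NA cell (this happens when passing rates sit at
100% across all cells). With one replicate, SD columns and ANOVA are
omitted rather than fabricated.

Everything is deterministic given the config seed: identical configs yield
byte-identical reports.

## Problem sizes and runtime

The package default grid is the study's 1 mm spacing. The test suite, the
analysis scripts and the acceptance script run the 2 mm fast profile
(133 × 133 × 135 voxels), where the full 5 × 3 experiment completes in
about a minute on one core; the clean-chain identities hold at any spacing
by construction. The diode lattice, gamma criteria and error models are
spacing-independent.

## What passing tests do and do not show

The synthetic measurement reproduces the *structure* of the physical
experiment — geometry, error mechanisms, replicate design — with known
ground truth, so the suite can assert exact identities (clean chain,
recovery of injected errors) and qualitative orderings (criterion
monotonicity, size-monotone field-size error). It does not emulate machine
delivery (leaf calibration, gantry sag, angular diode response, dose-rate
effects), so the published numerical passing rates and their strict decrease
with target size are not reproduced — under the published response
calibration alone, all rates sit at 100%. Conclusions about real hardware
require real measurements; what this package offers is a transparent,
fully-specified reference chain on which QA analysis methods can be
validated.

## Limitations

* Single-helix detector (not two interleaved grids); no angular sensitivity,
  dose-rate, or temperature models.
* Toy beam model: no heterogeneity, no divergence in the BEV projection, no
  leaf-by-leaf MLC fitting (leaf widths are metadata only).
* Reconstruction is a documented analog of a proprietary workflow, validated
  against its own invariants, not against the commercial implementation.
* Local-normalization gamma and time-resolved (arc) reconstruction are out
  of scope.
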