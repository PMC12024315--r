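---
title: "Methods: reduced-order virtual valve replacement hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order virtual valve replacement hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vavr)
```

## Scope and model

Virtual therapy planning for surgical aortic valve replacement asks, for one
patient: how would the transvalvular pressure gradient and the
ascending-aorta flow profile change if the implanted prosthesis were one
label size smaller or larger, and what happens to each option under physical
activity? Full answers come from patient-specific CFD on segmented
anatomy. This package implements everything *around* that step — the
reduced-order gradient model, the flow-profile metrics, the clinical
grading, and the cohort statistics — plus a synthetic data generator so that
the whole pipeline is testable without imaging data.

### Transvalvular chain

Three algebraic relations, composed per (patient, size, state) cell:

1. Continuity through the effective orifice: `Vmax = (Q / EOA) / 100`
   (Q in ml/s, EOA in cm², Vmax in m/s). This treats the orifice jet as the
   site of the velocity maximum and neglects the proximal velocity — the
   same assumption the clinical simplified Bernoulli makes.
2. Simplified Bernoulli: `DP = 4 * Vmax^2` (mmHg). The constant 4 absorbs
   `rho / 2` and the Pa→mmHg conversion. The source study never states how
   its printed gradients relate to its velocities, but every published
   median (Vmax, DP) pair satisfies this relation to printed precision
   (2.1 → 17.64 ≈ 17.6; 1.9 → 14.44; 1.2 → 5.76 ≈ 6), so the package adopts
   it as canonical.
3. Stress: peak systolic flow scaled by `stress_factor = 1.25`, the 25%
   exercise-induced increase measured in aortic-stenosis exercise studies.
   Under a fixed orifice the implied gradient ratio is exactly
   `1.25² = 1.5625`. Observed per-patient CFD ratios deviate from this
   (e.g. 14 → 23 mmHg is ratio 1.64): flow-dependent orifice behavior and
   turbulence are genuinely nonlinear. The generator exposes
   `stress_nonlinearity`, a deterministic multiplicative factor on the
   stress-state gradient (default 0), so both the idealized and the
   empirical regime can be produced; the *predictive* model stays purely
   quadratic.

`calibrate_eoa(q, dp) = q / (100 * sqrt(dp / 4))` inverts the chain. No
manufacturer EOA charts are hard-coded — chart-based mismatch prediction is
known to be unreliable — so EOA maps are user-supplied or calibrated from
data.

### Flow-profile metrics

On a cross-sectional plane with through-plane component `vz` and in-plane
part `(vx, vy)`, over lumen-masked points:

- **NFD** — distance between the unweighted lumen centroid and the centroid
  of forward-flow points (`vz > 0`) weighted by `vz`, divided by the
  equivalent-circle diameter `2 * sqrt(A / pi)`. Weighting by through-plane
  velocity follows the convention of the metric's originators; the
  unweighted variant is available (`weighted = FALSE`) since the source text
  says only "forward flow".
- **WPD** — mean of `|vz| / (|vz| + |v_inplane|)` over nonzero-velocity
  points; 1 for axial flow, 0 for purely in-plane flow.
- **Flow angle** — mean of `acos(vz / |v|)` in degrees over
  nonzero-velocity points.

Averaging domain: *all* nonzero-velocity lumen points, including retrograde
ones, because the definition speaks of "each measured velocity vector";
retrograde vectors contribute angles above 90° rather than being folded.
Whether the original analysis excluded them is unstated, so
`include_retrograde = FALSE` is available. Zero-velocity points are excluded
to avoid 0/0; a fully zero or fully retrograde plane raises an
undefined-metric error rather than returning a number.

### Grading

Stenosis severity by peak velocity: `< 2.5` none, `[2.5, 3)` mild,
`[3, 4]` moderate, `> 4` severe. The 4 m/s severe bound is strict ("above
4 m/s"); the 3.0 m/s mild/moderate boundary is not printed in the source and
is adopted from standard echo grading — it is a configurable threshold set.
Patient–prosthesis mismatch by indexed EOA: `> 0.85` cm²/m² none,
`[0.65, 0.85]` moderate, `< 0.65` severe. Percentile flags mark values
above the healthy 97th or below the 3rd percentile. Healthy *medians* are
published (gradient 6 mmHg, Vmax 1.2 m/s, angle 8°, NFD 0.03, WPD 0.75);
the percentile bounds are not, so `healthy_reference_ranges()` ships
synthetic placeholder bounds that must be replaced with cohort-derived
percentiles for any clinical interpretation.

### Statistics

Paired comparisons use the Wilcoxon signed-rank test (zero differences
dropped — Wilcoxon's original convention, consistent with the published
W = 55 for ten all-positive differences; mid-ranked ties), independent
comparisons the Wilcoxon–Mann–Whitney test. Reported statistic for the
latter is `U = #{x2 > x1} + 0.5 #ties`, so `U / (n1 n2)` *is* the relative
effect `p_rel` and `U + U' = n1 n2`. Exact p-values come from in-package
null-distribution recursions (signed-rank: generating-function convolution,
n ≤ 25; rank sum: subset-sum dynamic program, n1·n2 ≤ 10 000), used when the
data are tie-free; otherwise a tie-corrected normal approximation with
continuity correction. All tests are two-sided (the source reports
sidedness nowhere). Benjamini–Hochberg adjustment is applied within the
family of comparisons returned by each wrapper (`compare_valve_sizes`,
`compare_stress`, `compare_to_healthy`) — the source does not state its
family boundaries, so the family is whatever set of p-values you pass to
`bh_adjust()`.

Two published statistics are knowingly *not* reproduced: the paired-gradient
W values of 81.5/78.5/77.0 (impossible for a signed-rank sum with n = 10,
whose maximum is 55) and the rest/stress relative effects of 0.18/0.21/0.23
(not reproducible from the rounded per-patient table under the stated
definition). Both are flagged upstream as inconsistencies of the source.

## The synthetic generator: what it emulates, what it does not

`make_jet_plane()` builds a single peak-systolic plane: a circular lumen of
radius `lumen_radius` (default 15 mm, ascending-aorta scale) on a square
lattice (`grid_spacing`, default 0.5 mm, the CFD base mesh scale), carrying
a plug (default) or parabolic jet of radius `jet_radius` displaced by
`jet_center_offset`. The plug default is deliberate: the velocity-weighted
centroid of a symmetric patch is its centre, so NFD has the exact closed
form `|offset| / (2 * lumen_radius)` and the generator is verifiable.
Tilt keeps the through-plane profile and adds a uniform in-plane component
`vz * tan(tilt)`, so every jet vector deviates from the normal by exactly
`tilt_deg` (and `|v| = peak / cos(tilt)`). Swirl is solid-body rotation
about the jet centre reaching `swirl_strength` m/s at the wall — the
simplest field with nonzero in-plane energy, giving a computable WPD
depression. Retrograde flow is uniform outside the jet. Gaussian noise
(`noise_sd`) is added per component inside the lumen only.

`make_cohort()` emulates the 3 × 2 study design: `n_patients` (default 10)
with resting flows uniform on 235–539 ml/s (the span of the study cohort),
reference sizes drawn from {23, 25} mm so a smaller and larger neighbour
always exist in the EOA map, gradients from the transvalvular chain, and
flow-profile metrics drawn per patient — NFD from
`nfd_distribution` (default N(0.12, 0.04), the published patient median),
WPD from N(0.44, 0.06) and angle from N(28°, 6°) (the published medians;
the spec leaves these unspecified) — held approximately constant across
sizes and states with a small cell-level jitter, emulating the study's
finding that profile shape belongs to the patient's aorta, not to the valve
size or activity state. The default EOA map (21→1.7, 23→2.0, 25→2.3,
27→2.6 cm²) is synthetic: monotone in label size and scaled so typical flows
give low-teens gradients; it is not a manufacturer chart.

What the generator does **not** emulate: 3D velocity structure, time
resolution (cine), secondary-flow physics (helicity, wall shear stress),
non-circular lumens, measurement-specific artifacts (phase wraps, eddy
currents), or any correlation between gradient and flow-profile
abnormality. A green test on synthetic data therefore establishes the
*correctness of the computations*, not the physiological fidelity of the
inputs; the per-patient CFD results enter only as a bundled fixture.

## Numerical choices

- Metrics on a lattice carry a discretization error through the
  equivalent-circle diameter; tests verify the error shrinks under grid
  refinement rather than asserting lattice-free values exactly.
- `acos` arguments are clamped to [−1, 1] against roundoff.
- Exact-test paths require tie-free data; with ties the tie-corrected normal
  approximation is used (mid-ranks throughout). Degenerate signed-rank input
  (all differences zero) returns p = 1 by convention.
- Two-sided exact p-values double the smaller tail including the observed
  value, capped at 1.
- CSVs are written with 17 significant digits so write→read round trips are
  exact; rounding happens only at presentation.
- Seeds: every stochastic routine takes an explicit integer seed and uses a
  private RNG stream, leaving the caller's `.Random.seed` untouched;
  identical parameters and seed give bit-identical output.

## Known limitations

- The reduced-order chain cannot reproduce per-patient CFD nonlinearity
  (pressure recovery, flow-dependent orifice area); it is a planning-level
  approximation validated against cohort medians, not per-patient values.
- The healthy percentile bounds shipped are placeholders (see above).
- The analysis plane's anatomical position is abstract; the source does not
  report where in the ascending aorta its plane sat.
- Exact rank tests switch to approximations in the presence of ties, which
  is where published small-sample tables most often disagree between
  software implementations.
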