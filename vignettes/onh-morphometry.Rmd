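---
title: "ONH morphometry and longitudinal OHT analysis: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ONH morphometry and longitudinal OHT analysis: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhmorph)
```

This vignette documents the models behind `onhmorph`, the conventions and
numerical choices it commits to where the underlying methodology leaves them
open, and what its synthetic data do and do not establish about real OCT
data.

## 1. The measurement problem

In experimental ocular hypertension (OHT), the earliest structural damage at
the optic nerve head (ONH) appears as thinning of the neuroretinal rim and
posterior deformation of the lamina cribrosa (LC), well before retinal nerve
fibre layer loss. Two OCT-derived scalars capture this: the **minimum rim
width** (MRW) — per Bruch's membrane opening (BMO) point, the shortest
distance to the internal limiting membrane (ILM) — and the **lamina cribrosa
depth** (LCD) — the perpendicular distance from the BMO reference plane to
the anterior LC surface. `onhmorph` takes *segmented* surfaces as input (ILM
and anterior-LC height grids plus an ordered BMO ring); raw B-scan
processing, shadow compensation and the delineation itself are out of scope.

Grids follow the scanner lattice (default 73 B-scans × 384 A-scans over a
15°×15° field; 62 µm between B-scans). The lateral A-scan spacing is not part
of the scan metadata at acquisition; the default 11.6 µm makes the A-scan
direction span the same physical field as the B-scan direction. Because no
axial-length-based rescaling is applied (none of the source measurements
re-scaled the lateral dimensions either), the spacing is an explicit,
user-settable parameter rather than a hard-coded eye model. Axial
coordinates are micrometres with **larger z = more posterior**.

## 2. Morphometry: definitions and conventions

**BMO reference plane.** The reference methodology names the plane but not
its construction. We use orthogonal (total) least squares — the plane through
the centroid whose normal is the smallest principal axis of the centred ring
— because it is deterministic, symmetric in all three coordinates, and the
standard "reference plane" reading in the OCT morphometry literature. The
normal is oriented posteriorly (positive z, ties toward +z); `svd()` provides
the fit; the RMS perpendicular residual is reported. Fewer than 3 points or a
collinear ring is an error.

**BMO area.** Ring vertices are projected into the plane, ordered by angle
about the centroid, and the shoelace area is returned in mm². An inscribed
n-gon underestimates a smooth opening by ~`2π²/(3n²)` relatively (0.16% at
n = 64), vanishing quadratically — the test suite checks this convergence
order. The area is computed *in the reference plane*; an enface variant would
differ by the cosine of the plane tilt (a design choice documented here
because either reading is defensible).

**Mean LCD.** Every delineated LC node whose projection lies inside the
projected BMO polygon contributes its signed perpendicular distance
(positive = posterior). Anterior excursions count negative rather than being
clamped: this keeps the mean exactly linear in a uniform posterior shift
(verified to machine precision in the tests) and makes "deepening" a
monotone increase. Missing LC is never interpolated. On-boundary projections
count as inside (tolerance 1e−9 µm) — a deterministic tie-break.

**Mean MRW.** The ILM grid is triangulated (two triangles per cell; cells
touching a missing node are skipped). The published constraint — MRW must
stay within the neuroretinal rim bounded by the BMO — states an intent, not
a mechanism. We implement admissibility as: *a triangle is admissible when
its centroid projects inside the BMO polygon on the reference plane*. The
rule is isolated in a single predicate (`admissible_ilm_triangles()`) so an
alternative reading can be substituted without touching the distance code.
Distances use the exact closest-point-on-triangle computation (face, edge
and vertex regions), no approximation; a brute-force oracle
(`mrw_pointcloud_oracle()`) that densely subsamples admissible triangles
bounds the implementation from above and agrees with it to ≲0.01% on all
phantom shapes. Because admissibility is resolved at grid-cell granularity,
per-point MRW on an analytically flat rim can deviate from the exact value
by up to roughly `(cell/2)² / (2·MRW)` — about 0.2 µm at the default lattice.
If more than 25% of the ILM inside the BMO is missing the result is flagged.

**LC visibility.** The enface BMO polygon is rasterised with cell-centre
inclusion; visibility is 100 × (inside cells with delineated LC) / (inside
cells). Numerator and denominator share the raster deliberately: a fully
delineated LC then scores exactly 100, and the wedge phantoms recover their
constructed fraction to within the rasterisation tolerance of the default
lattice (on the order of 1 percentage point; the exact deviation depends on
how the wedge radii cut the cell rows, so it varies with the wedge position).

All measures are invariant under rigid motions of the inputs and stable to
<0.5% under a doubling of the lateral grid resolution (tested).

## 3. The phantom generator

`make_phantom_volume()` replaces manual delineation with constructed
surfaces whose morphometry is known:

- **BMO**: ellipse (default semi-axes 950 × 880 µm → area 2.63 mm², the
  healthy-primate scale), optionally tilted about the A-scan axis; the ring
  lies exactly on it.
- **ILM**: a rim-and-cup surface — `cup_depth` posterior at the centre,
  `rim_height` anterior at and beyond the ring (defaults 350/280 µm; MRW at
  the default is therefore the rim height, matching baseline primate MRW).
  The radial profile is a *quintic* smootherstep: zero slope **and zero
  curvature** at both ends, so the triangulated grid's chord error is
  negligible exactly where the MRW foot points live. `cup_depth =
  -rim_height` degenerates to a flat ILM for closed-form checks.
- **LC**: flat (parallel plane at perpendicular depth `lc_depth`, default
  200 µm), tilted (linear in x), or bowl (paraboloid, default 60 µm central
  sag). Heights are stored as vertical offsets `d/cosθ` so the perpendicular
  depth is exactly `d` under plane tilt θ.
- **Visibility**: a contiguous angular wedge of LC nodes is removed —
  mimicking shadowing, unlike i.i.d. dropout — using the *elliptic
  parametric* angle, so the removed area fraction equals
  `1 − lc_visible_fraction` exactly. The wedge position derives
  deterministically from the seed.

Truth values are closed-form where exact (flat LC: `lc_depth`; tilted or
bowl LC over the full ellipse: `lc_depth` and `lc_depth + sag/2`; ellipse
area `πab`; visibility `100·f`) and otherwise computed by dense integration
of the analytic surfaces on a 10×-oversampled lattice. Truth always refers
to the noise-free surfaces; `surface_noise_sd` perturbs only the stored
grids.

## 4. The cohort simulator

`generate_cohort()` emulates a 16-animal, 28-week study: 10 animals with
unilateral OHT (right eye injected, left eye an untreated control) and 6
with bilateral OHT at a lower target pressure.

**IOP dynamics.** A literal additive reading of the published protocol is
internally inconsistent (re-injection stops once IOP exceeds 30 mmHg in
Group 1, yet the period mean is ~43; ~6 injections over ~5 weeks, yet IOP
stays ≤20 for the first month). We therefore model a *saturating bead-load
response*: each injection adds `injection_effect` (default 5) to a
cumulative dose; the target IOP is a logistic function of dose between the
eye's baseline and the group plateau (43 mmHg in Group 1, 31 in Group 2;
`dose_half = 22`, `dose_slope = 3.5`); the weekly IOP state relaxes toward
the target at `relax_rate = 0.6`/week. Injections are evaluated weekly (at
most one per week, matching the tonometry cadence) whenever the previous
measured IOP is below the group's re-injection threshold (30/20 mmHg).
Under noise-free Group-1 defaults this yields 6 initial injections and
onset at week 4–5, reproducing the published induction course; the
stochastic means are ~5.9 injections and onset week ~4.9.

Measured IOP adds two noise components: tonometry error (`sd = 1.2` mmHg —
a weekly reading is the mean of five rebound-tonometry reads, and the
published per-animal baseline SDs of 0.4–2.9 mmHg bound it) and a
physiological fluctuation proportional to the elevation above baseline
(fraction 0.45, set by the published within-animal OHT-period SDs of 10–21
mmHg). Control eyes drift toward a consensual rise of +6 mmHg (ramping over
8 weeks, on by default because the source study observed it; switchable
off).

**Onset rule.** "More than two consecutive readings above 20 mmHg" is read
as a run of **≥ 3** weekly readings; `run_length` is a parameter (set it to
2 for the other reading). `detect_onset()` is monotone in the threshold.

**Structural trajectories.** Monthly MRW/LCD increments are
`slope × (monthly mean-IOP increment) + noise`. Because the IOP rise
concentrates in the month 1→2 interval, the largest structural change lands
there automatically, and setting the slopes to zero freezes the
trajectories — both properties are tested. The default slopes are
*calibrated*: the anchors (−93 µm MRW, +86 µm LCD — the published Group-1
month-1→2 changes, used here as generator parameters) are divided by the
expected Group-1 month-1→2 IOP rise, estimated once per parameter set by
Monte Carlo over a fixed internal seed stream (n = 400) and memoised. A
noise-free reference would overestimate the rise (onset-timing jitter
spreads it across month boundaries), biasing recovery by ~5%. Coupling is
to the *concurrent* month's rise; `structure_lag` shifts it. Trajectory
noise SDs are derived from the anchor SDs (42 / 79.6 µm).

**What the simulator does not claim.** It is a calibration instrument for
the analysis code, not a biophysical model: no microbead/outflow mechanics,
no per-quadrant structure, no floor effects, no measurement error on MRW/LCD
beyond the trajectory noise, group-wise centring rather than the real
between-animal susceptibility spectrum. Passing tests show the estimators
recover known generating parameters under the study's design and noise
scales — not that the model reproduces any particular animal.

## 5. Longitudinal statistics

- **Monthly aggregation**: fixed 4-week blocks anchored at study week 1
  (month m = weeks 4(m−1)+1 … 4m); the source does not define month
  boundaries, so this convention is ours. Missing weeks are dropped from a
  block; empty blocks are omitted. Month 0 is the baseline visit.
- **Per-interval changes**: mean, sample SD (n−1), and a two-sided paired
  t-test. The original analysis used a repeated-measures mixed model; the
  t-test is a documented substitution, so published mixed-model p-values are
  sign/ordering references only, not reproduction targets. All-equal
  differences report p = 1 with a `degenerate` flag; a single selected row
  reports SD 0 with a flag. No multiplicity correction is applied (none was
  in the source analysis).
- **Partial correlation**: within-subject centring of both variables (the
  residual of a regression on subject indicators), Pearson correlation of
  residuals; df = n − k − 1 for k subjects; Fisher z uses
  `√(n − (k−1) − 3)`. With one subject this reduces exactly to the ordinary
  Pearson correlation with df = n − 2. The df accounting is stated here
  because the methodology names the method but not the bookkeeping. |ρ̂| = 1
  yields an infinite statistic, reported with p = 0 and a flag. Under a
  simulated null (16 subjects × 7 visits, 2000 replicates) the empirical
  type-I error at α = 0.05 is ≈0.05 (tested against the [0.035, 0.065]
  band).

## 6. Problem sizes and tolerances used in the checks

The test suite and `scripts/acceptance.R` run at the sizes we consider
statistically meaningful for each claim: 5–6 phantom shapes at the native
73 × 384 lattice with 10× oversampled oracles; 100 seeds for the induction
course; 200 seeds × 256-row cohorts for parameter recovery (SE of the
month-1→2 mean change ≈ 0.8 µm, comfortably inside the ±5 µm recovery band)
and for the correlation-sign rate; 2000 replicates for the test-size check.
Phantom recovery is asserted at 1% (closed-form cases at machine precision),
oracle agreement at 0.5%, where the observed errors are an order of
magnitude smaller.

## 7. Known limitations

- The rim-constraint mechanism (triangle-centroid admissibility) is one
  reasonable reading of a stated intent; alternatives (vertex-based,
  foot-point-based) would differ at the fraction-of-a-micron scale at grid
  resolution.
- BMO area is an inscribed polygon: at low ring vertex counts (< 32) the
  deficit exceeds 1%.
- Visibility is raster-based; for very small openings (few grid cells) the
  ±1-percentage-point tolerance is optimistic.
- The IOP model's dose–response constants are phenomenological; only their
  emergent statistics (injections, onset week, period mean/max) were matched
  to the published induction course.
- Fixture tables store printed per-animal summary values; the per-animal
  SDs' averaging basis (across readings vs across weeks) is not defined by
  the source and is deliberately not reinterpreted — only across-animal
  statistics are recomputed from them.
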