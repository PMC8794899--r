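---
title: "Estimating cochlear duct length: models, synthetic data and method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cochlear duct length: models, synthetic data and method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlkit)
```

`cdlkit` implements the three clinically used routes to the cochlear duct
length (CDL) — 3D spline measurement of a segmented lateral wall, the
A-value (Escudé) formula, and the elliptic-circular A/B-value formula — an
insertion-angle-based reference, and the statistics used to compare them.
This vignette is the package's account of the underlying models, the
synthetic data that stands in for cadaver anatomy, and the numerical choices
made where the methods literature leaves the details open.

## 1. Coordinate conventions and the canonical frame

All geometry lives in a canonical *modiolar frame*: the spiral (modiolar)
axis is the z-axis, the basal turn lies in the xy-plane (the mean z of the
first 360° is zero), and the round window (RW) sits at unwrapped angle
θ = 0. Angles are **degrees**, unwrapped continuously along the wall (a full
cochlea covers about 900°, i.e. 2.5 turns); lengths are **mm**. θ increases
from base to apex, counterclockwise about +z. A left cochlea is a mirror
image of a right one; rather than maintaining two sign conventions we align
left ears into the same right-handed frame (the cloud is viewed "as a right
ear") and record the side, which keeps every downstream formula
side-agnostic.

### Axis estimation

`align_cochlea()` has to find the modiolar axis from the wall points alone.
It iterates two linear estimates to a fixed point:

* **center**: the radius profile `r(θ)` of a spiral around the *wrong*
  center picks up a first-harmonic term whose cosine/sine coefficients are
  exactly the in-plane center offset. We regress `r` on a polynomial
  baseline plus first and second harmonics and subtract the fitted
  first-harmonic coefficients.
* **tilt**: a residual tilt of the axis appears in the height profile as
  `z ≈ baseline(θ) + a·x + b·y`; the fitted slopes define the current plane
  normal `(−a, −b, 1)`, which is rotated onto z.

Details that matter and were found the hard way:

* The regressors use angles measured relative to the first point, so the
  fitted first-harmonic coefficients live in a basis rotated by that point's
  absolute polar angle; they must be rotated back before being applied as
  x/y corrections. Omitting this makes the iteration diverge for roughly
  half of all input orientations.
* The baseline must be *less* flexible than a first harmonic over the
  observed span. Over 2.5 turns a cubic is safe; over a single turn a cubic
  can track one full cosine cycle and the center becomes ill-determined, so
  clouds spanning less than 540° get a linear baseline.
* The basal turn of a real (and of our synthetic) cochlea is elliptic.
  Unmodelled second-harmonic content leaks into the center estimate, so
  second harmonics are always present in the regression; on multi-turn
  clouds they carry slow polynomial envelopes because the ellipticity fades
  toward the apex.
* A residual tilt perturbs apical polar angles by roughly `z·tilt/r`, and
  the apical radius is small (≈0.5 mm), so the apex can scramble the unwrap
  while the frame is still converging. The regressions therefore exclude
  points with radius below 20% of the 95th radius percentile, and tilt
  corrections are damped to at most 0.1 rad per iteration.

The procedure is rigid-equivariant and idempotent to machine precision
(both are tested), errors on collinear clouds and on spans below 270°, and
converges in well under the default 60 iterations.

## 2. Spline CDL

`fit_lateral_wall_spline()` fits one cubic spline per coordinate against the
unwrapped angle (the natural parameter of a spiral; a chordal
parameterisation is available for non-spiralling point sets such as a
digitised straight segment). Points are ordered by θ, ties collapsed by
averaging.

**Interpolation vs smoothing.** The classical description of the manual
procedure is an interpolating spline through hand-picked points. That is the
right model for sparse, carefully placed points, and `smoothing = "none"`
provides it. It is the wrong model for densely sampled noisy clouds: with
500 points along a ~41 mm wall the spacing is ≈0.086 mm, and 0.1 mm
isotropic jitter makes consecutive steps noise-dominated — an interpolating
curve through such points is several times longer than the wall. The default
`smoothing = "gcv"` therefore fits a cross-validated smoothing spline per
coordinate, which recovers the true arc length to within 1.5% under exactly
those conditions (tested over 50 seeds).

**Arc length** is the integral of the curve speed, computed by composite
15-point Gauss–Legendre quadrature on panels of at most 5°. The rule is
deterministic, vectorised, and accurate far below the 1e-6 mm additivity
tolerance that the tests assert.

## 3. Landmarks A, B, H

* `A` — distance in the xy-projection from the RW to the wall point at
  θ = 180° (the chord through the modiolar axis). On a circle this is the
  diameter; on an axis-centered ellipse with the RW at the major vertex it
  is `2a`.
* `B` — chord between the wall points at θ = 90° and θ = 270°
  (perpendicular to the A line through the axis); `2b` on that ellipse.
* `H` — z-extent of the wall trajectory. A warning is raised when the cloud
  spans less than 1.5 turns, where the apex (and hence H) is ill-defined.

All three are evaluated on the fitted spline, so they inherit rigid
invariance from the alignment.

## 4. Formula estimators and corrections

The two formula estimators are implemented exactly as published:
`2.62·A·ln(1 + θ/235)` (θ in **degrees** — the constant 235 is
degree-valued, and radian input would silently inflate the result, which is
why the package never accepts radians anywhere) and the elliptic-circular
bracket `1.18(A−0.7) + 2.69(B−0.7) − √(0.72(A−0.7)(B−0.7))` scaled by
pBTL(θ).

* `cdl_escude_full()` has a `printed_constant` mode reproducing the
  two-decimal truncation 1.57 of `ln(1 + 900/235) = 1.5748…` that circulates
  in the clinical literature; exact mode is the default (the truncation
  costs ≈0.125 mm at A = 10).
* **pBTL default.** The percentage-of-basal-turn-length profile used by the
  planning software is not published in closed form. The package default
  `pbtl_escude(θ) = ln(1 + θ/235) / ln(1 + 360/235)` reuses the Escudé
  angular shape normalised to 1 at one full turn, is flagged as an
  approximation, and any profile function can be injected. This preserves
  the bracket's meaning (a basal-turn length) without inventing
  coefficients.
* **Corrections.** `to_organ_of_corti()` (×0.9) and
  `apply_resolution_correction()` (×10/9) are recorded on the estimate and
  guarded against double application; they commute, and their composition is
  the exact identity. Because the order of 0.9 and pBTL is a pure product it
  does not matter numerically; the package applies surface conversion last
  and records it.
* Every estimate carries `method`, `theta_deg`, `surface` and `corrections`
  columns, so a 0.9-scaled organ-of-Corti length can never be silently
  compared with a lateral-wall length.

The coverage relations `CC = L/CDL·100`, `IA = 9·CC` and the reference
`CDL = L·900/IA` are mutually inverse to 1e-12, which the tests assert for
arbitrary lengths.

## 5. Insertion simulation

`simulate_insertion()` lays an array of length L along the trajectory
obtained by shifting the lateral wall radially toward the axis by
`wall_offset_mm` (default 0.5 mm — the array sits inside the scala, not on
the wall; on the default synthetic cochlea this lands the insertion angle of
a 31.5-mm array in the clinically observed 600–800° window). The trajectory
ends where the wall radius shrinks to the offset (near the apex); an array
longer than the trajectory yields a partial-insertion result rather than an
error.

Two insertion-angle conventions are computed and reported side by side:

* `contact_span` — the unwrapped angle between the most apical and most
  basal contacts, which is what a postoperative radiograph measurement
  yields; this is the default fed into the reference formula.
* `tip_from_rw` — the angle of the most apical trajectory point.

The array tip extends beyond contact 1, so `contact_span ≤ tip_from_rw`
always; using the contact span together with the full physical length L in
the reference formula therefore *overestimates* the reference CDL. Both
numbers are kept visible precisely so this tension is never hidden.
Contact positions default to 12 contacts from 1.0 mm behind the tip at
≈2.4 mm pitch. The zero reference of the angle is the RW, an explicit
stand-in for the radiographic zero line, which is not standardised.

## 6. The synthetic cochlea

`make_spiral()` generates the lateral wall as a decaying spiral

* radius `r(θ) = r0(1 − decay·θ)` with defaults `r0 = 4.95` mm and
  `decay = 1e-3` per degree,
* basal ellipticity 0.16 (y compressed), blended out smoothly between 360°
  and 540°,
* piecewise-linear rise totalling 4.0 mm with the slope doubling at 540°
  (the apical turns climb faster),
* extent 900°.

This is the simplest family that simultaneously hits the clinically reported
ranges — A ≈ 9 mm, full lateral-wall CDL ≈ 41 mm (cohorts span roughly
38–46 mm), height ≈ 4 mm — and it makes no claim of anatomical fidelity
beyond those summary dimensions. A consequence of the linear decay is an
apical radius of ≈0.5 mm, tighter than real anatomy; it is the main stress
on the alignment and smoothing code and the reason the voxel phantom covers
the basal 780° (below). Ground truth (cumulative `cdl_lw(θ)` by polyline
integration at 0.005° steps — refining the step tenfold moves the full CDL
by far less than 1e-6 mm — plus analytic A/B chords and the height) is
attached to every spiral.

`generate_cohort()` draws specimen-level parameters around the preset
(r0 SD 0.22 mm, ellipticity SD 0.03, height SD 0.25 mm), samples jittered
point clouds (500 points, 0.1 mm isotropic jitter by default), and simulates
the per-method measurement table. The measurement model is additive:
`observation = truth − bias + cell noise + rater jitter`, with the method
noise drawn once per specimen × method (both raters read the same scan) and
rater jitter per reading. Default biases are the published
reference-minus-method differences (7.7, 6.1, 7.2, 5.0, 6.1, 5.5 mm for
3D-HRCT, 3D-CBCT, A-HRCT, A-CBCT, SW-HRCT, SW-CBCT), default noise SDs the
published per-method spreads, rater jitter 0.5 mm, reference noise 2.0 mm.
All randomness flows from explicit integer seeds; identical seeds give
byte-identical cohorts, reports and manifests (tested).

### Voxel phantom and segmentation

`phantom_from_spiral()` rasterises a fluid tube into a CT-like volume. The
generator curve is the *lateral wall*, so the tube is centred on the curve
inset medially by the lumen radius — the lateral surface of the lumen then
coincides with the wall, which is the surface a rater traces. Intensities
follow an HU-like HRCT preset (fluid 0, bone +700, air −1000; segmentation
window −1024…+280) or a CBCT preset with shifted gray values and its own
window, reflecting that cone-beam gray values are not Hounsfield units.

Numerical pitfalls encoded in the defaults:

* the bone shell must be at least ~3 voxels thick to be voxel-watertight;
  a leaky shell connects the lumen with the in-window air background and the
  segmented "lumen boundary" silently includes the outer bone surface
  (default shell 0.6 mm);
* because air falls inside a CT fluid window, `threshold_segment()` accepts
  a seed point and restricts the mask to its 6-connected component — the
  voxel analogue of seeding a region-growing segmentation in the cochlear
  fluid;
* the phantom covers the basal 780° (~96% of the CDL): with the linear-decay
  geometry the apical wall radius approaches the lumen radius and a tube
  there would self-overlap across the axis — mirroring, conveniently, the
  clinical experience that the apical wall is hardest to segment.

`extract_lateral_wall()` turns the boundary cloud back into an ordered wall
point set: boundary points within a radial/axial band of the generating
spiral's profile (the synthetic analogue of the rater knowing roughly where
the wall is) are binned in 5° sectors and the lateral-most voxel centers of
each bin averaged into one wall point. Boundary voxel centers sit strictly
*inside* the lumen — deliberately, with no sub-voxel interpolation — so the
recovered wall is medially shifted by a fraction of a voxel. This reproduces
the clinically described shrinkage of clinical-resolution segmentations that
motivates the 10/9 correction: the pipeline's CDL bias is negative at 0.2 mm
spacing and shrinks at 0.1 mm (tested). Its expected magnitude is roughly
half a voxel over the effective spiral radius (≈0.1/2.9 ≈ 3.4% at 0.2 mm),
which is what the test asserts rather than a round number.

What the generator does **not** emulate: scanner physics (beam hardening,
point-spread, noise texture), true scala anatomy (the tube is circular, not
scala-shaped), anatomical variation beyond the three summary dimensions, and
inner-ear malformations. Passing tests therefore demonstrate correctness of
the estimation machinery under controlled conditions, not clinical accuracy
on real scans.

## 7. Comparison statistics

* `summarize_methods()` averages raters within specimen first, computes
  coverage per specimen before averaging (mean of ratios, not ratio of
  means), and derives the IA columns as exactly 9 × the CC columns.
* `anova_methods()` is the standard one-way decomposition; the degenerate
  all-equal case is defined as F = 0, p = 1.
* `dunnett_vs_control()` computes two-sided Dunnett-adjusted p-values and
  simultaneous confidence intervals from the multivariate-t distribution
  over the k−1 contrasts (correlation `λiλj`, `λi = √(ni/(ni+n0))`, which is
  the equicorrelated 1/2 structure for balanced designs). Signs follow the
  convention `control − method`, so underestimation is positive. The
  quasi-Monte-Carlo multivariate-t integration is run under a pinned local
  seed so reports are bit-reproducible. With a single comparison group the
  procedure reduces to the pooled t-test (tested to 1e-6), it agrees with an
  independent reference implementation, and its familywise error over an
  all-null family of 7 groups × 20 stays within 1.5 points of the nominal
  5% in a 5000-replicate simulation (tested).
* `compare_dependent_correlations()` implements the Hotelling–Williams t for
  two correlations sharing one variable (here: the reference CDL), with
  n − 3 degrees of freedom; the clinical sources do not name their
  procedure, so this documented default is flagged in the report header, and
  its type-I error is checked against a trivariate-normal simulation oracle.
* `icc_agreement()` computes ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — from the two-way mean squares:
  `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)`. The variant is likewise
  an unstated choice in the sources; ICC(2,1) is appropriate because
  absolute CDL values (not rankings) are compared across raters, and it is
  cross-checked against a REML variance-components oracle. Reliability
  banding: below 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, 0.75+ excellent
  (configurable).

`build_report()` assembles summary, ANOVA, Dunnett listing, correlations and
ICC table into one object that prints as Markdown and serialises to JSON,
with p-values formatted as `p < 0.001` below that threshold and the two
flagged assumptions in the header.

## 8. Problem sizes and determinism

The shipped tests run the geometry oracles at 80–2000 points, the recovery
study at 50 seeds × 500 points, the voxel loop at 0.2 and 0.1 mm spacing
over 780°, the Dunnett familywise simulation at 5000 replicates of 7 × 20,
and the dependent-correlation size check at 4000 replicates of n = 20 —
about half a minute in total. Every stochastic quantity is driven by an
explicit seed, and the pipeline writes a manifest of config hash and file
checksums so that a rerun with the same configuration is verifiably
identical.

## 9. Known limitations

* The alignment assumes a roughly monotone spiral; strongly self-occluding
  or fragmented clouds (severe malformations) are out of scope.
* The pBTL default is a shape-preserving approximation, not the planning
  software's proprietary profile; partial-insertion CDLs from
  `cdl_elliptic()` inherit that approximation (the full-turn bracket does
  not).
* The insertion simulator is purely geometric: no array mechanics, friction,
  scalar translocation or tip fold-over.
* PLY support is ASCII, vertex-only.
* The synthetic cohort reproduces summary dimensions and error structure,
  not anatomy; conclusions about real scanners or raters require real data.
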