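---
title: "Methods: geometry, statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmorph)
```

`ringmorph` quantifies residual deformations of radially cut arterial ring
specimens and their separated layers from manually traced boundary points.
This vignette records the model, the numerical choices, and the design
decisions taken where the measurement procedure left genuine freedom.

## Geometry chain

**Spline model.** A traced border (≈20 ordered points) is modeled as a
parametric planar B-spline (x(t), y(t)), cubic by default — the minimal
degree with continuous curvature. Points are parameterized by normalized
chord length; the parameterization only affects conditioning because
equidistance is later enforced explicitly by arc-length resampling. Closed
(uncut-ring) traces get a periodic fit, continuous in value and first two
derivatives across the seam. Traces are re-oriented counterclockwise
(shoelace sign for rings, accumulated turning for open segments) before
fitting, so a lumen-convex boundary has positive curvature; residual
deformation is carried by the *change* of curvature and by the sign of the
opening angle, never by a signed curvature, because wavy real traces would
otherwise flip signs locally.

**Smoothing.** `smoothing` is the admissible RMS Euclidean residual of the
fit at the trace points, in mm. Zero means interpolation. For a positive
value the fit is a least-squares B-spline whose uniformly spaced knots are
grown one at a time until the residual RMS drops below the tolerance — the
smallest model that explains the trace to within the noise. The pipeline
default is 0.03 mm: manual clicking error is ~0.02 mm per coordinate at
typical image scales, i.e. ~0.028 mm in Euclidean distance. Users tracing
at a different scale should set `smoothing` to their own expected noise.

**Resampling.** Cumulative arc length is computed by composite 7-point
Gauss–Legendre quadrature on a 256-interval grid and inverted by
root-finding (`uniroot`, parameter tolerance 1e-10), giving `n = 40`
points at equal arc spacing: endpoints included for open segments (39
equal arcs), a full period for rings (40 equal arcs, the polyline closed
by the chord back to the start). The chord sum of these points is the
reported boundary length; it is a lower bound of the true arc length,
non-decreasing and convergent in `n`.

**Curvature.** κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} is evaluated
analytically from the spline derivatives at the 38 interior resampled
points; the arithmetic mean is the boundary summary and the reported
radius is its reciprocal. The alternative order — averaging the local
radii — is also computed (`radius_mean_of_local`) because the two differ
on non-circular boundaries; the curvature mean is canonical since cohort
curvatures are tabulated in 1/mm. A numerically vanishing first
derivative (singular parameterization) is an error, and straight segments
must be handled by the caller (`radius_of_curvature` refuses κ = 0).

**Accuracy and aliasing.** For open circular arcs at manual-trace density
the whole chain recovers κ to ~0.005% (the averaging-knot collocation is
superconvergent between knots). For *closed* rings interpolated at n
uniform points the pointwise curvature error oscillates (~±0.8% at 20
points) and cancels almost exactly in a dense average, but the 38
evaluation points can alias with the knots (worst when the trace count
divides 40), leaving a mean bias of ~0.2% at 20-point rings. This is
inherent to cubic interpolation of a circle, not to the implementation;
densely traced rings (≥60 points) reach the 0.1% level. Cohort
simulations at the default 20 points carry the ~0.2% bias, well inside
the 1% recovery criterion.

**Opening angle.** The vertex is the *arc-length* midpoint of the inner
boundary (interpolated on the spline, not the middle index), and the
magnitude is the angle between the rays to the two endpoints. The sign
comes from the enclosed arc angle θ, computed by accumulating (unwrapped)
tangent-direction increments along the curve so that winding past 360° is
tracked correctly: Φ < 0 exactly when θ > 360°, reproducing closing
segments whose cut ends overlap, without any overlap heuristic. For
circular arcs the ray construction and Φ = 180° − θ/2 coincide; for real,
slightly non-circular traces the ray magnitude is used (the field's
definition) and θ contributes only the sign. Self-intersecting strongly
closed traces are permitted; uncut rings have no opening angle by
definition and asking for one is an error. When the ends coincide exactly
(θ = 360°, cut but unopened) both rays are degenerate and Φ = 0.
`circular_equivalent_curvature` converts (length, Φ) to an arc curvature
(θ_rad/length) for cross-study comparison; Φ = 180° maps to a straight
strip (κ = 0) and larger angles are rejected.

## Morphometry

Thickness is the mean of the three dial-indicator readings. A% is
t_A/(t_A + t_MI). Strains are percent length changes of each boundary
relative to the *uncut ring of the same physical specimen* — a paired
design; cross-specimen references are rejected. The membrane/bending split
assumes linear strain variation through the wall: membrane is the mean of
the inner and outer strains, bending the half-difference, so the two
boundary strains are exactly recoverable. For a pure bending field
(curvature change Δκ at constant mid-line length) the expected bending
strain is −tΔκ/2·100% up to a factor 1/(1 − (κt/2)²) ≈ 1 for realistic
wall slenderness, which is why the recovery test allows 5%.

## Gated statistics

The Anderson–Darling composite test (mean and variance estimated; the
size-corrected statistic A²(1 + 0.75/n + 2.25/n²) with the standard
piecewise-exponential p approximation) gates every path at α = 0.05.
Below n = 8, or for constant samples, the gate cannot decide and defaults
to the nonparametric path with a warning. Choices left open by the
procedure:

* **t-test variant** — Welch (unequal variances), the robust default.
* **Quartiles** — linear interpolation on the sorted sample (R type 7);
  fixed by the package's own worked example (quartiles of 1…9 are 3 and 7).
* **Paired gate** — applied to the paired differences, the quantity the
  paired t assumes normal. All-zero differences short-circuit to p = 1.
* **Multiplicity** — none by default, mirroring the study design; a Holm
  helper is provided (`holm_adjust`).
* **Ties** — average ranks; Spearman and rank tests use the large-sample
  approximation so tied data never silently switch conventions.

Protocols are merged only when none of the six parameters of interest
(thickness, opening angle, inner/outer curvature, inner/outer length)
differs significantly between them at the final time state; otherwise the
offending parameters are named and summaries are kept per protocol.

## Synthetic cohort

The generator states a world in which every descriptor has a closed form:
a specimen is a pair of concentric circular arcs (radii R ± t/2) with arc
angle θ, so κ_inner = 1/(R − t/2), lengths are Rθ-type products and
Φ = 180° − θ/2 exactly. Post-cut relaxation follows
κ(t) = κ∞ + (κ₀ − κ∞)e^{−t/τ} with the membrane strain saturating on the
same clock — a stand-in confined to this module, since the study reports
three time points only and the true functional form is unknown.

Defaults are the published cohort conditions: 17 patients; uncut-ring
inner curvatures 0.362 ± 0.051 (MI / intact) and 0.305 ± 0.010 1/mm
(adventitia; the published table prints that small dispersion); MI
thickness 0.60 ± 0.14 mm, intact wall 0.92 ± 0.15 mm; MI relaxation fast
(τ = 0.2 h — most of the change within 30 min) toward κ∞/κ₀ ≈ 0.67, with
≈ +3% membrane strain; adventitia slow (τ = 8 h — still creeping at 22 h)
toward a *clean-layer* ratio of 1.24 (closing) with −3.8% membrane
shortening. Tracing noise is isotropic Gaussian, 0.02 mm, applied after
scaling, 20 points per border — manual clicking at the study's density.

**Imperfect separation.** Each adventitia specimen carries a
residual-media fraction f ~ U(0, 0.5). Residual media (i) thickens the
observed adventitia by f·t_MI and thins the MI correspondingly — raising
A% and bringing the observed adventitia thickness mean to ≈0.36 mm, the
published value, which is itself a contaminated measurement — and (ii)
pulls the adventitia's asymptotic curvature ratio linearly toward the MI
value (full interpolation at f = 1), so contaminated specimens behave
MI-like (opening). Together these produce the negative A%–curvature and
positive A%–opening-angle rank associations, with an effect size that
makes the contaminated-average final curvature land near the published
0.343 1/mm.

Reproducibility is hierarchical: the cohort seed fixes all parameter
draws, and every specimen × state trace has a derived seed recorded in
the metadata, so any specimen can be regenerated bit-identically in
isolation. The generator's RNG use is scoped and restores the caller's
stream.

**What a green test does not establish.** The generator emulates
circular-arc geometry, layer-specific relaxation, contamination coupling
and tracing noise. It does not emulate non-circular (atherosclerotic)
boundary shapes beyond an optional elliptical test fixture, blurred outer
borders, friction between overlapping cut ends, repeated specimens with
correlated within-patient errors, or axial-direction effects. Recovery of
ground truth therefore validates the measurement chain, not the
biological conclusions; the published cohort statistics derive from
undeposited photographs and are not reproducible at desk scale.

## Known limitations

* Closed-ring mean curvature at sparse manual densities carries the ~0.2%
  aliasing bias described above.
* The opening-angle sign procedure for non-circular traces is this
  package's construction (signed winding); the original study does not
  describe one.
* The Anderson–Darling p approximation is accurate to ~1e-3 in p, ample
  for gating at 0.05 but not for reporting extreme normality p-values.
* Protocol-1 layer specimens are given their own synthetic ring reference
  state; in the laboratory the pre-separation reference is the intact
  ring, so protocol-1 layer strains are an idealization of the generator,
  not of the measurement code.
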