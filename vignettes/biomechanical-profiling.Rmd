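---
title: "Biomechanical profiling of swimming nematodes: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical profiling of swimming nematodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormswim)
```

## The measurement problem

A single *C. elegans* swimming in buffer executes a planar undulatory gait:
a wave of body curvature travels from head to tail and, because a slender
body at low Reynolds number experiences more drag moving sideways than
lengthwise, that wave propels the animal forward. The package quantifies
this gait from bright-field movies along two axes:

1. **Kinematics** — what the body does: length *L*, swimming speed *U*,
   beating frequency *f*, undulation wavelength λ, and the distribution of
   bending along the body.
2. **Dynamics** — what the muscles deliver: propulsive force and mechanical
   power, estimated with resistive force theory (RFT).

Both matter for phenotyping: mutants can swim slowly because they beat
slowly, because they bend less, or because a specific body region stops
bending — three different mechanistic stories that the curvature profile and
the force/power estimates disentangle.

## From frames to the parameterized body shape

Each frame is thresholded by inter-class variance maximization (Otsu; a
fixed threshold can be supplied for pathological histograms), the largest
dark connected component is kept, holes are filled, and components below a
minimum area are treated as debris. The worm's topological skeleton
(Zhang–Suen thinning) is pruned to its longest end-to-end path; because
thinning retracts the skeleton from the two body tips by roughly one body
radius, each end is extended along its local tangent to the mask boundary
before smoothing and resampling to `n_points` (default 100) points equally
spaced in arclength. The local half-width `a(σ)` is read off the mask's
distance transform along the path.

Head/tail orientation is resolved in two passes: per-frame flips are chosen
to minimize end-to-end displacement between consecutive frames, then a
single global assignment takes the head to be the end with the larger
time-averaged curvature magnitude over the terminal 15% of the body (worm
heads beat with larger amplitude than tails). When the two ends differ by
less than 10% the assignment is flagged low-confidence and can be forced by
configuration. Isolated tracking failures (fewer than three consecutive
frames) are linearly interpolated; longer gaps fail the movie.

Design notes a maintainer should know:

- The choice of a *skeleton*-based rather than contour-midline centerline is
  a pragmatic one; for bands of near-constant width the two coincide to
  sub-pixel accuracy, and the skeleton handles curved postures robustly.
- Coordinates are mm with origin at the image top-left and y increasing
  downward; frame indexing is 0-based in the CSV interchange format.
- Resampling places points on the extracted path at uniform steps of its
  cumulative arclength, so the arclength parameter spacing is exact by
  construction; chord spacing varies only at second order in curvature.

## Curvature, frequency, wave speed, speed

Bending curvature is the arclength derivative of the tangent angle,
κ = dθ/ds, evaluated at the interior centerline nodes after a fixed-lag
moving-average smoothing of θ spanning 5% of the body (suppresses
pixel-quantization noise; configurable, and attenuates a wave with λ ≈ L by
well under 1%). Positive κ means a counterclockwise tangent rotation in the
image frame — the sign convention only needs to be consistent, since all
downstream statistics use magnitudes or phases.

*Beating frequency* is the dominant spectral peak of the mid-body curvature
signal (mean over σ ∈ [0.3, 0.5]) with a Hann window, refined by maximizing
the windowed DFT magnitude over a continuous bracket around the peak bin;
with the 4–10 cycles a QC-accepted movie contains, this is accurate to a
fraction of a percent where naive bin-picking would err by several percent.
A zero-crossing cycle counter provides an independent cross-check and the
successive cycle periods used by QC. *Wave speed* comes from the phase of
each body position's dominant-frequency component: a traveling wave has
phase advancing linearly with arclength, and the fitted gradient gives
λ = 2π/|dφ/ds| and wave speed λ·f. Rows with little oscillation amplitude
(e.g. inside a suppressed region) are down-weighted; if the doubled-angle
phase resultant shows all phases equal modulo π (a standing wave) or the
phase span is under π/2, the wave speed is flagged absent rather than
invented. *Swimming speed* is the mean magnitude of the centroid velocity,
computed by central differences on a 5-frame-smoothed track — raw
differentiation at 30 fps amplifies segmentation jitter. The centroid of
the uniformly resampled centerline is used rather than the mask centroid;
it is pinned to the true body centroid by construction and less sensitive
to threshold-dependent area fluctuations.

### The curvature profile and its averaging order

The regional profile is the time-average of curvature along the body,
trimmed of the first and last 5% of body coordinate (the tips are thin and
transparent, and their curvature is unreliable), then normalized to 1 at
the head-most retained position (σ = 0.05; a head-window average is
available by configuration). Group profiles average the per-worm normalized
profiles and renormalize.

One subtlety is deliberately exposed: averaging the *signed* curvature in
time and then taking magnitudes nulls a zero-mean wave as the record grows,
producing a near-zero profile; averaging |κ| in time produces the familiar
head-to-tail-decaying nonzero profiles. Both orders are implemented
(`order = "time_first"` / `"magnitude_first"`); the default is
magnitude-first, which reproduces a flat ≈ 1 profile for a
uniform-envelope wave, and the discrepancy is asserted in the test suite
rather than hidden.

## Resistive force theory

Each segment of length *ds* moving with normal/tangential velocity
components u_N, u_T experiences drag
dF = −(C_N u_N **n̂** + C_T u_T **t̂**) ds. The package's default
coefficient pair is the refined slender-body form

- C_T = 2πμ / (ln(2λ/a) − ½),
- C_N = 4πμ / (ln(2λ/a) + ½),

with 1 < C_N/C_T < 2; the classical alternative (`"gray_hancock"`) keeps
C_T and sets C_N = 2 C_T. Viscosity μ defaults to 1.0 mPa·s (aqueous buffer
at room temperature) and is configurable; λ is the measured undulation
wavelength with body length as fallback; the characteristic radius *a* is
the median tracked half-width over the mid-body (σ ∈ [0.2, 0.8]), falling
back to 3% of body length — a typical radius-to-length ratio for these
animals — when no mask half-widths exist. With C in mPa·s, u in mm/s and ds
in mm, forces come out in nN and powers in pW with no further conversion.

A swimmer is force-free: summed over the body and averaged over a beat
period, propulsion balances drag. The literal body integral
∫(C_N u_N + C_T u_T) ds is sign-ambiguous as a definition of "propulsive
force" (its period average is near zero for a force-free swimmer), so the
reported F_P(t) is the **thrust magnitude**: the summed projections, onto
the instantaneous swimming direction, of the segment forces that push the
body forward. The opposing drag magnitude and the raw net force vector are
returned alongside, and the period-averaged net force is the package's
numerical check of the force-free closure — about 1% of thrust for the
default synthetic gait. Period averages use the largest whole number of
beat periods available; the partial-period remainder is discarded, and a
record too short for one period falls back to the full record with a flag.

Mechanical power is P(t) = ∫(C_N u_N² + C_T u_T²) ds, a weighted sum of
squares and hence nonnegative frame by frame; both force and power are
exactly linear in μ, and time-rescaling the gait by 2 quadruples P — all
asserted as tests.

RFT is a local approximation: no hydrodynamic interactions between body
parts, no wall corrections for the shallow chamber. These are known
simplifications shared by the measurement tradition this package follows;
absolute power values in particular should be read as a consistent index
rather than a calorimetric truth.

## The synthetic generator: what it emulates, and what it does not

The generator is curvature-first: a prescribed traveling wave
κ(σ, t) = κ₀ A(σ) sin(2π(σL₀/λ − f t)) is integrated to tangent angles and
then to coordinates at fixed arclength, making the analytic curvature field
exact ground truth and inextensibility true by construction (arclength
deviates from L₀ by < 0.1%, dominated by chord-versus-arc discretization).
The amplitude envelope decays linearly from 1 at the head to 0.5 at the
tail, matching the qualitative head-to-tail amplitude decrease of real
swimmers; a suppression window multiplies amplitude by a factor (default
0.15 over σ ∈ [0.5, 0.8]) to emulate regional neuromuscular failure. The
body extends opposite the heading so the animal leads with its head and the
head-to-tail wave pushes it forward.

Two default choices deserve their rationale:

- **κ₀ = 5/L₀** makes the dimensionless gait amplitude κ₀L₀ = 5,
  a realistic mid-range value for swimming worms, and length-invariant
  across presets.
- **λ = 1.2 L₀**: together with κ₀L₀ = 5 this makes the RFT-self-consistent
  swimming speed of the default gait (the speed at which period-averaged
  net force vanishes, ≈ 0.256 mm/s at 2.3 Hz and 0.63 mm) match the
  late-stage wild-type preset speed of 0.26 mm/s. Real worms satisfy force
  balance exactly; a generator whose prescribed translation contradicted
  its own wave would break the force-free closure that the dynamics module
  is validated against.

Presets carry group means and SDs of length, speed, and frequency for
wild-type and mutant cohorts at two developmental stages; `make_cohort()`
draws per-worm values from truncated normals with those SDs. Rendering
paints the worm as a dark band of tapered half-width on a bright
background, blurs, adds Gaussian noise, and quantizes to 8-bit, keeping the
clean masks as ground truth; identical seeds give bit-identical stacks.

What the generator does **not** emulate — and therefore what passing
round-trip tests do and do not show about real data: no self-occluding or
omega-turn postures (self-intersecting gaits are rejected, and real coiled
frames would be flagged, not solved), no illumination gradients or moving
debris, no out-of-plane motion, no worm-shape irregularities beyond the
smooth taper, and no fluid simulation (kinematics are prescribed, not
emergent). Tracker accuracy on rendered movies (~0.5 px mean centerline
error, < 2% length bias in the validation sweep) is therefore an upper
bound on clean-recording performance, not a guarantee for hard field data.

## Quality control

A movie is accepted only if it shows at least four full beating cycles
(exactly four passes, with a 10⁻³-cycle tolerance so estimator noise cannot
reject a nominally four-cycle movie), no body point within one body radius
of the chamber wall (the margin is configurable; the wall check is skipped
with a warning when no chamber geometry is supplied), and regular beating,
operationalized as a coefficient of variation of successive cycle periods
≤ 0.3. The original assay's "irregular or interrupted beating" criterion
was almost certainly judged by eye; the CV threshold is a declared
surrogate, logged with the QC report.

## Statistics

Group tables report mean ± SD and n per group and stage; percent changes
are computed from group means at full precision, with display rounding
(half away from zero, so 62.5 prints as 63) strictly separated from stored
values. Metric comparisons use the tie-corrected Kruskal–Wallis omnibus
with Dunn's pairwise rank z tests under a configurable adjustment
(Šidák default). "Dunnett" is accepted as a procedure name for
compatibility with prevailing lab usage but is parametric and incompatible
with rank tests, so it maps to Dunn-with-Šidák with a warning. Curvature
profiles are compared position by position with Welch t tests under
step-down Holm–Šidák family-wise correction; the head position, which is
exactly 1 for every worm by normalization, is a degenerate zero-variance
case that counts as a clean null. Calibration is verified by simulation:
the omnibus type-I error at α = 0.05 falls in [0.03, 0.07] over 1000 null
replicates, and the family-wise any-rejection rate of the profile tests
stays ≤ 0.07 over 500 null cohort pairs.

## Problem sizes and numerical conventions

Validation uses 3 s movies at 30 fps (6–7 beat cycles, comfortably above
the QC floor), 100-point centerlines, and a 3 × 3 length × frequency sweep
for rendered round trips; the family-wise-error simulation uses 50-point
centerlines, 2 s records, and 0.5 µm coordinate noise emulating tracking
error, with two cohorts of 20 worms per replicate. Ties in skeleton path
selection resolve to the first maximal endpoint pair; degenerate inputs
(repeated centerline points, uniform frames, single-frame stacks,
zero-curvature normalization) raise classed errors rather than NaNs, and
every stochastic step is reproducible from explicit integer seeds.

## Known limitations

Skeleton-based centerlines degrade on self-occluding postures; the RFT
force scale inherits the coefficient-model choice (the two shipped models
differ by tens of percent in C_N, which is why the model tag is recorded in
every result); wavelength estimation needs a genuinely traveling wave and
at least a half-turn of phase across the body; and synthetic mechanical
power for the default presets sits at the upper end of the realistic range
because the generator prescribes a single envelope shape for all worms
rather than fitting per-animal amplitude.
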