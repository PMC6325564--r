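# wormswim

Biomechanical profiling of swimming *C. elegans* from bright-field movies.

Swimming nematodes are a workhorse readout for neuromuscular phenotypes:
mutants of the survival-motor-neuron ortholog *smn-1* (a spinal muscular
atrophy model), the insulin/IGF-1-like receptor *daf-2*, and related genes
differ not just in how fast they thrash but in *where along the body* the
bending machinery fails and *how much mechanical work* the muscles deliver.
`wormswim` turns a movie of a single swimming worm (TIFF stack or PNG
sequence, 30 frames/s, known mm/pixel) — or a pre-extracted centerline time
series — into a quantitative biomechanical profile:

- **Tracking** — worm/background separation, ordered head→tail centerlines,
  and the parameterized body shape *s(x, y, t)*.
- **Kinematics** — the curvature kymograph κ(s, t), beating frequency
  *f* = 1/*T*, wave speed from the kymograph stripe slope, forward swimming
  speed *U* from the differentiated centroid track, and the time-averaged
  curvature profile, trimmed 5% at each end and normalized to 1 at the head.
- **Dynamics** — resistive force theory at low Reynolds number. Each body
  segment contributes a drag force
  *dF* = (C_N u_N **n̂** + C_T u_T **t̂**) *ds*, with slender-body drag
  coefficients C_T = 2πμ/(ln(2λ/a) − ½) and C_N = 4πμ/(ln(2λ/a) + ½).
  Because a swimmer is force-free (F_P + F_D = 0), thrust balances drag over
  a beat period; the package reports the period-averaged propulsive force
  F_P(t) = ∫ (C_N u_N + C_T u_T) ds (nN) and mechanical power
  P(t) = ∫ (C_N u_N² + C_T u_T²) ds (pW).
- **QC** — movies with fewer than four beating cycles, wall interactions, or
  irregular beating are excluded before any statistic is computed.
- **Statistics** — group tables (mean ± SD), stage-to-stage percent changes,
  Kruskal–Wallis with Dunn post hoc comparisons, and position-wise Welch *t*
  tests with Holm–Šidák correction for curvature profiles.

Because raw recordings of this kind are rarely deposited, the package ships a
**synthetic worm-movie generator** with exact ground truth: a prescribed
traveling curvature wave (optionally suppressed over a mid-tail window to
emulate regional neuromuscular failure) integrated to inextensible
centerlines, rendered as noisy bright-field-like frames. Every estimator in
the pipeline is validated round-trip against this ground truth.

## Worked example

```r
library(wormswim)

# a late-stage wild-type-like swimmer: 0.63 mm, 2.3 Hz, 0.26 mm/s
gg <- generate_gait(gait_params(L0 = 0.63, f_true = 2.3, U_true = 0.26))
gg$series
#> <body_shape_series> 90 frames @ 30 fps, 100 points, L = 0.630 mm (mean)

build_profile(gg$series, id = "sim_worm")
#>         id L_mm speed_mm_s frequency_hz wavelength_mm force_nN power_pW
#> 1 sim_worm 0.63       0.26          2.3         0.757    0.621     6.01
```

The profile row reads: a 0.63 mm worm swimming at 0.26 mm/s, beating at
2.3 Hz with a 0.76 mm undulation wavelength, generating a period-averaged
propulsive force of 0.62 nN and spending 6.0 pW on locomotion — the same
fraction-of-a-nanonewton force scale measured for real late-stage worms.

Cohort-level analysis with QC and group statistics:

```r
co <- make_cohort(c("N2_L2", "N2_late"), n_per_group = 6, seed = 42)
res <- profile_cohort(co, chamber = list(center_mm = c(0, 0), radius_mm = 10))
gt <- summarize_groups(res$profiles)
subset(gt, metric == "speed_mm_s")
#>   group stage     metric n  mean      sd
#> 2    N2    L2 speed_mm_s 5 0.198 0.04651
#> 7    N2  late speed_mm_s 6 0.240 0.08349
```

(One L2 movie was rejected by QC for having fewer than four beating cycles —
exactly the exclusion a real assay applies.) Rendering a movie and tracking
it back:

```r
cfg <- auto_render_config(gg$series)
stack <- render_movie(shift_series(gg$series, attr(cfg, "offset_mm")), cfg)$stack
tracked <- track_movie(stack)       # centerlines within ~0.5 px of truth
```

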