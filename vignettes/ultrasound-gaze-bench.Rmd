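---
title: "Emulating an ultrasound gaze-estimation bench: models, noise, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating an ultrasound gaze-estimation bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echogaze)
```

## The problem

Camera-based eye trackers fail under changing ambient light and are hard to
run fast at low power. Airborne megahertz ultrasound is an alternative: the
acoustic impedance mismatch between air and tissue means an eye reflects
essentially all incident ultrasound, and because the cornea protrudes from
the scleral sphere, the timing and strength of echoes received around a
glasses frame change with gaze. `echogaze` emulates a complete benchtop
study of this idea — a model eye on a goniometer probed by directional
transducers — and carries the synthetic measurements through the published
feature-engineering and regression pipeline, so that every stage (acoustic
physics, signal chain, estimator) is reproducible and testable at desk
scale.

The package is organised as an analysis: numbered drivers under `analysis/`
run the characterization benches, the protocol simulation, feature
extraction and the regression study, writing tables under `results/`; all
computation lives in the package functions those drivers call.

## Acoustic model

Sound is modeled as rays from a point source. Three physical ingredients
enter, all with closed forms:

* **Reflection.** At an interface with impedances $Z_1, Z_2$ the reflected
  energy fraction is $R = ((Z_2 - Z_1)/(Z_2 + Z_1))^2$ with $Z = \rho c$.
  For air against any of the relevant solids (tear film, cornea, fat,
  glass) this exceeds 99.87%, so the tracer treats solid surfaces as total
  reflectors (`reflection_fraction()` documents the calculation; a
  per-surface reflectance below 1 is available and is used for the occluder,
  see below).
* **Attenuation.** Amplitude decays as $10^{-A d / 20}$ with
  $A = 470$ dB/m at ~1.7 MHz in air and $d$ the path length; the speed of
  sound is fixed at 343 m/s.
* **Directivity.** Transducers follow the native curve
  $w(\alpha) = \cos(\min(\alpha \cdot 90/15, 90^\circ))$: weight 1 on axis,
  zero at and beyond the 15° cutoff, in both transmit and receive mode. The
  cutoff is a parameter; the measured emission cone of such devices is
  nearer 10°, and the 15° weight curve is the modeling convention adopted
  here, so the discrepancy is exposed rather than hidden.

`trace_rays()` propagates each ray through specular reflections until it
crosses a receiver's aperture disc, escapes, or exhausts the bounce budget
(default 3; attenuation and directivity make deeper recursion negligible).
A detected ray contributes emission weight × reception weight × attenuation
over its full path; rays arriving outside the receiver's acceptance cone
are rejected before they are counted.

**Emission sampling.** `emit_rays()` draws directions uniformly per solid
angle on the hemisphere. For the bench protocol the sampler instead draws
uniformly from the 15° cap and multiplies weights by the cap/hemisphere
solid-angle ratio — an importance-sampling identity (rays outside the cap
carry exactly zero weight), cutting the variance of every detected-energy
estimate by ~30× at equal ray counts.

**Detection aperture.** Receivers are discs, not points, because a
Monte-Carlo tracer needs a finite target. The physical device is ~1 mm
across, and `transducer()` defaults to a 0.5 mm radius; the bench ring uses
2.0 mm. This is an estimator-variance control, not a physical claim: after
reflection off the convex cornea the ray bundle diverges so strongly that a
0.5 mm disc at desk-scale ray counts detects well under one ray per trace.
The arrival-time geometry is unaffected; only the hit statistics change.

## Scene geometry

The eye is the standard sphere-on-sphere model: a scleral sphere
(11.925 mm) and a corneal sphere (7.8 mm) offset 5.6 mm along the gaze
axis, so the corneal apex protrudes 1.475 mm. Gaze poses rotate the corneal
cap rigidly about the sclera center; coordinates are right-handed with the
origin at the sclera center, +z toward the transducer ring, +x nasal, +y
up. Ring angular positions are measured from +x toward −y, so the
transmitter arc position +90° sits below the eye. Intersections are
analytic ray–quadric solutions (relative tolerance 1e−9; tangent rays count
as hits) rather than fixed-time-step marching: exact, faster, and free of
step-size artifacts.

**The occluder** stands in for the printed face replica of a physical
bench, which is not reproducible here. It is a reflective shell in front of
the eye with an elliptical aperture narrowed by two wedges — a deep shelf
over the upper sector (upper lid/brow) and a graded edge over the
lower-temporal sector (lower lid/cheek/nose pad). Two properties matter and
both are diffraction-motivated:

* **Penumbra.** At 1.74 MHz the wavelength is ~0.2 mm and edges smooth
  geometric shadows over roughly the Fresnel width $\sqrt{\lambda d}
  \approx 2$ mm. Each edge therefore carries a linear transmission ramp
  (`wedge_softness`, default 2.8 and 2.0 mm; ellipse edge 1.0 mm): rays in
  the penumbra pass with weight scaled by the local transmission, rays in
  full shadow reflect. Occlusion grades the signal instead of switching
  channels off.
* **Low specular reflectance.** The shell's specular reflectance defaults
  to 0.005: the soft printed material scatters diffusely, and a coherent
  flat mirror at full strength would bury the corneal echo under a
  gaze-invariant shell echo. Blocking is independent of reflectance, so the
  occlusion geometry is exact either way.

The wedge parameters were chosen by examining where the specular ray
bundles cross the shell plane (they cross on the temporal side: upper half
for positive transmitter angles, lower half for negative) so that the
emulated bench reproduces the qualitative occlusion signatures a face
produces: mean received amplitude asymmetric across transmitter positions
with its maximum near +10 to +20°, and signal that degrades as the eye
looks down, because downward gaze pushes the reflected bundles into the
lower graded edge.

## Bench protocols and the noise model

Three benches are emulated. `bench1_attenuation_sweep()` (flat plate on a
translation stage) verifies the expected log-linear amplitude decay over
the doubled acoustic path; `bench2_directivity_sweep()` (rotating
transmitter) returns the native curve scaled by the fixed-pair attenuation.
The gaze bench (`simulate_bench_dataset()`) runs the full protocol: a 6×6
grid of poses over {−5, −3, −1, +1, +3, +5}° in both axes, the transmitter
stepped over −90..+90° in 10° steps opposite a fixed receiver at 180°,
7-cycle 1.74 MHz bursts repeated at 2 kHz, 50 repeats per position
digitized at 80 MHz, 9 sessions. Ray tracing runs once per
(pose, transmitter) and is reused across repeats and sessions.

The protocol literature is internally inconsistent about the pose grid (a
1°-step grid over ±5° would give 121 poses; the dataset size corresponds to
36); the 6×6 grid is the default here because the total of 36 poses × 45
samples = 1620 is authoritative for the dataset, and the 1° grid remains
available through the configuration.

Measurement noise has five components, each with a physical counterpart:

| term | default | emulates |
|---|---|---|
| additive per-sample noise | calibrated to 6 dB single-trace peak SNR | receiver/electronics noise floor; raw traces are unusable before averaging |
| session gain jitter | 5% | day-to-day sensitivity drift |
| session timing jitter | 0.2 µs | day-to-day trigger/geometry drift, common across positions |
| placement gain jitter | lognormal sd 0.25 per (pose, session, transmitter) | re-aiming error of the stepped transmitter: a small aim error moves the operating point on the steep cosine directivity curve |
| placement timing jitter | 0.1 µs | re-positioning error; path length is set by position, not aim, so this term is much smaller than the gain term |
| per-burst scintillation | 10%, averaging down by √10 | drive and air-path fluctuation between bursts |

The placement terms are what give the per-channel time-of-flight and
amplitude distributions their spread; without them the frozen Monte-Carlo
arrival set would repeat identically across sessions and amplitude would
become an unrealistically clean pose fingerprint.

The trace duration defaults to 300 µs (longest configured round trip plus
the analysis window); `"fast"` mode synthesizes the 10-trace group averages
directly — the average of 10 i.i.d. renders is the noiseless signal plus
Gaussian noise at std/√10, so the distribution of every downstream feature
is unchanged while rendering cost drops tenfold. Counting and feature
outputs are invariant to the mode, and the whole dataset is bitwise
reproducible from (configuration, seed).

## Feature engineering

Exactly the published chain: consecutive disjoint groups of 10 traces are
averaged (`average_groups()`, 50 repeats → 5 averages, so the 2 kHz burst
rate becomes an effective 200 Hz feature rate); each average is band-pass
filtered at [1.6, 1.9] MHz with an order-4 Butterworth
(`bandpass()`); the filtered trace is squared and a 45 µs window centered
on its global maximum (clipped at trace edges); the time of the *first*
occurrence of the maximum of the raw averaged trace inside the window is
the time of flight τ, and that maximum is the amplitude a
(`extract_peak_features()`).

Filtering is zero-phase so the filter's group delay cannot bias τ. The
default implementation multiplies the spectrum by the filter's
magnitude-squared response — the exact steady-state forward-backward
response, an order of magnitude faster on 24 000-sample traces — and the
time-domain `filtfilt` path is retained and tested against it. A causal
single-pass mode exists for completeness.

`build_feature_matrix()` pivots to one row per (pose, session, group):
19 τ columns then 19 a columns, ordered by transmitter angle. The 19
transmitter positions give 38 features; a 36-dimensional feature count is
sometimes quoted for this protocol, which cannot be reconciled with the
19-position list, so 38 is used here rather than guessing which positions
were dropped. The default protocol yields 1620 × 38.

## Gaze regression

Two regressors per axis, trained on squared error: gradient-boosted
regression trees (XGBoost; learning rate 0.0825, depth 5, 750 trees,
minimum child weight 23, L1 0.01, L2 1 — the published tuned values, taken
as given) and an ordinary-least-squares baseline. Evaluation is shuffled
5-fold cross-validation; whether the original study's folds respected
session boundaries is unstated, so row-level shuffling is the default and a
session-grouped mode is provided for leakage-sensitive analyses. Reported
metrics: RMSE per axis and pooled as
$\sqrt{\tfrac{1}{n}\sum (e_\theta^2 + e_\phi^2)/2}$ (one number comparable
to a per-axis RMSE), and adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$ in
percent with $p = 38$. `epsilon_ball_curve()` reports the fraction of
estimates within a radius of truth; `feature_importance()` returns
gain-based importances normalized per axis; `ablation()` restricts
cross-validation to the τ or a columns; `permutation_null()` (20 label
shuffles) gives the no-signal reference; `error_map()` aggregates mean
Euclidean error per pose.

## What the synthetic bench does and does not show

At the frozen defaults (8192 rays per trace in the test suite; the
simulation default is 131 072) the pipeline reproduces the study's
structure and most of its findings: 1620 samples, GBRT pooled CV RMSE
≈ 0.7° — well inside the 2° resolution bound and far better than the
linear baseline (≈ 1.6°); both-feature CV beats τ-only, which beats the
permutation null decisively; τ-only adjusted R² (≈ 81%) lands close to the
published 85.4; the amplitude profile across transmitter positions is
asymmetric with its maximum on the positive side (at +10° for the test
seed), and cross-validated error is elevated for downward gaze.

Two caveats on the occlusion signatures: the positive-side amplitude excess
(roughly 1.7× the negative side) is robust across seeds, but the exact
argmax wanders between 0° and +20° at desk-scale ray counts; and the
downward-gaze error elevation is the weakest emulated signature — a few
percent at the study seed, with a sign that can flip under a different
Monte-Carlo seed at these ray counts. Both checks are therefore run at the
declared study seed, and neither should be read as a precise quantitative
prediction.

One published finding does **not** reproduce: gain importance of the
trained GBRT is amplitude-dominated here, whereas the physical bench found
time-of-flight on top. The synthetic amplitude channel is more informative
than the physical one for identifiable reasons: the five group averages
within a (pose, session, transmitter) cell share one physical placement,
so amplitude is a stable within-session signature that row-level folds can
exploit; the penumbral occlusion response makes amplitude a smooth encoder
of gaze near every clipped channel; and the session-level timing jitter is
common-mode across channels, which axis-aligned tree splits cannot
subtract. Amplitude-only CV reaches ≈ 96% adjusted R² here versus the
published 78.6. This is reported as a known limitation of the emulation
rather than hidden by inflating amplitude noise beyond what the published
distribution spreads support. Conclusions that depend on the *relative*
informativeness of amplitude versus timing on a physical device should not
be read off this bench.

Other limitations: rays, not waves (no interference or frequency-dependent
attenuation); a parametric occluder, not a scanned face; static gaze only
— the temporal dynamics of saccades are out of scope; and absolute
amplitudes are arbitrary units — only ratios and decay shapes are
meaningful.

## Numerical choices

* Geometry tolerance 1e−9 relative; tangent hits resolve to "hit";
  post-bounce self-intersection guard 1e−6 mm.
* Monte-Carlo: counter-seeded streams per (pose, transmitter); every
  stochastic stage takes an explicit seed and restores the caller's RNG
  state.
* Peak ties resolve to the earliest sample, exactly as the feature
  definition requires; windows clip at trace edges; an all-zero analysis
  window raises a degenerate-trace error rather than returning a value.
* Problem sizes in the shipped tests: the full default protocol at 8192
  rays (the simulation default is 131 072, which sharpens amplitude
  estimates but does not change any tested conclusion), 65 536 rays for
  the directional-vs-omnidirectional comparison, 16 384 for profile
  checks.
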