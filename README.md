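# echogaze

Ultrasound time-of-flight gaze estimation on a synthetic acoustic bench.

Light-based eye trackers struggle outdoors and at high frame rates.
Airborne megahertz ultrasound is a candidate replacement: the air–tissue
impedance mismatch makes the eye a near-perfect acoustic mirror
(`R = ((Z₂−Z₁)/(Z₂+Z₁))² > 99.87%`), and because the cornea protrudes
~1.5 mm from the scleral sphere, echo timing and amplitude at transducers
around a glasses frame vary with gaze direction. `echogaze` is a full
emulation of a benchtop study of this idea, for researchers who want to
probe the sensing principle, the signal chain, or the estimator without
hardware:

* **acoustic ray tracing** of a sphere-on-sphere model eye (cornea 7.8 mm,
  sclera 11.925 mm, offset 5.6 mm) behind a parametric facial occluder,
  with specular reflection, 470 dB/m air attenuation at 1.7 MHz, and the
  cosine transducer directivity `w(α) = cos(min(α·90/15, 90°))` with a 15°
  cutoff, in transmit and receive;
* **bench emulation**: 7-cycle 1.74 MHz tone bursts at 2 kHz digitized at
  80 MHz; 36 goniometer poses within ±5°, a transmitter stepped over
  −90..+90° opposite a fixed receiver, 50 repeats × 9 sessions with
  day-to-day, placement and per-burst noise;
* **feature extraction**: 10-trace averaging (2 kHz → 200 Hz effective),
  order-4 Butterworth band-pass at [1.6, 1.9] MHz applied zero-phase, and
  first-peak detection in a 45 µs window around the filtered-energy
  maximum, yielding per-position time of flight τ and amplitude a
  (38 features);
* **gaze regression**: per-axis gradient-boosted regression trees
  (XGBoost; learning rate 0.0825, depth 5, 750 trees, min child weight 23,
  L1 0.01, L2 1) against an ordinary-least-squares baseline, with 5-fold
  cross-validated RMSE and adjusted R², epsilon-ball sensitivity curves,
  gain importances, τ/a ablations with a permutation null, and per-pose
  error maps.

## Worked example

The numbered drivers under `analysis/` run the whole study and write
tables under `results/`:

```sh
Rscript analysis/01_characterize.R        # reflection, attenuation, directivity
Rscript analysis/02_simulate_dataset.R    # bench protocol -> long feature table
Rscript analysis/03_extract_features.R    # 1620 x 38 design matrix
Rscript analysis/04_gaze_regression.R     # CV study, ablations, error maps
```

With the default configuration (16 384 rays per pose–transmitter trace,
seed 1), the final driver prints:

```
Cross-validated gaze estimation (5 folds):
                 model adj_r2_pct adj_r2_sd rmse_deg rmse_sd
                  gbrt       94.0     0.644    0.784  0.0373
                linear       74.0     0.883    1.632  0.0432
         gbrt tof-only       82.1     1.341    1.400  0.0344
         gbrt amp-only       93.6     0.852    0.834  0.0516
 gbrt permutation null      -37.1     2.172    3.751  0.0295

Epsilon-ball sensitivity: 56% of estimates within 0.8 deg, 94% within 2 deg.
```

Reading it: the boosted trees recover gaze to ~0.8° pooled RMSE — well
inside the 2° resolution the sensing principle promises — and roughly
halve the linear baseline's error, confirming that the occluder makes the
feature-to-gaze map nonlinear. Time-of-flight alone reaches 82% adjusted
R², far above the shuffled-label null, so timing carries genuine gaze
signal; amplitude is even more informative on this synthetic bench (see
the methods vignette for why that differs from a physical bench, where
timing dominates). The epsilon-ball numbers say half the estimates land
within ~0.7° of truth.

Equivalent programmatic use:

```r
library(echogaze)
ds <- simulate_bench_dataset(n_rays = 16384, seed = 1)   # ~36 poses x 19 tx x 9 sessions
fm <- build_feature_matrix(ds$features)                  # 1620 x 38
cv <- cross_validate_gaze(fm$X, fm$Y, kind = "gbrt", seed = 11)
print(cv)
#> 5-fold CV (gbrt): RMSE 0.784 +/- 0.037 deg, adj-R2 94.0 +/- 0.6 %
```

Configuration (geometry, protocol, noise, filters, GBRT) lives in a
structured YAML file read by `read_run_config()`; every output CSV gets a
JSON sidecar with the seed and configuration hash.

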