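# pedalkin

Kinematics and load analytics for sensor-instrumented ergometer pedals.

Instrumented pedals used in rehabilitation training stream, per pedal at
25 Hz, a 3-axis accelerometer, a 3-axis gyroscope and the resonance
frequencies of four inductive (LC-tank) load-sensing coils. `pedalkin`
turns those streams into the quantities a therapist or athlete works
with — crank angle, cadence, pedal (ankle) angle, applied loads — and
into post-session summaries and game-control signals for interactive
training. It is aimed at engineers and movement scientists building or
evaluating such sensing chains.

## The method in brief

With crank-arm length *r* and revolutions traversed at approximately
constant rate, the squared magnitude of the pedal's acceleration is

a² = r²φ̇⁴ + 2 g r φ̇² cos φ + g²,

maximal at top dead centre (φ = 0°) and minimal at bottom dead centre
(φ = 180°). Crank angle is recovered by detecting the alternating
extrema of the low-pass-filtered a² (zero-phase second-order Butterworth,
f_c = 2.2 Hz), refining them to sub-sample precision, anchoring them at
0°/180° and interpolating linearly in time; cadence follows from the
half-revolution intervals, and the left–right crank offset (nominally
180°) serves as a built-in accuracy check.

The pedal angle combines two weak estimators in a scalar Kalman filter:
the accelerometer-only angle θ̂ₐ = atan2(−aₓ, a_z) (exact only for a
stationary crank; biased by the centripetal term while pedalling) as the
measurement, and dead-reckoned integration of the gyroscope pitch rate
ω = θ̇ as the process model θ[k] = θ[k−1] + ω T_s. Innovations are
wrapped to (−180°, 180°] so the ±180° seam of the arctangent cannot
unwind the state.

Loads are mapped from the four coil frequencies by per-channel LASSO
regressions (Fx, Fz, Mx), with the regularisation strength chosen by
10-fold cross-validation over 25 log-spaced values in [10⁻¹⁰, 10²] on a
seeded 70/30 train/test split; accuracy is reported as μ, σ, MAE, RMSE
and R² on the untouched test set.

A forward simulator (`make_session()` and friends) generates complete
two-sided sessions with known ground truth — crank phase, pedal angle,
loads and a sign-structured linear load→frequency surrogate — and is the
oracle for the entire test suite.

## Worked example

```r
library(pedalkin)

# a 60 s two-sided session at 65 rpm with default sensor noise
sim <- make_session(duration = 60, cadence_rpm = 65, seed = 42)
sim$session
#> <pedal_session> 3000 samples (L: 1500, R: 1500), fs = 25 Hz, r = 0.17 m, g = 9.81 m/s^2

est <- estimate_session(sim$session)
round(est$lr_offset_deg, 2)
#>   mean     sd
#> 180.01   2.40
```

The estimated left–right crank offset of 180.01° (spread 2.4°) recovers
the mechanical 180° mounting, confirming the crank chain end to end.

```r
eL <- est$estimates[est$estimates$side == "L", ]
mean(eL$cadence_rpm, na.rm = TRUE)
#> [1] 65
rmse <- function(a, b) sqrt(mean((a - b)^2))
rmse(eL$theta_rough_deg, sim$truth$L$theta_deg)  # accelerometer only
#> [1] 35.2
rmse(eL$theta_deg, sim$truth$L$theta_deg)        # Kalman-fused
#> [1] 3.28
```

The fusion cuts the pedal-angle error from 35.2° to 3.3° RMSE: at
65 rpm the centripetal acceleration badly biases the accelerometer-only
angle, and the gyroscope supplies the missing dynamics.

```r
# calibrate the load sensor on a simulated bench run, then use it
rec <- simulate_calibration_records(seed = 42)
model <- fit_calibration(rec, seed = 42)
model
#> <calibration_model> channels: Fx, Fz, Mx (folds=10, test=30%)
#>   Fx: alpha=1e-10  MAE=0.3198  RMSE=0.4026  R2=1
#>   Fz: alpha=1e-10  MAE=0.2381  RMSE=0.2959  R2=1
#>   Mx: alpha=1e-10  MAE=0.03976 RMSE=0.05048 R2=0.9992

freqs <- subset(sim$session$samples, side == "L",
                select = c(f0, f1, f2, f3))
loads <- predict_loads(model, freqs)
prof <- force_by_crank_angle(loads$Fx, loads$Fz, est$traces$L)
prof$mid[which.max(prof$mean)]
#> [1] 95
```

The crank-phase force profile peaks in the 95° bin — the downstroke,
where the simulated load bump is centred (90°). Test-set MAEs of a few
tenths of a newton reflect the 1 Hz frequency noise on an exactly linear
surrogate sensor; a physical cell is nonlinear and lands far higher.

```r
game_controls(65, left_force = 120, right_force = 100)
#> speed 65, yaw 0.091  (harder-working left side steers left)
```

A command-line front end wrapping these functions ships in
`inst/cli/pedalkin.R` (subcommands `validate`, `simulate`, `estimate`,
`calibrate`).

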