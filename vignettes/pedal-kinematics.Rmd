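---
title: "Estimating pedalling kinematics and loads from instrumented pedals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pedalling kinematics and loads from instrumented pedals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedalkin)
```

## The measurement problem

Sensor-instrumented ergometer pedals stream, per pedal and at a low rate
(25 Hz, constrained by the wireless link), a three-axis accelerometer, a
three-axis gyroscope and the resonance frequencies of four inductive
(LC-tank) load-sensing coils. From these streams the analysis has to
recover quantities that the rider and therapist actually care about: the
crank angle $\phi$ (measured from the world vertical, top dead centre
TDC at $\phi = 0°$, bottom dead centre BDC at $180°$), the cadence
$\dot\phi$, the pedal angle $\theta$ (against the world horizontal, a
proxy for ankle angle, mechanically confined to a subrange of
$[-90°, 90°]$), and the applied loads: forward shear $F_x$, normal force
$F_z$ and the crank-axis torque $M_x$.

`pedalkin` implements the full chain — session I/O, pre-processing,
crank and pedal-angle estimation, load calibration and post-session
analytics — together with a forward simulator that generates sessions
with known ground truth. Every estimator in the package is tested
against that simulator, not against recordings: no reference bench rig,
force sensor or camera system ships with a software package, so accuracy
claims here are *consistency* claims about the model chain, quantified
on synthetic data whose generating process is known exactly.

## Forward model

The pedal rides the crank at radius $r$ (default 0.17 m). For
revolutions traversed at an approximately constant rate
($\ddot\phi \approx 0$), the body-frame specific force is the
centripetal term plus gravity, rotated into the pedal frame by $\theta$:

$$
a_x = -r\dot\phi^2\,(\sin\phi\cos\theta + \cos\phi\sin\theta) - g\sin\theta,
\qquad
a_z = -r\dot\phi^2\,(\sin\phi\sin\theta - \cos\phi\cos\theta) + g\cos\theta,
$$

with $a_y = 0$ (planar constraint). Its squared magnitude is
rotation-invariant and therefore independent of $\theta$:

$$
a^2 = r^2\dot\phi^4 + 2\,g\,r\,\dot\phi^2\cos\phi + g^2 ,
$$

maximal at TDC and minimal at BDC. This single scalar signal carries the
crank phase. The gyroscope's pitch component measures the pedal angular
rate $\omega = \dot\theta$ directly.

The simulator (`simulate_crank_trajectory()`, `simulate_pedal_angle()`,
`simulate_imu()`, `simulate_loads()`, `loads_to_frequencies()`,
`make_session()`) evaluates exactly this model. Design choices worth
knowing:

* **Per-revolution constant rate.** The cadence profile (constant or a
  slowly varying function of time) is quantised per revolution: each
  revolution's rate is chosen so that the phase at revolution boundaries
  equals the exact time-integral of the profile. Rate changes thus occur
  only between revolutions — the same assumption the estimator makes —
  while total revolutions match the profile integral to within a sample.
* **Ankle model.** The admissible range of $\theta$ is known but its
  trajectory is not specified by the hardware; the simulator uses a
  crank-phase-locked sinusoid
  $\theta = \theta_0 + A\sin(\phi + \varphi)$ with
  $|\theta_0| + |A| \le 90°$, defaults $\theta_0 = 0°$, $A = 20°$ — a
  plausible plantar/dorsiflexion excursion. The gyroscope truth is the
  central finite difference of $\theta(t)$, keeping gyro and angle
  consistent for dead-reckoning tests.
* **Loads.** Each channel is a smooth half-cosine bump per revolution,
  peaking at a configurable crank phase (default 90°, the downstroke),
  with peaks confined to the bench calibration ranges
  ($F_x \in [-189.72, 243.81]$ N, $F_z \in [-244.12, 555.28]$ N,
  $M_x \in [-2.618, 3.329]$ Nm). Defaults: 60 N / 300 N / 1 Nm.
* **Load sensor surrogate.** The physical LC-tank cell is replaced by an
  affine map from $(F_x, F_z, M_x)$ to the four coil frequencies. Only
  its sign structure is contractual: $F_x$ shifts coil 0 opposite to
  coils 1 and 2; $M_x$ leaves coil 0 unchanged and shifts coils 1 and 2
  oppositely; $F_z$ shifts coils 0–2 equally. The fourth channel is
  redundant and mirrors coil 0. Magnitudes (≈250 kHz baselines, Hz-per-N
  sensitivities) are order-of-magnitude placeholders, not an
  electromagnetic model.
* **Noise.** i.i.d. Gaussian per channel: $\sigma_{accel} = 0.5$ m/s²,
  $\sigma_{gyro} = 0.02$ rad/s, $\sigma_f = 1$ Hz by default. These are
  plausible for a consumer MEMS IMU and a fast inductance-to-digital
  readout; the device datasheets do not pin them down. Every stochastic
  operation takes an explicit seed; identical seeds give identical
  output.
* **Two sides.** The right crank is mounted exactly 180° out of phase.
  The two sides keep independent clocks; optional uniform per-sample
  time-stamp jitter (must stay below half a sampling interval) emulates
  unsynchronised logging.

What the simulator does *not* emulate: within-revolution cadence
fluctuations, pedal wobble out of the crank plane, correlated or
load-dependent sensor noise, soft-tissue dynamics, and the ergometer's
resistance dynamics. Passing tests therefore demonstrate that the
estimator chain inverts its own modelling assumptions at realistic
noise levels — not that it reaches any particular accuracy on human
recordings.

## Pre-processing

All analysis-relevant signals pass through a second-order Butterworth
low-pass at $f_c = 2.2$ Hz, applied forward and backward
(`lowpass_zero_phase()`), giving zero phase shift and the squared
magnitude response. Edges are handled with odd-reflection padding of
length $3(\text{order}+1)$ and steady-state initial conditions on each
pass. The cutoff sits above the pedalling fundamental at usual cadences
(40–90 rpm → 0.67–1.5 Hz) and far below the 12.5 Hz Nyquist limit.
Signals shorter than the padding are rejected with an explicit error.
Non-uniform time stamps are ignored at this stage — the filter operates
on sample index at the nominal rate — and `validate_session()` flags
sessions where the mean interval deviates more than 10% from nominal.

One ordering subtlety: the crank-detection signal $a^2$ is computed from
the **raw** acceleration components and the magnitude signal itself is
filtered. Filtering the components first would attenuate their second
harmonic (gain ≈ 0.59 at 2 Hz for two passes at $f_c = 2.2$ Hz), and
squaring mixes harmonics, so the distortion displaces the extrema of the
squared sum; measured on noiseless 60 rpm sessions this inflated the
crank-angle error from ≈0.001° to ≈3.6° MAE. The rough pedal angle, by
contrast, is a ratio of filtered components and benefits from the usual
stream filtering.

## Crank angle, cadence and the left–right check

`detect_extrema()` finds the alternating maxima (TDC) and minima (BDC)
of the filtered $a^2$. Peak picking uses: a minimum event spacing of
$60/(2 \cdot \text{cadence}_{max})$ s (default ceiling 150 rpm); adaptive
pruning of wiggles below half the median event-to-event amplitude; and
strict alternation with ties resolved toward the more extreme sample.
Each surviving extremum is then refined to sub-sample precision with a
three-point parabolic fit. The refinement matters at this sampling rate:
one sample at 25 Hz spans 14.4° of crank phase at 60 rpm, and a dead
centre falling midway between samples would otherwise displace its
anchor by up to 7.2°.

`interpolate_crank_angle()` anchors TDC at $0° \pmod{360}$ and BDC at
$180°$ and interpolates linearly in time — the piecewise-constant-rate
assumption again. Samples outside the first and last event are marked
invalid rather than extrapolated. Cadence is $30/\Delta t$ rpm per
half-revolution interval, piecewise constant; forward pedalling is
assumed throughout ($a^2$ is direction-blind, and direction detection is
out of scope).

Because the two cranks are mechanically 180° apart, the offset between
the independently estimated left and right crank angles is a built-in
accuracy check (`lr_offset()`). The right-side angle is linearly
interpolated across the bracketing right time stamps at every valid left
sample (the clocks are not assumed synchronised), and the circular mean
and circular standard deviation of $\phi_R - \phi_L$ are reported. On
noiseless constructions with 5 ms clock jitter the package recovers
$180° \pm 0.2°$ with a spread of ≈1.2–1.4°.

## Pedal angle: rough estimate and Kalman fusion

The accelerometer-only ("rough") pedal angle is
$\hat\theta_a = \mathrm{atan2}(-a_x, a_z)$, the gravity direction in the
pedal frame. The sign of the first argument is fixed so that a
stationary pedal tilted by $\theta$ returns $+\theta$ (the uncorrected
arctangent of the stationary-case components returns $-\theta$). The
estimate is exact only for a stationary crank; while pedalling, the
centripetal term biases it by up to
$\mathrm{atan2}(r\dot\phi^2, g)$ — about 34° at 60 rpm — and once
$r\dot\phi^2 > g$ (≈73 rpm at $r = 0.17$ m) the sensed acceleration
vector rotates full circles and the rough angle sweeps through all
values once per revolution.

`kalman_pedal_angle()` fuses the gyroscope with this measurement in a
scalar Kalman filter: predict
$\theta^- = \theta + \omega T_s$, $P^- = P + Q$; update with
$y = \hat\theta_a$ and variance $R$. Defaults, exposed via
`kf_params()`:

* $T_s = 1/f_s$;
* $Q = (\sigma_{gyro} T_s \cdot 180/\pi)^2$ — the angle-increment
  variance implied by the gyro noise — times a tunable factor (default
  1);
* $R = 100$ deg², reflecting that the measurement error is dominated by
  the centripetal bias (tens of degrees), not sensor noise;
* $\theta_0$ = first valid measurement, $P_0 = R$.

The innovation $y - \theta^-$ is wrapped to $(-180°, 180°]$ before the
update. This removes the $\pm 180°$ seam of the arctangent without
letting a drifting measurement unwind the state: globally unwrapping
$\hat\theta_a$ instead makes the filter follow the measurement's
360°-per-revolution drift at fast cadences (measured: ≈104° RMSE at
90 rpm, versus ≈10° with innovation wrapping). `NA` measurements (a
vanishing in-plane acceleration) trigger a predict-only step.

Under the default noise model at 60 rpm the fusion reduces the
pedal-angle RMSE from ≈29° (rough) to ≈3° — an ≈89% reduction, and the
filter wins in 20/20 seeded runs across cadences 40–90 rpm and ankle
amplitudes 5–30°. The margin is generous because the simulator's noise
is exactly the Gaussian the filter assumes; on human data, where the
centripetal bias is correlated with the pedalling cycle, the improvement
is necessarily smaller.

## Load calibration

Calibration data pair the four coil frequencies with a simultaneously
logged reference load, per channel (`simulate_calibration_records()`
emulates the bench protocol: eight triangular loading cycles sweeping
each channel's range). `fit_calibration()` fits, per channel, an
L1-regularised (LASSO) linear map on a seeded 70/30 train/test split,
choosing the regularisation strength by 10-fold cross-validation over 25
log-spaced values in $[10^{-10}, 10^{2}]$ — minimum mean CV squared
error, ties toward the larger (sparser) value. Features are standardised
internally so the grid is meaningful across Hz-scale channels;
coefficients are reported in raw units. Standardisation is explicit
(centre, population scale) rather than delegated, because the
pure-normal-force protocol makes all four coils shift equally — a
near-collinear design on which the delegated path failed to converge at
the small-$\alpha$ end of the grid. Test-set accuracy is reported as
`error_stats()`: $\mu$, $\sigma$, MAE, RMSE, $R^2$, using the population
convention (divide by $n$), under which
$\text{RMSE}^2 = \mu^2 + \sigma^2$ holds exactly. On noise-free
surrogate data the fit recovers the affine map to $\text{MAE} < 10^{-6}$
with $R^2 = 1$; with frequency noise it tracks the ordinary
least-squares floor on the identical split.

## Analytics and game controls

`binned_force_magnitude()` averages the in-plane magnitude
$\sqrt{F_x^2 + F_z^2}$ (the lateral component is not sensed) over 1 s
bins with a $\pm 1$ population standard deviation band;
`force_by_crank_angle()` does the same over 36 angular bins (10° — the
bin width is a package default, chosen to resolve the downstroke bump
without emptying bins at session lengths of a few minutes).
`per_side_breakdown()` summarises cadence, pedal angle and forces per
side over the whole session or a sub-interval. `game_controls()` maps
cadence to the speed of the in-game avatar and the left/right force
balance to yaw via $(L - R)/(L + R)$, clipped to $[-1, 1]$, zero when
unloaded — positive steers left, matching the rule that the harder-working
side pulls the avatar toward itself. The ratio form is an implementation
choice (only the direction contract is fixed by the application); it is
dimensionless, antisymmetric under side swap and saturates gracefully.

## Numerical conventions and degenerate inputs

* Angles are degrees at every user-facing boundary, radians inside
  trigonometric kernels; angular rates are rad/s on disk and in
  `SensorSample`s.
* Session and calibration CSVs carry 9 significant digits — beyond
  sensor resolution — so write → read → write is byte-identical.
* Constant signals yield no extrema (warning, empty result); a constant
  reference makes $R^2$ undefined (`NA`); zero in-plane acceleration
  marks the rough angle invalid at that sample; empty analytics bins
  report `NA` with count 0.
* Time stamps within a side must be non-decreasing (read error names the
  first offending row); the two sides are never assumed aligned.
* Problem sizes used in the test suite and the acceptance script — 60 s
  sessions at 25 Hz, 20-seed repetitions, 1200-record calibration runs —
  are the package's standard desk-scale verification conditions; the
  whole suite runs in well under a minute.

## Known limitations

The constant-rate-per-revolution assumption breaks down for riders with
strongly non-uniform crank motion, which is precisely the impaired
population a rehabilitation device targets; the crank estimator then
interpolates through rate changes and its error grows. The measurement
noise entering the Kalman filter is modelled as white, while the real
centripetal bias is periodic and correlated with crank phase — a dynamic
(phase-dependent) measurement variance would track the pedal-angle
extrema better. The load surrogate is linear by construction; a physical
LC-tank has geometric nonlinearity that a linear map can only
approximate within the calibrated range. None of these limitations
affect the package's internal consistency guarantees, but all of them
temper extrapolation to clinical recordings.
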