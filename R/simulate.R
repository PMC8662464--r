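## Forward model of an instrumented-pedal session. The simulator produces
## sessions with known ground truth (crank angle, pedal angle, loads) and
## is the oracle against which every estimator in the package is tested.

LOAD_CHANNELS <- c("Fx", "Fz", "Mx")

#' Bench calibration ranges per load channel
#'
#' Admissible load ranges of the calibration rig: forward shear `Fx` and
#' normal force `Fz` in N, crank-axis torque `Mx` in Nm. Simulated load
#' peaks and calibration sweeps are confined to these ranges.
#' @export
CALIBRATION_RANGES <- list(
  Fx = c(-189.72, 243.81),
  Fz = c(-244.12, 555.28),
  Mx = c(-2.618, 3.329)
)

#' Sensor noise model
#'
#' Additive i.i.d. Gaussian noise applied to each simulated channel. The
#' defaults are plausible for a consumer-grade MEMS IMU after quantisation
#' and for an inductance-to-digital frequency readout at short conversion
#' times; the device datasheets do not pin them down, so they are exposed
#' here as the single place to change them.
#'
#' @param sigma_accel accelerometer noise s.d. (m/s^2) per axis.
#' @param sigma_gyro gyroscope noise s.d. (rad/s) per axis.
#' @param sigma_freq resonance-frequency noise s.d. (Hz) per channel.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream (used when a caller manages seeding for a whole session).
#' @return list of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(sigma_accel = 0.5, sigma_gyro = 0.02,
                               sigma_freq = 1, seed = NULL) {
  stopifnot(sigma_accel >= 0, sigma_gyro >= 0, sigma_freq >= 0)
  structure(list(sigma_accel = sigma_accel, sigma_gyro = sigma_gyro,
                 sigma_freq = sigma_freq, seed = seed),
            class = "sensor_noise_model")
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Linear load-to-frequency sensor surrogate
#'
#' Stand-in for the physical LC-tank load cell: an affine map from the
#' three sensed loads (Fx, Fz, Mx) to the four coil resonance frequencies.
#' Only the sign structure of the sensitivity matrix is contractual, and it
#' encodes how the coil layout separates the load components:
#' a forward shear `Fx` shifts coil 0 one way and coils 1 and 2 the
#' opposite way; a torque `Mx` leaves coil 0 unchanged and shifts coils 1
#' and 2 in opposite directions; a normal force `Fz` shifts coils 0-2
#' equally. Coil 3 is treated as a redundant channel and by default
#' duplicates coil 0's pattern. The default magnitudes (hundreds-of-kHz
#' baseline, Hz-per-N shifts) are order-of-magnitude placeholders; this is
#' a synthetic surrogate, not a fitted electromagnetic model.
#'
#' @param baseline length-4 vector of unloaded resonance frequencies (Hz).
#' @param sensitivity 4 x 3 matrix (rows: coils 0-3; columns: Fx, Fz, Mx)
#'   in Hz/N, Hz/N, Hz/Nm.
#' @return list of class `load_sensor_surrogate`.
#' @export
load_sensor_surrogate <- function(
    baseline = c(250e3, 251e3, 252e3, 253e3),
    sensitivity = rbind(
      c( 1.2, -2.0,   0),   # coil 0
      c(-0.8, -2.0,  15),   # coil 1
      c(-0.8, -2.0, -15),   # coil 2
      c( 1.2, -2.0,   0))   # coil 3 (redundant, mirrors coil 0)
) {
  stopifnot(length(baseline) == 4L, all(baseline > 0),
            is.matrix(sensitivity), all(dim(sensitivity) == c(4L, 3L)))
  s <- sensitivity
  ok_fx <- s[1, 1] != 0 && sign(s[2, 1]) == -sign(s[1, 1]) &&
    sign(s[3, 1]) == -sign(s[1, 1])
  ok_fz <- s[1, 2] != 0 && s[1, 2] == s[2, 2] && s[2, 2] == s[3, 2]
  ok_mx <- s[1, 3] == 0 && s[2, 3] != 0 && sign(s[2, 3]) == -sign(s[3, 3])
  if (!ok_fx || !ok_fz || !ok_mx) {
    stop("sensitivity matrix violates the coil sign pattern ",
         "(Fx: coil 0 opposite to coils 1,2; Fz: coils 0-2 equal; ",
         "Mx: coil 0 zero, coils 1,2 opposite)", call. = FALSE)
  }
  colnames(sensitivity) <- LOAD_CHANNELS
  structure(list(baseline = baseline, sensitivity = sensitivity),
            class = "load_sensor_surrogate")
}

as_cadence_fn <- function(cadence_rpm) {
  if (is.function(cadence_rpm)) return(cadence_rpm)
  stopifnot_scalar(cadence_rpm, "cadence_rpm")
  function(t) rep(cadence_rpm, length(t))
}

## Revolution-quantised crank phase: each revolution is traversed at the
## constant rate that accumulates exactly one turn of the cadence
## profile's time integral, so phase at revolution boundaries matches the
## integral exactly and the rate changes only between revolutions.
crank_phase_model <- function(duration, cadence_rpm, fs) {
  cad_fn <- as_cadence_fn(cadence_rpm)
  tf <- seq(0, duration, by = 1 / (fs * 20))
  cad <- cad_fn(tf) / 60                      # rev/s
  if (any(!is.finite(cad)) || any(cad <= 0)) {
    stop("cadence profile must be strictly positive and finite",
         call. = FALSE)
  }
  revs <- cumtrapz(tf, cad)
  n_full <- floor(revs[length(revs)])
  bounds <- if (n_full >= 1) {
    approx(x = revs, y = tf, xout = seq_len(n_full), ties = "ordered")$y
  } else numeric(0)
  bounds <- c(0, bounds)
  # open-ended final segment at the rate current at its start
  last_rate <- cad_fn(bounds[length(bounds)]) / 60
  bounds_ext <- c(bounds, bounds[length(bounds)] + 1 / last_rate)
  seg_len <- diff(bounds_ext)
  list(
    phi = function(t) {
      j <- pmax(pmin(findInterval(t, bounds_ext), length(seg_len)), 1L)
      wrap_deg(360 * ((j - 1) + (t - bounds_ext[j]) / seg_len[j]))
    },
    phi_unwrapped = function(t) {
      j <- pmax(pmin(findInterval(t, bounds_ext), length(seg_len)), 1L)
      360 * ((j - 1) + (t - bounds_ext[j]) / seg_len[j])
    },
    phidot = function(t) {
      j <- pmax(pmin(findInterval(t, bounds_ext), length(seg_len)), 1L)
      2 * pi / seg_len[j]
    }
  )
}

#' Simulate a crank trajectory
#'
#' Generates the ground-truth crank angle and cadence for a session under
#' the modelling assumption that each individual revolution is traversed at
#' a constant rate (negligible within-revolution angular acceleration)
#' while the cadence may drift slowly from revolution to revolution. Phase
#' zero is top dead centre (TDC, pedal highest); the angle grows in the
#' forward-pedalling direction and is wrapped to \[0, 360).
#'
#' @param duration session length (s).
#' @param cadence_rpm constant cadence (rpm) or a function of time in
#'   seconds returning rpm; must be strictly positive throughout.
#' @param fs sampling rate (Hz).
#' @param t optional explicit sample times (s); defaults to a regular grid
#'   of `floor(duration * fs)` samples starting at 0.
#' @return data frame of class `trajectory_truth` with `t`, `phi_deg`
#'   (wrapped), `phi_unwrapped_deg` and `phidot_rad_s`.
#' @export
#' @examples
#' tr <- simulate_crank_trajectory(2, 60, fs = 25)
#' range(tr$phi_deg)
simulate_crank_trajectory <- function(duration, cadence_rpm, fs = 25,
                                      t = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (is.null(t)) t <- (seq_len(floor(duration * fs)) - 1L) / fs
  model <- crank_phase_model(duration, cadence_rpm, fs)
  out <- data.frame(
    t = t,
    phi_deg = model$phi(t),
    phi_unwrapped_deg = model$phi_unwrapped(t),
    phidot_rad_s = model$phidot(t)
  )
  class(out) <- c("trajectory_truth", "data.frame")
  out
}

#' Simulate the pedal (ankle) angle
#'
#' Fills the pedal-angle channel of a trajectory with a crank-phase-locked
#' sinusoid, `theta(t) = theta0 + amplitude * sin(phi(t) + phase)`. The
#' pedal angle is measured against the world horizontal and must stay
#' inside the mechanically admissible \[-90, 90\] degrees, which constrains
#' `|theta0| + |amplitude| <= 90`.
#'
#' @param truth a `trajectory_truth` from [simulate_crank_trajectory()].
#' @param theta0 mean pedal angle (deg).
#' @param amplitude oscillation amplitude (deg).
#' @param phase crank phase of the oscillation (deg).
#' @return the truth with a `theta_deg` column added.
#' @export
simulate_pedal_angle <- function(truth, theta0 = 0, amplitude = 20,
                                 phase = 0) {
  stopifnot(inherits(truth, "trajectory_truth"))
  if (abs(theta0) + abs(amplitude) > 90) {
    stop("|theta0| + |amplitude| must not exceed 90 degrees", call. = FALSE)
  }
  truth$theta_deg <- theta0 +
    amplitude * sin(deg2rad(truth$phi_deg + phase))
  truth
}

#' Simulate the IMU output
#'
#' Body-frame specific force of a pedal riding the crank at radius `r`:
#' the centripetal term of magnitude `r * phidot^2` directed from the pedal
#' towards the crank axle, plus gravity, both rotated into the pedal frame
#' by the pedal angle. In components (x forward, z down-normal):
#' \deqn{a_x = -r\dot\phi^2(\sin\phi\cos\theta + \cos\phi\sin\theta) - g\sin\theta}
#' \deqn{a_z = -r\dot\phi^2(\sin\phi\sin\theta - \cos\phi\cos\theta) + g\cos\theta}
#' with `a_y = 0` (the pedal is constrained to the xz-plane). The gyroscope
#' senses the pedal pitch rate: its y-component is the central finite
#' difference of the true pedal angle; the other components are zero.
#' Gaussian noise is added per the noise model.
#'
#' @param truth complete `trajectory_truth` (with `theta_deg`).
#' @param r crank-arm length (m).
#' @param g gravitational acceleration (m/s^2).
#' @param noise a [sensor_noise_model()].
#' @param seed integer seed for the noise draws; defaults to the model's.
#' @return data frame `t, ax, ay, az, gx, gy, gz`.
#' @export
simulate_imu <- function(truth, r, g = 9.81,
                         noise = sensor_noise_model(0, 0, 0),
                         seed = noise$seed) {
  stopifnot(inherits(truth, "trajectory_truth"))
  if (is.null(truth$theta_deg)) {
    stop("truth is incomplete: theta_deg missing ",
         "(run simulate_pedal_angle first)", call. = FALSE)
  }
  stopifnot_scalar(r, "r", positive = TRUE)
  phi <- deg2rad(truth$phi_deg)
  th <- deg2rad(truth$theta_deg)
  w2 <- truth$phidot_rad_s^2
  ax <- -r * w2 * (sin(phi) * cos(th) + cos(phi) * sin(th)) - g * sin(th)
  az <- -r * w2 * (sin(phi) * sin(th) - cos(phi) * cos(th)) + g * cos(th)
  n <- nrow(truth)
  # pitch rate from the theta truth itself so gyro and angle stay consistent
  gy <- deg2rad(fd_gradient(truth$theta_deg, truth$t))
  out <- data.frame(t = truth$t, ax = ax, ay = 0, az = az,
                    gx = 0, gy = gy, gz = 0)
  with_opt_seed(seed, {
    if (noise$sigma_accel > 0) {
      for (cc in c("ax", "ay", "az")) {
        out[[cc]] <- out[[cc]] + rnorm(n, 0, noise$sigma_accel)
      }
    }
    if (noise$sigma_gyro > 0) {
      for (cc in c("gx", "gy", "gz")) {
        out[[cc]] <- out[[cc]] + rnorm(n, 0, noise$sigma_gyro)
      }
    }
  })
  out
}

## Central finite difference with one-sided ends.
fd_gradient <- function(y, t) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d
}

#' Simulate pedal loads
#'
#' Crank-phase-locked load profiles: each channel is a smooth half-cosine
#' bump per revolution, centred at `peak_phase_deg` (default 90 degrees,
#' the downstroke) with half-width `halfwidth_deg`, scaled to the given
#' peak. Peaks must lie inside the bench calibration range of their
#' channel ([CALIBRATION_RANGES]).
#'
#' @param truth `trajectory_truth` with `phi_deg`.
#' @param peak_Fx,peak_Fz,peak_Mx peak loads (N, N, Nm).
#' @param peak_phase_deg crank angle of the load maximum (deg).
#' @param halfwidth_deg half-width of the bump (deg).
#' @return the truth with `Fx`, `Fz`, `Mx` columns added.
#' @export
simulate_loads <- function(truth, peak_Fx = 60, peak_Fz = 300, peak_Mx = 1,
                           peak_phase_deg = 90, halfwidth_deg = 90) {
  stopifnot(inherits(truth, "trajectory_truth"))
  peaks <- c(Fx = peak_Fx, Fz = peak_Fz, Mx = peak_Mx)
  for (ch in LOAD_CHANNELS) {
    rg <- CALIBRATION_RANGES[[ch]]
    if (peaks[[ch]] < rg[1] || peaks[[ch]] > rg[2]) {
      stop(sprintf("peak_%s = %g outside calibration range [%g, %g]",
                   ch, peaks[[ch]], rg[1], rg[2]), call. = FALSE)
    }
  }
  delta <- wrap_pm180(truth$phi_deg - peak_phase_deg)
  w <- ifelse(abs(delta) <= halfwidth_deg,
              cos(pi / 2 * delta / halfwidth_deg), 0)
  truth$Fx <- peak_Fx * w
  truth$Fz <- peak_Fz * w
  truth$Mx <- peak_Mx * w
  truth
}

#' Map loads to LC-tank resonance frequencies
#'
#' Applies the affine surrogate: `freqs = baseline + sensitivity %*%
#' (Fx, Fz, Mx)` per sample, plus optional Gaussian frequency noise. The
#' noiseless map is exactly linear in the loads.
#'
#' @param loads data frame with `Fx`, `Fz`, `Mx` columns (a completed
#'   truth works directly).
#' @param surrogate a [load_sensor_surrogate()].
#' @param noise a [sensor_noise_model()].
#' @param seed integer seed for the noise draws.
#' @return matrix with columns `f0`..`f3` (Hz), one row per sample.
#' @export
loads_to_frequencies <- function(loads, surrogate = load_sensor_surrogate(),
                                 noise = sensor_noise_model(0, 0, 0),
                                 seed = noise$seed) {
  stopifnot(inherits(surrogate, "load_sensor_surrogate"))
  L <- as.matrix(as.data.frame(loads)[, LOAD_CHANNELS, drop = FALSE])
  f <- L %*% t(surrogate$sensitivity)
  f <- sweep(f, 2, surrogate$baseline, "+")
  colnames(f) <- FREQ_COLUMNS
  if (noise$sigma_freq > 0) {
    with_opt_seed(seed, {
      f <- f + matrix(rnorm(length(f), 0, noise$sigma_freq), nrow = nrow(f))
    })
  }
  f
}

#' Simulate a complete two-sided session
#'
#' Builds a full session with ground truth for both pedals. The right
#' crank is mounted exactly 180 degrees out of phase with the left, so the
#' right-side truth satisfies `phi_R = phi_L + 180 (mod 360)` by
#' construction. The two sides keep independent time stamps; optional
#' per-sample uniform jitter emulates unsynchronised logging clocks.
#'
#' @param duration session length (s).
#' @param cadence_rpm constant rpm or function of time (s) returning rpm.
#' @param theta0,amplitude,phase ankle model, see [simulate_pedal_angle()].
#' @param peak_Fx,peak_Fz,peak_Mx load peaks, see [simulate_loads()].
#' @param surrogate load sensor surrogate, or `NULL` for an IMU-only
#'   session (frequency channels absent).
#' @param noise a [sensor_noise_model()].
#' @param fs sampling rate (Hz).
#' @param r crank-arm length (m).
#' @param g gravitational acceleration (m/s^2).
#' @param jitter_s half-range of the uniform per-sample time-stamp jitter
#'   (s); must stay below half a sampling interval.
#' @param seed integer seed governing every random draw; identical seeds
#'   give identical sessions.
#' @return list with `session` (a [pedal_session()]) and `truth` (list of
#'   `trajectory_truth` for sides `L` and `R`).
#' @export
#' @examples
#' sim <- make_session(duration = 10, cadence_rpm = 60, seed = 1)
#' sim$session
make_session <- function(duration = 60, cadence_rpm = 60,
                         theta0 = 0, amplitude = 20, phase = 0,
                         peak_Fx = 60, peak_Fz = 300, peak_Mx = 1,
                         surrogate = load_sensor_surrogate(),
                         noise = sensor_noise_model(),
                         fs = 25, r = 0.17, g = 9.81,
                         jitter_s = 0, seed = 1L) {
  stopifnot(jitter_s >= 0)
  if (jitter_s >= 0.5 / fs) {
    stop("jitter_s must be below half a sampling interval", call. = FALSE)
  }
  withr::with_seed(seed, {
    base_t <- (seq_len(floor(duration * fs)) - 1L) / fs
    model <- crank_phase_model(duration, cadence_rpm, fs)
    sides <- list()
    truths <- list()
    for (sd in c("L", "R")) {
      t <- base_t
      if (jitter_s > 0) {
        t <- t + runif(length(t), -jitter_s, jitter_s)
        t <- sort(t)  # guaranteed non-crossing for jitter < dt/2
      }
      offset <- if (sd == "L") 0 else 180
      truth <- data.frame(
        t = t,
        phi_deg = wrap_deg(model$phi(t) + offset),
        phi_unwrapped_deg = model$phi_unwrapped(t) + offset,
        phidot_rad_s = model$phidot(t)
      )
      class(truth) <- c("trajectory_truth", "data.frame")
      truth <- simulate_pedal_angle(truth, theta0, amplitude, phase)
      truth <- simulate_loads(truth, peak_Fx, peak_Fz, peak_Mx)
      imu <- simulate_imu(truth, r = r, g = g, noise = noise, seed = NULL)
      tab <- data.frame(time_s = t, side = sd,
                        ax = imu$ax, ay = imu$ay, az = imu$az,
                        gx = imu$gx, gy = imu$gy, gz = imu$gz)
      if (!is.null(surrogate)) {
        fr <- loads_to_frequencies(truth, surrogate, noise, seed = NULL)
        tab <- cbind(tab, as.data.frame(fr))
      }
      sides[[sd]] <- tab
      truths[[sd]] <- truth
    }
    session <- pedal_session(do.call(rbind, sides), fs = fs, r = r, g = g)
    list(session = session, truth = truths)
  })
}

#' Simulate a bench calibration run
#'
#' Emulates the bench protocol: per channel, the rig is loaded in repeated
#' cycles sweeping the channel's calibration range (a triangular
#' load ramp, `n_cycles` cycles), with the remaining channels unloaded,
#' while frequencies are logged through the surrogate with noise.
#'
#' @param surrogate a [load_sensor_surrogate()].
#' @param noise a [sensor_noise_model()] (only `sigma_freq` is used).
#' @param n_cycles loading cycles per channel.
#' @param n_per_cycle samples per cycle.
#' @param seed integer seed.
#' @return data frame of calibration records
#'   (`f0..f3`, `load`, `channel`).
#' @export
simulate_calibration_records <- function(surrogate = load_sensor_surrogate(),
                                         noise = sensor_noise_model(),
                                         n_cycles = 8, n_per_cycle = 50,
                                         seed = 1L) {
  withr::with_seed(seed, {
    recs <- lapply(LOAD_CHANNELS, function(ch) {
      rg <- CALIBRATION_RANGES[[ch]]
      u <- rep(c(seq(0, 1, length.out = ceiling(n_per_cycle / 2)),
                 seq(1, 0, length.out = floor(n_per_cycle / 2))), n_cycles)
      load <- rg[1] + u * (rg[2] - rg[1])
      loads <- data.frame(Fx = 0, Fz = 0, Mx = 0)[rep(1, length(load)), ]
      loads[[ch]] <- load
      fr <- loads_to_frequencies(loads, surrogate, noise, seed = NULL)
      cbind(as.data.frame(fr), load = load, channel = ch,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}
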