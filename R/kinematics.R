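## Crank and pedal angle estimation from the filtered IMU streams.
##
## The crank angle is recovered from the squared acceleration magnitude,
## which under constant-rate revolutions is
##   a^2 = r^2 phidot^4 + 2 g r phidot^2 cos(phi) + g^2,
## maximal at top dead centre (phi = 0) and minimal at bottom dead centre
## (phi = 180 deg). Detected extrema anchor a piecewise-linear phase, and
## cadence follows from the half-revolution intervals. The pedal angle is
## estimated roughly from the gravity direction in the accelerometer and
## refined by fusing the gyroscope pitch rate in a scalar Kalman filter.

#' Squared acceleration magnitude
#'
#' Per-sample squared Euclidean norm of the three-axis acceleration. The
#' norm is invariant to the sensor's orientation, so it can be computed in
#' the body frame directly.
#'
#' @param ax,ay,az acceleration components (m/s^2).
#' @return numeric vector of squared magnitudes (m^2/s^4).
#' @export
accel_sq_magnitude <- function(ax, ay, az) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  ax^2 + ay^2 + az^2
}

## Strict local extrema of a numeric vector; kind +1 max, -1 min.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), kind = integer()))
  left <- x[2:(n - 1)] - x[1:(n - 2)]
  right <- x[2:(n - 1)] - x[3:n]
  is_max <- left > 0 & right >= 0
  is_min <- left < 0 & right <= 0
  idx <- c(which(is_max) + 1L, which(is_min) + 1L)
  kind <- c(rep(1L, sum(is_max)), rep(-1L, sum(is_min)))
  o <- order(idx)
  data.frame(index = idx[o], kind = kind[o])
}

## Keep the more extreme of consecutive same-kind events.
enforce_alternation <- function(ev, x) {
  repeat {
    if (nrow(ev) < 2L) return(ev)
    same <- which(diff(ev$kind) == 0)
    if (length(same) == 0L) return(ev)
    i <- same[1L]
    a <- ev$index[i]; b <- ev$index[i + 1L]
    drop <- if (ev$kind[i] == 1L) {
      if (x[a] >= x[b]) i + 1L else i
    } else {
      if (x[a] <= x[b]) i + 1L else i
    }
    ev <- ev[-drop, , drop = FALSE]
  }
}

#' Detect crank dead-centre events
#'
#' Finds the alternating maxima (TDC) and minima (BDC) of the filtered
#' squared acceleration magnitude. Small wiggles are pruned adaptively:
#' consecutive extrema whose amplitude falls below `prominence_frac` times
#' the median event-to-event amplitude are removed, and events closer than
#' the half-revolution interval at `cadence_max_rpm` are merged keeping
#' the more extreme one. Strict TDC/BDC alternation is guaranteed in the
#' result.
#'
#' @param a2 filtered squared acceleration magnitude.
#' @param fs sampling rate (Hz).
#' @param cadence_max_rpm fastest plausible cadence; sets the minimum
#'   event spacing `60 / (2 * cadence_max_rpm)` seconds.
#' @param prominence_frac fraction of the median amplitude below which a
#'   wiggle is pruned.
#' @return data frame with `index` (into `a2`), `kind` (`"TDC"`/`"BDC"`)
#'   and `frac`, the sub-sample offset of the extremum (in samples, from a
#'   parabolic fit through the three surrounding points); zero rows (with
#'   a warning) when no extrema exist.
#' @export
detect_extrema <- function(a2, fs, cadence_max_rpm = 150,
                           prominence_frac = 0.5) {
  ev <- local_extrema(a2)
  empty <- data.frame(index = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    warning("no extrema found; stationary or too-short session")
    return(empty)
  }
  ev <- enforce_alternation(ev, a2)
  # adaptive prominence pruning
  if (nrow(ev) >= 2L) {
    repeat {
      amps <- abs(diff(a2[ev$index]))
      thr <- prominence_frac * median(amps)
      weak <- which(amps < thr)
      if (length(weak) == 0L) break
      i <- weak[which.min(amps[weak])]
      ev <- ev[-c(i, i + 1L), , drop = FALSE]  # drop the wiggle pair
      ev <- enforce_alternation(ev, a2)
      if (nrow(ev) < 2L) break
    }
  }
  # minimum spacing at the fastest plausible cadence
  min_sep <- max(1L, floor(fs * 60 / (2 * cadence_max_rpm)))
  repeat {
    if (nrow(ev) < 2L) break
    close <- which(diff(ev$index) < min_sep)
    if (length(close) == 0L) break
    i <- close[1L]
    a <- ev$index[i]; b <- ev$index[i + 1L]
    drop <- if (abs(a2[a]) >= abs(a2[b])) i + 1L else i
    ev <- ev[-drop, , drop = FALSE]
    ev <- enforce_alternation(ev, a2)
  }
  if (nrow(ev) == 0L) {
    warning("no extrema survived pruning; stationary session")
    return(empty)
  }
  # sub-sample refinement: parabola through the three samples around each
  # extremum; offset in samples, clamped to half a sample
  frac <- vapply(ev$index, function(i) {
    if (i <= 1L || i >= length(a2)) return(0)
    denom <- a2[i - 1L] - 2 * a2[i] + a2[i + 1L]
    if (denom == 0) return(0)
    max(-0.5, min(0.5, 0.5 * (a2[i - 1L] - a2[i + 1L]) / denom))
  }, numeric(1))
  data.frame(index = ev$index,
             kind = ifelse(ev$kind == 1L, "TDC", "BDC"),
             frac = frac,
             stringsAsFactors = FALSE)
}

#' Interpolate the crank angle between dead-centre events
#'
#' Anchors the crank phase at the detected events (TDC at 0 mod 360, BDC
#' at 180) and interpolates linearly in time between adjacent events,
#' consistent with the constant-rate-per-revolution model. Samples outside
#' the first and last event are marked invalid. Forward pedalling is
#' assumed: phase increases by 180 degrees per event.
#'
#' @param extrema data frame from [detect_extrema()] (alternating kinds).
#' @param t sample times (s), same indexing as the signal the extrema were
#'   detected on.
#' @return data frame of class `crank_trace` with `t`, `phi_deg`
#'   (wrapped), `phi_unwrapped_deg`, `valid`; attributes `extrema` and
#'   `revolutions` (completed half-event pairs / 2).
#' @export
interpolate_crank_angle <- function(extrema, t) {
  if (nrow(extrema) < 2L) {
    stop("need at least 2 alternating extrema to interpolate the crank angle",
         call. = FALSE)
  }
  if (any(extrema$kind[-1] == extrema$kind[-nrow(extrema)])) {
    stop("extrema must alternate TDC/BDC", call. = FALSE)
  }
  te <- t[extrema$index]
  if (!is.null(extrema$frac)) {
    # apply the sub-sample offsets using the local sampling interval
    n <- length(t)
    lo <- pmax(extrema$index - 1L, 1L)
    hi <- pmin(extrema$index + 1L, n)
    dt_local <- (t[hi] - t[lo]) / (hi - lo)
    te <- te + extrema$frac * dt_local
  }
  phi0 <- if (extrema$kind[1L] == "TDC") 0 else 180
  anchors <- phi0 + 180 * (seq_len(nrow(extrema)) - 1L)
  phi_unwrapped <- approx(te, anchors, xout = t, rule = 1)$y
  valid <- !is.na(phi_unwrapped)
  out <- data.frame(t = t,
                    phi_deg = ifelse(valid, wrap_deg(phi_unwrapped), NA_real_),
                    phi_unwrapped_deg = phi_unwrapped,
                    valid = valid)
  class(out) <- c("crank_trace", "data.frame")
  attr(out, "extrema") <- extrema
  attr(out, "anchor_t") <- te
  attr(out, "revolutions") <- floor((nrow(extrema) - 1L) / 2L)
  out
}

#' Cadence from a crank trace
#'
#' Each pair of adjacent dead-centre events spans half a revolution, so
#' the cadence over that interval is `30 / dt` rpm. The estimate is
#' piecewise constant per interval.
#'
#' @param trace a `crank_trace` from [interpolate_crank_angle()].
#' @return per-sample cadence (rpm), `NA` outside the valid region, with
#'   attribute `intervals` (data frame `t0`, `t1`, `rpm`).
#' @export
cadence_from_crank <- function(trace) {
  stopifnot(inherits(trace, "crank_trace"))
  te <- attr(trace, "anchor_t")
  dt <- diff(te)
  rpm <- 30 / dt
  intervals <- data.frame(t0 = te[-length(te)], t1 = te[-1], rpm = rpm)
  j <- findInterval(trace$t, te)
  out <- ifelse(j >= 1 & j < length(te), rpm[pmax(j, 1L)], NA_real_)
  out[trace$t == te[length(te)]] <- rpm[length(rpm)]
  attr(out, "intervals") <- intervals
  out
}

#' Left-right crank offset
#'
#' Mechanically the two cranks are mounted 180 degrees apart, so the
#' offset between the independently estimated left and right crank angles
#' is a built-in accuracy check. Because the two sides' clocks are not
#' synchronised, the right-side angle is linearly interpolated across the
#' bracketing right time stamps at every valid left sample, the circular
#' difference `phi_R - phi_L` is taken, and its circular mean and circular
#' standard deviation are returned in degrees.
#'
#' @param left,right `crank_trace` objects for the two sides.
#' @return named numeric vector `c(mean, sd)` in degrees, mean in
#'   \[0, 360).
#' @export
lr_offset <- function(left, right) {
  stopifnot(inherits(left, "crank_trace"), inherits(right, "crank_trace"))
  rv <- right[right$valid, , drop = FALSE]
  lv <- left[left$valid, , drop = FALSE]
  if (nrow(rv) < 2L || nrow(lv) < 1L) {
    stop("need valid samples on both sides", call. = FALSE)
  }
  keep <- lv$t >= min(rv$t) & lv$t <= max(rv$t)
  if (!any(keep)) {
    stop("left and right valid regions do not overlap in time",
         call. = FALSE)
  }
  lq <- lv[keep, , drop = FALSE]
  phi_r <- approx(rv$t, rv$phi_unwrapped_deg, xout = lq$t,
                  ties = "ordered")$y
  d <- wrap_deg(phi_r - lq$phi_deg)
  st <- circ_mean_sd_deg(d)
  c(mean = unname(st["mean"]), sd = unname(st["sd"]))
}

#' Rough pedal angle from the accelerometer
#'
#' Two-argument arctangent of the gravity direction sensed by the
#' accelerometer, `atan2(-ax, az)` in degrees. The sign of the x-argument
#' is chosen so that a stationary pedal tilted by `theta` (sensing
#' `(-g sin theta, g cos theta)` in its x/z axes) returns `+theta`. The
#' estimate is exact only for a stationary crank; during pedalling the
#' centripetal acceleration biases it, which is precisely the measurement
#' uncertainty the Kalman filter absorbs.
#'
#' @param ax,az filtered body-frame acceleration components (m/s^2).
#' @param eps squared-magnitude threshold below which a sample is marked
#'   invalid (`NA`).
#' @return angles in degrees in (-180, 180\]; `NA` where the in-plane
#'   magnitude vanishes.
#' @export
rough_pedal_angle <- function(ax, az, eps = 1e-12) {
  stopifnot(length(ax) == length(az))
  out <- rad2deg(atan2(-ax, az))
  out[ax^2 + az^2 < eps] <- NA_real_
  out
}

#' Kalman filter parameters
#'
#' Scalar process/measurement noise settings of the pedal-angle filter,
#' all in degrees. The process model integrates the gyroscope pitch rate
#' (`theta[k] = theta[k-1] + omega[k-1] * Ts + noise`), so the default
#' process variance is the angle increment variance implied by the gyro
#' noise, `(sigma_gyro * Ts * 180 / pi)^2`, times a tuning factor. The
#' measurement is the accelerometer-derived rough angle, whose default
#' variance of 100 deg^2 reflects that during pedalling its error is
#' dominated by the centripetal bias (tens of degrees at usual cadences),
#' not by sensor noise.
#'
#' @param Q process-noise variance (deg^2).
#' @param R measurement-noise variance (deg^2).
#' @param Ts sampling interval (s).
#' @param theta0 initial angle (deg); `NULL` uses the first valid
#'   measurement.
#' @param P0 initial variance (deg^2); `NULL` uses `R`.
#' @return list of class `kf_params`.
#' @export
kf_params <- function(Q, R = 100, Ts = 1 / 25, theta0 = NULL, P0 = NULL) {
  stopifnot(Q > 0, R >= 0, Ts > 0)
  if (is.null(P0)) P0 <- max(R, Q)
  stopifnot(P0 > 0)
  structure(list(Q = Q, R = R, Ts = Ts, theta0 = theta0, P0 = P0),
            class = "kf_params")
}

## Default Q from the configured gyro noise density.
default_kf_params <- function(fs, sigma_gyro = 0.02, q_scale = 1, R = 100) {
  Ts <- 1 / fs
  kf_params(Q = (rad2deg(sigma_gyro * Ts))^2 * q_scale, R = R, Ts = Ts)
}

#' Pedal angle by Kalman-filter fusion
#'
#' Scalar predict-update recursion fusing dead-reckoned gyroscope
#' integration with the accelerometer-derived rough angle:
#' predict `theta- = theta + omega * Ts`, `P- = P + Q`; update with
#' measurement `y = theta_rough` and variance `R`. The innovation is
#' wrapped to (-180, 180\] before the update, which removes the +-180
#' degree seam of the arctangent without letting a drifting measurement
#' unwind the state (at fast cadences, when the centripetal acceleration
#' exceeds g, the accelerometer angle sweeps full revolutions). The
#' returned angle is re-wrapped to (-180, 180\]. `NA` measurements
#' trigger a predict-only step.
#'
#' @param theta_rough rough pedal angle (deg), from [rough_pedal_angle()].
#' @param omega gyroscope pitch rate (rad/s), same length.
#' @param params a [kf_params()].
#' @return data frame of class `pedal_angle_trace` with `theta_rough_deg`,
#'   `theta_deg` (posterior), `theta_var` (posterior variance, deg^2).
#' @export
kalman_pedal_angle <- function(theta_rough, omega, params) {
  stopifnot(inherits(params, "kf_params"))
  if (length(theta_rough) != length(omega)) {
    stop("theta_rough and omega must have equal length", call. = FALSE)
  }
  n <- length(theta_rough)
  y <- theta_rough
  w <- rad2deg(omega)  # deg/s
  theta <- numeric(n)
  Pv <- numeric(n)
  first <- which(!is.na(y))[1L]
  if (is.na(first)) stop("no valid rough-angle measurement", call. = FALSE)
  th <- if (is.null(params$theta0)) y[first] else params$theta0
  P <- params$P0
  for (k in seq_len(n)) {
    if (k > 1L) {
      th <- th + w[k - 1L] * params$Ts
      P <- P + params$Q
    }
    if (!is.na(y[k])) {
      K <- P / (P + params$R)
      th <- th + K * wrap_pm180(y[k] - th)
      P <- (1 - K) * P
    }
    theta[k] <- th
    Pv[k] <- P
  }
  out <- data.frame(theta_rough_deg = theta_rough,
                    theta_deg = wrap_pm180(theta),
                    theta_var = Pv)
  class(out) <- c("pedal_angle_trace", "data.frame")
  out
}

#' Run the full estimation chain on a session
#'
#' Filters the streams, recovers the crank angle and cadence from the
#' acceleration magnitude, and estimates the pedal angle by Kalman-filter
#' fusion, independently for each side. When both sides are present the
#' left-right crank offset (nominally 180 degrees) is reported as a
#' consistency check.
#'
#' @param session a [pedal_session()].
#' @param config configuration list, see [default_config()].
#' @return list with `estimates` (data frame `time_s, side, phi_deg,
#'   phi_valid, cadence_rpm, theta_rough_deg, theta_deg, theta_var`),
#'   `traces` (per-side `crank_trace`) and `lr_offset_deg`
#'   (`c(mean, sd)` or `NULL` for single-sided sessions).
#' @export
#' @examples
#' sim <- make_session(duration = 20, seed = 2)
#' est <- estimate_session(sim$session)
#' est$lr_offset_deg
estimate_session <- function(session, config = default_config()) {
  stopifnot(inherits(session, "pedal_session"))
  fs <- session$meta$fs
  spec <- filter_spec(order = config$filter$order, fc = config$filter$fc_hz,
                      fs = fs)
  filtered <- filter_session(session, spec)
  sides <- intersect(c("L", "R"), unique(filtered$samples$side))
  traces <- list()
  parts <- list()
  for (sd in sides) {
    ss <- side_samples(filtered, sd)
    raw <- side_samples(session, sd)
    # the magnitude is formed from the raw components and filtered itself:
    # low-passing the components first distorts their squared sum, because
    # the squaring mixes harmonics that the filter attenuates unevenly
    a2 <- lowpass_zero_phase(
      accel_sq_magnitude(raw$ax, raw$ay, raw$az), spec)
    ex <- detect_extrema(a2, fs,
                         cadence_max_rpm = config$peaks$cadence_max_rpm,
                         prominence_frac = config$peaks$prominence_frac)
    trace <- interpolate_crank_angle(ex, ss$time_s)
    cad <- cadence_from_crank(trace)
    rough <- rough_pedal_angle(ss$ax, ss$az)
    kfp <- default_kf_params(fs, sigma_gyro = config$kf$sigma_gyro,
                             q_scale = config$kf$q_scale, R = config$kf$R)
    pat <- kalman_pedal_angle(rough, ss$gy, kfp)
    traces[[sd]] <- trace
    parts[[sd]] <- data.frame(
      time_s = ss$time_s, side = sd,
      phi_deg = trace$phi_deg, phi_valid = trace$valid,
      cadence_rpm = as.numeric(cad),
      theta_rough_deg = pat$theta_rough_deg,
      theta_deg = pat$theta_deg, theta_var = pat$theta_var,
      stringsAsFactors = FALSE
    )
  }
  est <- do.call(rbind, parts)
  rownames(est) <- NULL
  off <- if (all(c("L", "R") %in% names(traces))) {
    lr_offset(traces$L, traces$R)
  } else NULL
  list(estimates = est, traces = traces, lr_offset_deg = off)
}
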