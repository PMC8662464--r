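test_that("squared acceleration magnitude is frame invariant", {
  expect_equal(accel_sq_magnitude(0, 0, 9.81), 96.2361, tolerance = 1e-9)
  # closed form at bottom dead centre
  bdc <- manual_truth(c(0, 1), c(180, 180), c(2 * pi, 2 * pi), c(0, 0))
  imu <- simulate_imu(bdc, r = 0.17)
  expect_equal(accel_sq_magnitude(imu$ax, imu$ay, imu$az)[1],
               (9.81 - 0.17 * (2 * pi)^2)^2, tolerance = 1e-9)
  # invariance under arbitrary rotations
  withr::with_seed(8, {
    v <- matrix(rnorm(30), ncol = 3)
    for (i in 1:5) {
      ang <- runif(3, 0, 2 * pi)
      Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                  c(0, sin(ang[1]), cos(ang[1])))
      Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                  c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
      vr <- v %*% t(Rz %*% Rx)
      expect_equal(accel_sq_magnitude(vr[, 1], vr[, 2], vr[, 3]),
                   accel_sq_magnitude(v[, 1], v[, 2], v[, 3]),
                   tolerance = 1e-9)
    }
  })
})

test_that("extrema detection labels and alternates dead centres", {
  expect_warning(ex0 <- detect_extrema(rep(5, 100), 25), "no extrema")
  expect_equal(nrow(ex0), 0L)

  t <- seq(0, 1, by = 0.01)
  one <- cos(2 * pi * t)  # one period: one interior max is at the ends
  ex1 <- detect_extrema(-cos(2 * pi * t), 25)
  expect_equal(ex1$kind, c("TDC"))  # single interior maximum
  ex2 <- detect_extrema(sin(2 * pi * t), 25)
  expect_equal(ex2$kind, c("TDC", "BDC"))

  # 10 s at 60 rpm: ten revolutions, so 10 TDC and 10 BDC within +-1
  sim <- quiet_session(duration = 10, noise = sensor_noise_model(0, 0, 0),
                       seed = 2)
  ss <- sim$session$samples[sim$session$samples$side == "L", ]
  a2 <- lowpass_zero_phase(accel_sq_magnitude(ss$ax, ss$ay, ss$az),
                           filter_spec())
  ex <- detect_extrema(a2, 25)
  expect_lte(abs(sum(ex$kind == "TDC") - 10), 1)
  expect_lte(abs(sum(ex$kind == "BDC") - 10), 1)
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
  # detected events coincide with true dead centres within one sample
  phi_ev <- sim$truth$L$phi_deg[ex$index]
  target <- ifelse(ex$kind == "TDC", 0, 180)
  expect_lt(max(abs(((phi_ev - target + 180) %% 360) - 180)),
            360 * 60 / 60 / 25 + 1e-6)
})

test_that("crank angle interpolates linearly between anchors", {
  t <- seq(0, 1, by = 0.25)
  ex <- data.frame(index = c(1L, 5L), kind = c("TDC", "BDC"), frac = 0)
  tr <- interpolate_crank_angle(ex, t)
  expect_equal(tr$phi_deg[t == 0.5], 90)
  ex2 <- data.frame(index = c(1L, 5L), kind = c("BDC", "TDC"), frac = 0)
  tr2 <- interpolate_crank_angle(ex2, t)
  expect_equal(tr2$phi_deg[t == 0.5], 270)
  expect_true(all(tr$valid))

  expect_error(interpolate_crank_angle(ex[1, ], t), "at least 2")
  bad <- data.frame(index = c(1L, 3L), kind = c("TDC", "TDC"), frac = 0)
  expect_error(interpolate_crank_angle(bad, t), "alternate")

  # full-chain accuracy against simulator truth, noiseless
  sim <- quiet_session(duration = 60, noise = sensor_noise_model(0, 0, 0),
                       seed = 3)
  est <- estimate_session(sim$session)
  v <- est$traces$L$valid
  expect_lte(mae_circ_deg(est$traces$L$phi_deg[v],
                          sim$truth$L$phi_deg[v]), 5)
})

test_that("cadence derives from half-revolution intervals", {
  t <- seq(0, 2.5, by = 0.05)
  ex <- data.frame(index = c(1L, 11L, 21L, 41L),
                   kind = c("TDC", "BDC", "TDC", "BDC"), frac = 0)
  tr <- interpolate_crank_angle(ex, t)
  cad <- cadence_from_crank(tr)
  ints <- attr(cad, "intervals")
  expect_equal(ints$rpm, c(60, 60, 30))  # 0.5 s, 0.5 s, 1.0 s gaps
  expect_equal(cad[2], 60)
  expect_true(is.na(cad[length(cad)]))  # beyond the last event

  # slowly ramped cadence recovered interval by interval
  sim <- quiet_session(duration = 40, cadence_rpm = function(t) 50 + t / 4,
                       noise = sensor_noise_model(0, 0, 0), seed = 4)
  est <- estimate_session(sim$session)
  eL <- est$estimates[est$estimates$side == "L", ]
  ok <- !is.na(eL$cadence_rpm)
  truth_rpm <- 30 / pi * sim$truth$L$phidot_rad_s
  expect_lt(max(abs(eL$cadence_rpm[ok] - truth_rpm[ok])), 2)
})

test_that("left-right offset recovers the mechanical phase difference", {
  t <- seq(0, 10, by = 0.001)
  anchors <- function(offset_deg, tgrid) {
    # event times where phi = offset + 360 t crosses multiples of 180
    p <- 180 * (0:100)
    ev_t <- (p - offset_deg) / 360
    keep <- ev_t >= min(tgrid) & ev_t <= max(tgrid)
    data.frame(index = vapply(ev_t[keep],
                              function(x) which.min(abs(tgrid - x)),
                              integer(1)),
               kind = ifelse(p[keep] %% 360 == 0, "TDC", "BDC"),
               frac = 0)
  }
  left <- interpolate_crank_angle(anchors(0, t), t)
  tR <- t + 0.0003  # unsynchronised clocks
  right175 <- interpolate_crank_angle(anchors(175, tR), tR)
  off <- lr_offset(left, right175)
  expect_lt(abs(off["mean"] - 175), 1)

  same <- lr_offset(left, left)
  expect_equal(unname(same["mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(same["sd"]), 0, tolerance = 1e-9)

  # exact 180-degree construction through the full chain
  sim <- quiet_session(duration = 30, noise = sensor_noise_model(0, 0, 0),
                       seed = 5)
  est <- estimate_session(sim$session)
  expect_equal(unname(est$lr_offset_deg["mean"]), 180, tolerance = 0.5)

  shifted <- right175
  shifted$t <- shifted$t + 100
  attr(shifted, "anchor_t") <- attr(shifted, "anchor_t") + 100
  expect_error(lr_offset(left, shifted), "overlap")
})

test_that("rough pedal angle inverts the gravity direction", {
  expect_equal(rough_pedal_angle(0, 9.81), 0)
  # stationary pedal at 30 degrees
  still <- manual_truth(c(0, 1), c(0, 0), c(0, 0), c(30, 30))
  imu <- simulate_imu(still, r = 0.17)
  expect_equal(rough_pedal_angle(imu$ax, imu$az)[1], 30, tolerance = 1e-9)
  # moving crank at phi = 90: bias equals atan2(r * phidot^2, g)
  mov <- manual_truth(c(0, 1), c(90, 90), c(2 * pi, 2 * pi), c(0, 0))
  imu_m <- simulate_imu(mov, r = 0.17)
  expect_equal(rough_pedal_angle(imu_m$ax, imu_m$az)[1],
               atan2(0.17 * (2 * pi)^2, 9.81) * 180 / pi, tolerance = 1e-9)
  expect_true(is.na(rough_pedal_angle(0, 0)))
})

test_that("Kalman filter reaches the scalar steady state on constant input", {
  n <- 2000
  p <- kf_params(Q = 0.5, R = 10, Ts = 0.04, theta0 = 12, P0 = 10)
  out <- kalman_pedal_angle(rep(12, n), rep(0, n), p)
  expect_equal(out$theta_deg, rep(12, n), tolerance = 1e-9)
  # fixed point of the scalar Riccati recursion
  p_star <- (-p$Q + sqrt(p$Q^2 + 4 * p$Q * p$R)) / 2
  expect_equal(out$theta_var[n], p_star, tolerance = 1e-6)
  expect_true(all(out$theta_var > 0))
  # posterior never exceeds the prior variance
  prior <- c(p$P0, out$theta_var[-n] + p$Q)
  expect_true(all(out$theta_var <= prior + 1e-12))
})

test_that("Kalman limits: gyro-only integration and measurement tracking", {
  n <- 500
  Ts <- 0.04
  t <- (0:(n - 1)) * Ts
  theta_true <- 15 * sin(2 * pi * 0.4 * t)
  omega <- c(0, diff(theta_true)) / Ts * pi / 180  # rad/s, Euler-consistent
  # R -> infinity: dead reckoning from the exact initial angle (P0 small
  # so the filter trusts the state, not the disabled measurement)
  p_gyro <- kf_params(Q = 1e-4, R = 1e12, Ts = Ts, theta0 = theta_true[1],
                      P0 = 1e-4)
  out <- kalman_pedal_angle(rep(0, n), omega, p_gyro)
  euler <- theta_true[1] + cumsum(c(0, (omega * 180 / pi * Ts)[-n]))
  expect_equal(out$theta_deg, euler, tolerance = 1e-3)
  # R -> 0: posterior sticks to the measurement
  p_meas <- kf_params(Q = 1, R = 1e-12, Ts = Ts)
  withr::with_seed(9, y <- rnorm(n, 0, 5))
  track <- kalman_pedal_angle(y, rep(0, n), p_meas)
  expect_equal(track$theta_deg, y, tolerance = 1e-6)
  # Q -> 0 with zero rate: closed-form Bayesian running mean
  p0 <- kf_params(Q = 1e-15, R = 4, Ts = Ts, theta0 = 0, P0 = 8)
  run <- kalman_pedal_angle(y, rep(0, n), p0)
  k <- seq_len(n)
  closed <- (0 / p0$P0 + cumsum(y) / p0$R) / (1 / p0$P0 + k / p0$R)
  expect_equal(run$theta_deg, closed, tolerance = 1e-6)

  expect_error(kalman_pedal_angle(y, omega[-1], p_meas), "equal length")
})

test_that("fusion beats the accelerometer-only angle across conditions", {
  # 20 seeded runs over a grid of cadences and ankle amplitudes
  grid <- expand.grid(rpm = c(40, 65, 90), amp = c(5, 20, 30))
  wins <- logical(0)
  for (s in 1:20) {
    g <- grid[(s - 1) %% nrow(grid) + 1, ]
    sim <- quiet_session(duration = 30, cadence_rpm = g$rpm,
                         amplitude = g$amp, surrogate = NULL, seed = 100 + s)
    est <- estimate_session(sim$session)
    eL <- est$estimates[est$estimates$side == "L", ]
    truth <- sim$truth$L$theta_deg
    r_kf <- rmse_of(eL$theta_deg, truth)
    r_rough <- rmse_of(eL$theta_rough_deg, truth)
    expect_true(is.finite(r_kf))
    wins <- c(wins, r_kf < r_rough)
  }
  expect_gte(mean(wins), 0.95)
})
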