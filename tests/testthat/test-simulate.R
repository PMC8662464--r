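test_that("constant-cadence crank trajectory is exact", {
  tr <- simulate_crank_trajectory(2, 60, fs = 25)
  expect_equal(nrow(tr), 50L)
  # 60 rpm = 1 rev/s: two full revolutions over 2 s
  expect_equal(tr$phi_unwrapped_deg, 360 * tr$t, tolerance = 1e-10)
  expect_equal(tr$phidot_rad_s, rep(2 * pi, 50), tolerance = 1e-10)
  expect_true(all(tr$phi_deg >= 0 & tr$phi_deg < 360))
  expect_error(simulate_crank_trajectory(2, -10), "positive")
})

test_that("ramped cadence accumulates the time-integral of the profile", {
  prof <- function(t) 50 + 20 * t / 60
  tr <- simulate_crank_trajectory(60, prof, fs = 25)
  # independent quadrature oracle on a fine grid
  tf <- seq(0, max(tr$t), length.out = 200001)
  revs_oracle <- sum(diff(tf) * (prof(tf[-1]) + prof(tf[-length(tf)])) / 2) / 60
  # agreement within the phase advanced during one sample period
  tol <- 360 * max(prof(tr$t)) / 60 / 25
  expect_lt(abs(tr$phi_unwrapped_deg[nrow(tr)] - 360 * revs_oracle), tol)
  # rate is constant within each revolution: phidot changes at most once
  # per 180 degrees of phase
  expect_lte(sum(diff(tr$phidot_rad_s) != 0),
             ceiling(tr$phi_unwrapped_deg[nrow(tr)] / 360) + 1)
})

test_that("pedal-angle model respects range and phase", {
  tr <- simulate_crank_trajectory(5, 60)
  flat <- simulate_pedal_angle(tr, theta0 = -10, amplitude = 0)
  expect_true(all(flat$theta_deg == -10))

  tr90 <- manual_truth(0, 90, 2 * pi)
  expect_equal(simulate_pedal_angle(tr90, 0, 20, 0)$theta_deg, 20)

  # dense-grid brute force: extreme value equals theta0 +/- amplitude
  dense <- simulate_crank_trajectory(2, 60, fs = 1000)
  th <- simulate_pedal_angle(dense, theta0 = 10, amplitude = 25)$theta_deg
  expect_equal(max(abs(th)), 35, tolerance = 1e-4)

  expect_error(simulate_pedal_angle(tr, theta0 = 80, amplitude = 20), "90")
})

test_that("noiseless IMU matches the planar forward model", {
  # stationary crank: accelerometer senses pure gravity in the body frame
  still <- manual_truth(c(0, 0.04), c(0, 0), c(0, 0), c(0, 0))
  imu <- simulate_imu(still, r = 0.17)
  expect_equal(imu$ax, c(0, 0), tolerance = 1e-12)
  expect_equal(imu$az, c(9.81, 9.81), tolerance = 1e-12)

  tilt <- manual_truth(c(0, 0.04), c(0, 0), c(0, 0), c(30, 30))
  imu30 <- simulate_imu(tilt, r = 0.17)
  expect_equal(imu30$ax[1], -9.81 / 2, tolerance = 1e-12)
  expect_equal(imu30$az[1], 9.81 * cos(pi / 6), tolerance = 1e-12)

  # moving crank at TDC: squared magnitude equals (r*phidot^2 + g)^2
  tdc <- manual_truth(c(0, 0.04), c(0, 0), c(2 * pi, 2 * pi), c(0, 0))
  imu_t <- simulate_imu(tdc, r = 0.17)
  a2 <- accel_sq_magnitude(imu_t$ax, imu_t$ay, imu_t$az)
  expect_equal(a2[1], (0.17 * (2 * pi)^2 + 9.81)^2, tolerance = 1e-9)
  expect_equal(a2[1], a2_closed_form(0.17, 2 * pi, 0), tolerance = 1e-9)
})

test_that("squared magnitude follows the closed form at every sample", {
  tr <- simulate_crank_trajectory(30, 72, fs = 25)
  tr <- simulate_pedal_angle(tr, theta0 = 5, amplitude = 20)
  imu <- simulate_imu(tr, r = 0.17)
  a2 <- accel_sq_magnitude(imu$ax, imu$ay, imu$az)
  ref <- a2_closed_form(0.17, tr$phidot_rad_s, tr$phi_deg)
  expect_lt(max(abs(a2 - ref) / ref), 1e-9)
  # extrema of the magnitude signal sit at the dead centres
  expect_lt(min(abs(c(tr$phi_deg[which.max(a2)],
                      tr$phi_deg[which.max(a2)] - 360))), 8)
  expect_lt(abs(tr$phi_deg[which.min(a2)] - 180), 8)
})

test_that("load profiles are phase-locked, bounded and balanced", {
  tr <- simulate_crank_trajectory(10, 60)
  zero <- simulate_loads(tr, 0, 0, 0)
  expect_true(all(zero$Fx == 0 & zero$Fz == 0 & zero$Mx == 0))

  tr <- simulate_loads(tr, peak_Fx = 60, peak_Fz = 300, peak_Mx = 1)
  expect_gt(max(tr$Fz), 0)
  expect_lte(max(tr$Fz), 300)
  expect_true(all(tr$Fz >= CALIBRATION_RANGES$Fz[1] &
                    tr$Fz <= CALIBRATION_RANGES$Fz[2]))
  # peak occurs in the downstroke quadrant
  expect_lt(abs(tr$phi_deg[which.max(tr$Fz)] - 90), 10)

  expect_error(simulate_loads(tr, peak_Fz = 600), "range")

  # identical peaks on both sides: per-revolution impulse is equal
  sim <- quiet_session(duration = 20, noise = sensor_noise_model(0, 0, 0),
                       seed = 1)
  revL <- sim$truth$L[sim$truth$L$t < 10, ]
  revR <- sim$truth$R[sim$truth$R$t < 10, ]
  intL <- sum(diff(revL$t) * (revL$Fz[-1] + revL$Fz[-nrow(revL)]) / 2)
  intR <- sum(diff(revR$t) * (revR$Fz[-1] + revR$Fz[-nrow(revR)]) / 2)
  expect_equal(intL, intR, tolerance = 5e-3)  # quadrature at 25 Hz
})

test_that("load-to-frequency surrogate obeys the coil sign structure", {
  sg <- load_sensor_surrogate()
  zero <- loads_to_frequencies(data.frame(Fx = 0, Fz = 0, Mx = 0), sg)
  expect_equal(drop(zero), sg$baseline, ignore_attr = TRUE)

  fz <- loads_to_frequencies(data.frame(Fx = 0, Fz = 100, Mx = 0), sg)
  shifts <- unname(drop(fz) - sg$baseline)
  expect_equal(shifts[1], shifts[2], tolerance = 1e-12)
  expect_equal(shifts[2], shifts[3], tolerance = 1e-12)

  mx <- loads_to_frequencies(data.frame(Fx = 0, Fz = 0, Mx = 2), sg)
  mshift <- unname(drop(mx) - sg$baseline)
  expect_equal(mshift[1], 0, tolerance = 1e-12)
  expect_equal(mshift[2], -mshift[3], tolerance = 1e-12)

  # exact affinity: superposition to machine precision
  l1 <- data.frame(Fx = 13, Fz = -40, Mx = 0.7)
  l2 <- data.frame(Fx = -5, Fz = 120, Mx = -1.1)
  l12 <- l1 + l2
  f <- function(l) unname(drop(loads_to_frequencies(l, sg)))
  expect_equal(f(l1) + f(l2) - sg$baseline, f(l12), tolerance = 1e-12)

  # a matrix breaking the sign pattern is rejected
  bad <- rbind(c(1, -2, 0), c(1, -2, 15), c(-1, -2, -15), c(1, -2, 0))
  expect_error(load_sensor_surrogate(sensitivity = bad), "sign pattern")
})

test_that("make_session builds a consistent two-sided recording", {
  sim <- quiet_session(duration = 60, seed = 42)
  expect_equal(sum(sim$session$samples$side == "L"), 1500L)
  expect_equal(sum(sim$session$samples$side == "R"), 1500L)
  # exact 180-degree mechanical offset in the ground truth
  d <- (sim$truth$R$phi_deg - sim$truth$L$phi_deg) %% 360
  expect_equal(d, rep(180, 1500), tolerance = 1e-9)
  rep <- validate_session(sim$session)
  expect_false(any(rep$flag_rate | rep$flag_gap))

  # determinism: identical seed, identical session
  again <- quiet_session(duration = 60, seed = 42)
  expect_identical(sim$session, again$session)
  other <- quiet_session(duration = 60, seed = 43)
  expect_false(identical(sim$session$samples$ax, other$session$samples$ax))
})
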