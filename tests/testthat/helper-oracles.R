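# Shared oracles and small builders used across the suite.

rmse_of <- function(a, b) sqrt(mean((a - b)^2))

# mean absolute circular difference in degrees
mae_circ_deg <- function(a, b) mean(abs(((a - b + 180) %% 360) - 180))

# closed-form squared acceleration magnitude under constant-rate
# revolutions (independent derivation from the planar kinematics)
a2_closed_form <- function(r, phidot, phi_deg, g = 9.81) {
  r^2 * phidot^4 + 2 * g * r * phidot^2 * cos(phi_deg * pi / 180) + g^2
}

# analytic two-pass (squared) Butterworth low-pass magnitude response
butter2_sq_gain <- function(f, fc, order = 2) {
  1 / (1 + (f / fc)^(2 * order))
}

# hand-rolled truth container for direct forward-model evaluation
manual_truth <- function(t, phi_deg, phidot_rad_s, theta_deg = NULL) {
  tr <- data.frame(t = t, phi_deg = phi_deg,
                   phi_unwrapped_deg = phi_deg,
                   phidot_rad_s = phidot_rad_s)
  if (!is.null(theta_deg)) tr$theta_deg <- theta_deg
  class(tr) <- c("trajectory_truth", "data.frame")
  tr
}

# least-squares amplitude/phase of a sinusoid at frequency f in x[t]
fit_sinusoid <- function(x, t, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  co <- qr.solve(X, x)
  list(amplitude = sqrt(sum(co^2)), phase_deg = atan2(co[2], co[1]) * 180 / pi)
}

quiet_session <- function(...) {
  suppressWarnings(make_session(...))
}
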