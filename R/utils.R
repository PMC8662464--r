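## Angle helpers. All user-facing angles are degrees; radians appear only
## inside trigonometric kernels.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to \[0, 360) degrees
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to \[0, 360).
#' @keywords internal
wrap_deg <- function(x) x %% 360

## Wrap to (-180, 180].
wrap_pm180 <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

## Unwrap a degree series: remove jumps larger than 180 deg between
## consecutive samples so the series becomes continuous.
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  adj <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
  x + adj
}

## Circular mean (deg, in [0,360)) and circular standard deviation (deg,
## RMS angular deviation about the circular mean, population convention).
circ_mean_sd_deg <- function(x) {
  r <- deg2rad(x)
  mu <- rad2deg(atan2(mean(sin(r)), mean(cos(r)))) %% 360
  dev <- wrap_pm180(x - mu)
  c(mean = mu, sd = sqrt(mean(dev^2)))
}

## Cumulative trapezoidal integral of y over (possibly irregular) grid t.
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
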