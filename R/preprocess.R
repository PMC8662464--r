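## Zero-phase low-pass filtering. All analysis-relevant streams pass
## through a low-order Butterworth filter applied forward and backward,
## which squares the magnitude response and cancels the phase response.
## Edge transients are controlled by odd-reflection padding plus
## steady-state initial conditions, the conventional filtfilt scheme.

#' Low-pass filter specification
#'
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 2; the effective two-pass response is of order `2 * order`).
#' @param fc cutoff frequency in Hz (default 2.2, well above the pedalling
#'   fundamental at usual cadences yet far below the 12.5 Hz Nyquist of
#'   the 25 Hz streams).
#' @param fs sampling rate in Hz.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 2, fc = 2.2, fs = 25) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(fc, "fc", positive = TRUE)
  if (fc >= fs / 2) {
    stop(sprintf("cutoff fc = %g Hz must be below the Nyquist rate %g Hz",
                 fc, fs / 2), call. = FALSE)
  }
  if (order < 1 || order != round(order)) {
    stop("order must be a positive integer", call. = FALSE)
  }
  structure(list(order = as.integer(order), fc = fc, fs = fs),
            class = "filter_spec")
}

## Steady-state initial state of the direct-form-II-transposed filter for
## a unit-step input, so that filtering a constant leaves it unchanged
## from the very first sample.
lfilter_zi <- function(b, a) {
  n <- length(a)
  # companion matrix of the monic polynomial a
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1] / a[1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

## Direct-form-II-transposed linear filter with initial state zi.
df2t_filter <- function(b, a, x, zi) {
  nz <- length(b) - 1L
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1L) {
      z[1:(nz - 1L)] <- b[2:nz] * xi + z[2:nz] - a[2:nz] * yi
    }
    z[nz] <- b[nz + 1L] * xi - a[nz + 1L] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a uniformly sampled signal forward and backward with a
#' Butterworth low-pass filter, giving zero net phase shift and the
#' squared Butterworth magnitude response. Edges are handled by
#' odd-reflection padding of length `3 * (order + 1)` with steady-state
#' initial conditions on each pass.
#'
#' Non-uniform time stamps are ignored at this stage: the filter operates
#' on sample index at the nominal rate ([validate_session()] flags
#' sessions where that assumption is poor).
#'
#' @param x numeric signal, uniformly sampled at `spec$fs`.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 25)
#' x <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 10 * t)
#' y <- lowpass_zero_phase(x, filter_spec())
lowpass_zero_phase <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x))
  pad <- 3L * (spec$order + 1L)
  if (length(x) <= pad) {
    stop(sprintf("signal too short for zero-phase filtering: need > %d samples",
                 pad), call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$fc / (spec$fs / 2), type = "low")
  b <- bt$b
  a <- bt$a
  zi <- lfilter_zi(b, a)
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - pad)])
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

## Filter the analysis-relevant streams of a session in place:
## accelerometer and gyroscope always, frequency channels when present.
filter_session <- function(session, spec = filter_spec(fs = session$meta$fs)) {
  stopifnot(inherits(session, "pedal_session"))
  streams <- c("ax", "ay", "az", "gx", "gy", "gz", FREQ_COLUMNS)
  for (sd in unique(session$samples$side)) {
    idx <- session$samples$side == sd
    for (cc in streams) {
      v <- session$samples[[cc]][idx]
      if (all(is.finite(v))) {
        session$samples[[cc]][idx] <- lowpass_zero_phase(v, spec)
      }
    }
  }
  session
}
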