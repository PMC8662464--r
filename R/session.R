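## The Session container: one flat per-sample table covering both pedals,
## plus the session metadata needed by the kinematic model.

SESSION_COLUMNS <- c("time_s", "side", "ax", "ay", "az", "gx", "gy", "gz",
                     "f0", "f1", "f2", "f3")
FREQ_COLUMNS <- c("f0", "f1", "f2", "f3")

#' Construct a pedalling session
#'
#' A session bundles the per-sample sensor table of one recording (both
#' pedals) with the metadata required by the kinematic model: the nominal
#' sampling rate `fs`, the crank-arm length `r` (crank-axle centre to
#' pedal-axle centre) and the gravitational acceleration `g`.
#'
#' The sample table holds one row per time stamp and side with columns
#' `time_s` (absolute seconds), `side` (`"L"` or `"R"`), body-frame
#' acceleration `ax`, `ay`, `az` (m/s^2), body-frame angular rate `gx`,
#' `gy`, `gz` (rad/s; `gy` is the pedal's pitch rate, the time derivative
#' of the pedal angle) and the four LC-tank resonance frequencies
#' `f0`..`f3` (Hz, `NA` for IMU-only sessions). The two sides are not
#' assumed to share time stamps: each side is an independent stream.
#'
#' @param samples data frame with columns `time_s`, `side`, `ax`, `ay`,
#'   `az`, `gx`, `gy`, `gz` and optionally `f0`..`f3`. Rows may arrive in
#'   any order; they are sorted by side and time.
#' @param fs nominal sampling rate in Hz (default 25, the device rate).
#' @param r crank-arm length in metres.
#' @param g gravitational acceleration in m/s^2.
#' @return an object of class `pedal_session` with elements `samples`
#'   (the normalised table) and `meta` (list with `fs`, `r`, `g`).
#' @export
#' @examples
#' s <- pedal_session(data.frame(
#'   time_s = c(0, 0.04), side = "L",
#'   ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0
#' ))
#' validate_session(s)
pedal_session <- function(samples, fs = 25, r = 0.17, g = 9.81) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(r, "r", positive = TRUE)
  stopifnot_scalar(g, "g", positive = TRUE)
  samples <- as.data.frame(samples)
  required <- setdiff(SESSION_COLUMNS, FREQ_COLUMNS)
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    stop("session table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (fc in FREQ_COLUMNS) {
    if (!fc %in% names(samples)) samples[[fc]] <- rep(NA_real_, nrow(samples))
  }
  samples <- samples[, SESSION_COLUMNS, drop = FALSE]
  samples$side <- as.character(samples$side)
  bad_side <- !samples$side %in% c("L", "R")
  if (any(bad_side)) {
    stop("side must be 'L' or 'R'; first offending row: ",
         which(bad_side)[1L], call. = FALSE)
  }
  num_cols <- setdiff(SESSION_COLUMNS, "side")
  for (nc in num_cols) samples[[nc]] <- as.numeric(samples[[nc]])
  if (nrow(samples) > 0L && any(!is.finite(samples$time_s))) {
    stop("time_s must be finite", call. = FALSE)
  }
  fr <- as.matrix(samples[, FREQ_COLUMNS])
  if (any(fr[!is.na(fr)] <= 0)) {
    stop("resonance frequencies must be strictly positive where present",
         call. = FALSE)
  }
  samples <- samples[order(match(samples$side, c("L", "R")), samples$time_s), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(samples = samples, meta = list(fs = fs, r = r, g = g)),
    class = "pedal_session"
  )
}

#' @export
print.pedal_session <- function(x, ...) {
  n <- table(factor(x$samples$side, levels = c("L", "R")))
  cat(sprintf(
    "<pedal_session> %d samples (L: %d, R: %d), fs = %g Hz, r = %g m, g = %g m/s^2\n",
    nrow(x$samples), n[["L"]], n[["R"]], x$meta$fs, x$meta$r, x$meta$g
  ))
  invisible(x)
}

side_samples <- function(session, side) {
  session$samples[session$samples$side == side, , drop = FALSE]
}

#' Diagnostic report for a session
#'
#' Report-only checks of stream quality: per-side sampling-interval
#' statistics, the largest gap, NaN counts and duration. A side is flagged
#' when its mean sampling interval deviates by more than 10% from the
#' nominal `1/fs`, or when the largest gap exceeds three nominal intervals.
#' The input is never modified and no error is ever raised.
#'
#' @param session a [pedal_session()].
#' @return data frame with one row per side present: `side`, `n`,
#'   `duration_s`, `mean_interval_s`, `max_gap_s`, `n_nan`,
#'   `flag_rate` (mean interval off-nominal), `flag_gap` (large gap).
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "pedal_session"))
  fs <- session$meta$fs
  nominal <- 1 / fs
  sides <- intersect(c("L", "R"), unique(session$samples$side))
  rows <- lapply(sides, function(sd) {
    ss <- side_samples(session, sd)
    dt <- diff(ss$time_s)
    num <- as.matrix(ss[, setdiff(SESSION_COLUMNS, c("side", FREQ_COLUMNS))])
    mean_dt <- if (length(dt) > 0L) mean(dt) else NA_real_
    max_gap <- if (length(dt) > 0L) max(dt) else NA_real_
    data.frame(
      side = sd,
      n = nrow(ss),
      duration_s = if (nrow(ss) > 0L) diff(range(ss$time_s)) else 0,
      mean_interval_s = mean_dt,
      max_gap_s = max_gap,
      n_nan = sum(is.nan(num)),
      flag_rate = isTRUE(abs(mean_dt - nominal) > 0.1 * nominal),
      flag_gap = isTRUE(max_gap > 3 * nominal),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(side = character(), n = integer(),
                      duration_s = numeric(), mean_interval_s = numeric(),
                      max_gap_s = numeric(), n_nan = integer(),
                      flag_rate = logical(), flag_gap = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
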