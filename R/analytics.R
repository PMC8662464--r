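## Post-session analytics and game-control signals. Force "magnitude" is
## the in-plane norm sqrt(Fx^2 + Fz^2): the lateral component is not
## sensed by the pedal.

binned_stats <- function(values, bin_id, edges, labels) {
  n_bins <- length(edges) - 1L
  count <- tabulate(bin_id, nbins = n_bins)
  mean_v <- rep(NA_real_, n_bins)
  sd_v <- rep(NA_real_, n_bins)
  for (b in which(count > 0L)) {
    v <- values[bin_id == b]
    mean_v[b] <- mean(v)
    sd_v[b] <- sqrt(mean((v - mean(v))^2))  # population, as in error_stats
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             mid = labels, mean = mean_v, sd = sd_v, count = count)
}

#' Binned force magnitude over time
#'
#' Per-sample in-plane force magnitude `sqrt(Fx^2 + Fz^2)` averaged over
#' fixed-width time bins (default 1 s), with the per-bin population
#' standard deviation — the session bar-plot summary. Empty bins carry
#' `NA` statistics and count 0.
#'
#' @param Fx,Fz force components (N).
#' @param t sample times (s), aligned with the forces.
#' @param bin_width bin width (s), > 0.
#' @return data frame `bin_lo, bin_hi, mid, mean, sd, count`.
#' @export
binned_force_magnitude <- function(Fx, Fz, t, bin_width = 1.0) {
  stopifnot(length(Fx) == length(Fz), length(Fz) == length(t))
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  mag <- sqrt(Fx^2 + Fz^2)
  t0 <- floor(min(t) / bin_width) * bin_width
  edges <- seq(t0, max(t) + bin_width, by = bin_width)
  bin_id <- findInterval(t, edges, rightmost.closed = TRUE)
  binned_stats(mag, bin_id, edges, (edges[-length(edges)] + edges[-1L]) / 2)
}

#' Force magnitude by crank angle
#'
#' Assigns every sample with a valid crank angle to one of `n_bins` equal
#' angular bins over \[0, 360) and reports the per-bin mean and population
#' standard deviation of the in-plane force magnitude — the crank-phase
#' force profile of a session. Samples outside the valid crank region are
#' excluded.
#'
#' @param Fx,Fz force components (N), aligned with the trace samples.
#' @param trace a `crank_trace` from [interpolate_crank_angle()].
#' @param n_bins number of angular bins (default 36, i.e. 10-degree bins).
#' @return data frame `bin_lo, bin_hi, mid, mean, sd, count` (angles in
#'   degrees).
#' @export
force_by_crank_angle <- function(Fx, Fz, trace, n_bins = 36) {
  stopifnot(inherits(trace, "crank_trace"),
            length(Fx) == nrow(trace), length(Fz) == nrow(trace))
  keep <- trace$valid
  if (!any(keep)) {
    stop("no samples with a valid crank angle", call. = FALSE)
  }
  mag <- sqrt(Fx[keep]^2 + Fz[keep]^2)
  phi <- trace$phi_deg[keep]
  edges <- seq(0, 360, length.out = n_bins + 1L)
  bin_id <- pmin(floor(phi / (360 / n_bins)) + 1L, n_bins)
  binned_stats(mag, bin_id, edges, (edges[-length(edges)] + edges[-1L]) / 2)
}

#' Per-side session breakdown
#'
#' Summaries (mean, population sd, min, max, n) of cadence, pedal angle,
#' normal force, shear force and in-plane force magnitude, per side, over
#' the whole session or a sub-interval.
#'
#' @param estimates estimates table from [estimate_session()].
#' @param loads optional data frame `time_s, side, Fx, Fz` (predicted or
#'   simulated loads); when `NULL` only kinematic metrics are summarised.
#' @param interval optional `c(t0, t1)` restricting the summary (s).
#' @return data frame `side, metric, mean, sd, min, max, n`; metrics with
#'   no samples in the interval appear with `n = 0` and `NA` statistics.
#' @export
per_side_breakdown <- function(estimates, loads = NULL, interval = NULL) {
  stopifnot(all(c("time_s", "side") %in% names(estimates)))
  clip <- function(df) {
    if (is.null(interval)) return(df)
    df[df$time_s >= interval[1] & df$time_s <= interval[2], , drop = FALSE]
  }
  estimates <- clip(estimates)
  if (!is.null(loads)) loads <- clip(loads)
  summarise <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
               max = NA_real_, n = 0))
    }
    c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
      min = min(v), max = max(v), n = length(v))
  }
  rows <- list()
  for (sd_ in c("L", "R")) {
    es <- estimates[estimates$side == sd_, , drop = FALSE]
    metrics <- list(cadence_rpm = es$cadence_rpm,
                    pedal_angle_deg = es$theta_deg)
    if (!is.null(loads)) {
      ls <- loads[loads$side == sd_, , drop = FALSE]
      metrics$normal_force_N <- ls$Fz
      metrics$shear_force_N <- ls$Fx
      metrics$force_magnitude_N <- sqrt(ls$Fx^2 + ls$Fz^2)
    }
    for (m in names(metrics)) {
      st <- summarise(metrics[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        side = sd_, metric = m, mean = st["mean"], sd = st["sd"],
        min = st["min"], max = st["max"], n = st["n"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Game-control signals
#'
#' Maps cycling parameters to the two control channels of the interactive
#' trainer: cadence drives speed (`speed = gain_speed * cadence`) and the
#' left/right force balance drives yaw,
#' `yaw = (L - R) / (L + R)` clipped to \[-1, 1\] — positive when the left
#' pedal carries more force, steering toward the left. Zero total force
#' gives zero yaw.
#'
#' @param cadence_rpm cadence (rpm, >= 0).
#' @param left_force,right_force per-side force magnitudes (N, >= 0),
#'   typically sliding 1 s window means.
#' @param gain_speed speed gain per rpm.
#' @return list of class `game_control` with `speed` and `yaw`.
#' @export
#' @examples
#' game_controls(60, left_force = 100, right_force = 50)
game_controls <- function(cadence_rpm, left_force, right_force,
                          gain_speed = 1) {
  if (any(c(cadence_rpm, left_force, right_force) < 0)) {
    stop("cadence and force magnitudes must be non-negative", call. = FALSE)
  }
  total <- left_force + right_force
  yaw <- ifelse(total > 0, (left_force - right_force) / total, 0)
  structure(list(speed = gain_speed * cadence_rpm,
                 yaw = pmin(1, pmax(-1, yaw))),
            class = "game_control")
}
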