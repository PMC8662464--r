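## On-disk formats. One flat CSV per session with the metadata in leading
## `# key=value` comment lines; calibration records as a plain CSV. Numeric
## fields are written with 9 significant digits, which exceeds the sensor
## resolution and keeps write -> read -> write byte-identical.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.9g", x))
  out
}

#' Write a session to CSV
#'
#' Writes the metadata as `# key=value` comment lines followed by one flat
#' CSV table (`time_s,side,ax,ay,az,gx,gy,gz,f0,f1,f2,f3`). Missing
#' frequency channels become empty fields. Numbers carry 9 significant
#' digits so that a read-back session is numerically identical and a second
#' write is byte-identical.
#'
#' @param session a [pedal_session()].
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "pedal_session"))
  s <- session$samples
  lines <- c(
    sprintf("# fs=%s", fmt_num(session$meta$fs)),
    sprintf("# r=%s", fmt_num(session$meta$r)),
    sprintf("# g=%s", fmt_num(session$meta$g)),
    paste(SESSION_COLUMNS, collapse = ",")
  )
  if (nrow(s) > 0L) {
    cols <- lapply(SESSION_COLUMNS, function(cn) {
      if (cn == "side") s[[cn]] else fmt_num(s[[cn]])
    })
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a session from CSV
#'
#' Reads the format written by [write_session()]. Metadata (`fs`, `r`, `g`)
#' is taken from the leading `# key=value` comment lines; absent keys fall
#' back to the [pedal_session()] defaults. Per-side time stamps must be
#' non-decreasing in file order.
#'
#' @param path session CSV path.
#' @return a [pedal_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- as.numeric(m[3L])
  }
  body <- lines[!is_meta]
  if (length(body) == 0L) stop("session file has no header row", call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  missing <- setdiff(SESSION_COLUMNS, header)
  if (length(missing) > 0L) {
    stop("session file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- read.csv(text = body, stringsAsFactors = FALSE,
                 colClasses = setNames(
                   ifelse(header == "side", "character", "numeric"), header))
  n_meta <- sum(is_meta)
  for (sd in unique(df$side)) {
    ts <- df$time_s[df$side == sd]
    bad <- which(diff(ts) < 0)
    if (length(bad) > 0L) {
      row <- which(df$side == sd)[bad[1L] + 1L] + n_meta + 1L  # file line
      stop(sprintf("non-monotone time stamps on side %s: file row %d", sd, row),
           call. = FALSE)
    }
  }
  pedal_session(df,
                fs = meta$fs %||% 25,
                r = meta$r %||% 0.17,
                g = meta$g %||% 9.81)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write calibration records
#'
#' Calibration records pair a four-channel resonance-frequency readout with
#' a simultaneously logged reference load. The CSV columns are
#' `f0,f1,f2,f3,load,channel` with `channel` one of `Fx`, `Fz` (N) or
#' `Mx` (Nm).
#'
#' @param path CSV path.
#' @return `read_calibration_records`: data frame with the columns above.
#' @export
read_calibration_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(FREQ_COLUMNS, "load", "channel")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("calibration file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !df$channel %in% LOAD_CHANNELS
  if (any(bad)) {
    stop("unknown calibration channel: ", df$channel[which(bad)[1L]],
         call. = FALSE)
  }
  df[, need, drop = FALSE]
}

#' @rdname read_calibration_records
#' @param records data frame of calibration records.
#' @export
write_calibration_records <- function(records, path) {
  need <- c(FREQ_COLUMNS, "load", "channel")
  stopifnot(all(need %in% names(records)))
  lines <- paste(need, collapse = ",")
  if (nrow(records) > 0L) {
    lines <- c(lines, paste(
      fmt_num(records$f0), fmt_num(records$f1), fmt_num(records$f2),
      fmt_num(records$f3), fmt_num(records$load), records$channel,
      sep = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Default run configuration
#'
#' The configuration bundles every tunable of the processing chain:
#' sampling rate, crank geometry, low-pass filter, peak detection, Kalman
#' filter noise covariances and seeds. [read_config()] merges a YAML file
#' over these defaults (one level deep), so a config file only needs the
#' keys it overrides.
#'
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    fs = 25,              # Hz, nominal device rate
    r = 0.17,             # m, crank-arm length
    g = 9.81,             # m/s^2
    filter = list(order = 2, fc_hz = 2.2),
    peaks = list(cadence_max_rpm = 150, prominence_frac = 0.5),
    kf = list(R = 100, q_scale = 1, sigma_gyro = 0.02),
    seed = 1L
  )
}

#' @rdname default_config
#' @param path YAML config path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}
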