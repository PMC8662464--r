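## Frequency -> load calibration. Each load channel (Fx, Fz, Mx) gets its
## own L1-regularised linear map from the four coil resonance frequencies,
## with the regularisation strength chosen by K-fold cross-validation on a
## held-out training portion and the reported accuracy measured on the
## untouched test split.

#' Error statistics of an estimate against a reference
#'
#' For the estimation error `e = x - xhat`: mean error `mu`, error
#' standard deviation `sigma` (population convention, divide by n), mean
#' absolute error `mae`, root-mean-square error `rmse` and coefficient of
#' determination `r2 = 1 - sum(e^2) / sum((x - mean(x))^2)`. With the
#' population convention the identity `rmse^2 = mu^2 + sigma^2` holds
#' exactly. A constant reference leaves `r2` undefined (`NA`).
#'
#' @param reference reference values `x`.
#' @param estimate estimated values `xhat`, same length (>= 2).
#' @return list of class `error_stats` with `mu`, `sigma`, `mae`, `rmse`,
#'   `r2`, `n`.
#' @export
#' @examples
#' error_stats(c(1, 2, 3), c(1, 3, 2))
error_stats <- function(reference, estimate) {
  if (length(reference) != length(estimate) || length(reference) < 2L) {
    stop("reference and estimate must have equal length >= 2", call. = FALSE)
  }
  e <- reference - estimate
  mu <- mean(e)
  sigma <- sqrt(mean((e - mu)^2))
  ss_tot <- sum((reference - mean(reference))^2)
  r2 <- if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_
  structure(list(mu = mu, sigma = sigma, mae = mean(abs(e)),
                 rmse = sqrt(mean(e^2)), r2 = r2, n = length(e)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf(
    "<error_stats> n=%d  mu=%.4g  sigma=%.4g  MAE=%.4g  RMSE=%.4g  R2=%s\n",
    x$n, x$mu, x$sigma, x$mae, x$rmse,
    if (is.na(x$r2)) "NA" else sprintf("%.4g", x$r2)))
  invisible(x)
}

#' Default regularisation grid
#'
#' 25 log-spaced regularisation strengths from 1e-10 to 1e2, the grid
#' searched during calibration.
#' @return decreasing numeric vector of length 25.
#' @export
default_alpha_grid <- function() {
  sort(10^seq(-10, 2, length.out = 25), decreasing = TRUE)
}

#' Fit the frequency-to-load calibration
#'
#' Per channel: the records are split into a training portion and a
#' `test_fraction` holdout (seeded); an L1-regularised (LASSO) linear
#' model from the four frequencies to the load is fitted on the training
#' portion with the regularisation strength `alpha` chosen by `folds`-fold
#' cross-validation over `alpha_grid` (minimum mean CV squared error, ties
#' broken toward the larger, sparser `alpha`); accuracy is then measured
#' once on the untouched test split. Features are standardised internally;
#' coefficients are reported in raw units (Hz scale).
#'
#' @param records calibration records: data frame with `f0..f3`, `load`,
#'   `channel` (see [read_calibration_records()]).
#' @param folds number of cross-validation folds.
#' @param test_fraction fraction of records held out for testing.
#' @param alpha_grid regularisation grid, default [default_alpha_grid()].
#' @param seed integer seed controlling the split and fold assignment.
#' @return list of class `calibration_model`: per-channel `channels`
#'   (each with `weights`, `intercept`, the chosen `alpha`, the CV error
#'   curve `cv_mse` and the regularisation path summaries `path_alpha`,
#'   `path_l1`), `stats`
#'   (per-channel test-set [error_stats()]), and `meta` (folds,
#'   test fraction, grid, seed, error convention). Channels absent from
#'   `records` are skipped and listed in `meta$missing_channels`.
#' @export
fit_calibration <- function(records, folds = 10, test_fraction = 0.3,
                            alpha_grid = default_alpha_grid(), seed = 1L) {
  stopifnot(all(c(FREQ_COLUMNS, "load", "channel") %in% names(records)))
  alpha_grid <- sort(alpha_grid, decreasing = TRUE)
  present <- intersect(LOAD_CHANNELS, unique(records$channel))
  missing_ch <- setdiff(LOAD_CHANNELS, present)
  if (length(missing_ch) > 0L) {
    warning("no records for channel(s): ", paste(missing_ch, collapse = ", "),
            "; fitting the rest")
  }
  channels <- list()
  stats <- list()
  withr::with_seed(seed, {
    for (ch in present) {
      rec <- records[records$channel == ch, , drop = FALSE]
      n <- nrow(rec)
      need <- max(2L * folds, 20L)
      if (n < need) {
        stop(sprintf("channel %s has %d records; need >= %d", ch, n, need),
             call. = FALSE)
      }
      X <- as.matrix(rec[, FREQ_COLUMNS])
      if (any(apply(X, 2, function(v) diff(range(v)) == 0))) {
        warning(sprintf("channel %s: constant frequency column retained", ch))
      }
      y <- rec$load
      n_test <- max(1L, round(test_fraction * n))
      test_idx <- sample.int(n, n_test)
      Xtr <- X[-test_idx, , drop = FALSE]
      ytr <- y[-test_idx]
      # explicit standardisation: the penalty grid is defined on
      # unit-variance features, which keeps it meaningful across the
      # Hz-scale channels; a constant column stays in with zero weight
      mu_x <- colMeans(Xtr)
      sd_x <- apply(Xtr, 2, function(v) sqrt(mean((v - mean(v))^2)))
      sd_x[sd_x == 0] <- 1
      Xs <- sweep(sweep(Xtr, 2, mu_x, "-"), 2, sd_x, "/")
      foldid <- sample(rep_len(seq_len(folds), nrow(Xtr)))
      cv <- glmnet::cv.glmnet(Xs, ytr, alpha = 1, lambda = alpha_grid,
                              foldid = foldid, standardize = FALSE,
                              thresh = 1e-12, maxit = 1e6)
      # ties toward the larger (sparser) alpha
      lam <- max(cv$lambda[cv$cvm <= min(cv$cvm)])
      co <- as.numeric(coef(cv$glmnet.fit, s = lam))
      w_raw <- co[-1L] / sd_x
      b_raw <- co[1L] - sum(mu_x * w_raw)
      beta_path <- as.matrix(cv$glmnet.fit$beta)  # standardized scale
      channels[[ch]] <- list(
        weights = setNames(w_raw, FREQ_COLUMNS),
        intercept = b_raw,
        alpha = lam,
        cv_mse = setNames(cv$cvm, sprintf("%.3e", cv$lambda)),
        path_alpha = cv$glmnet.fit$lambda,
        path_l1 = colSums(abs(beta_path))
      )
      pred <- drop(X[test_idx, , drop = FALSE] %*% w_raw) + b_raw
      stats[[ch]] <- error_stats(y[test_idx], pred)
    }
  })
  structure(list(
    channels = channels,
    stats = stats,
    meta = list(cv_folds = folds, test_fraction = test_fraction,
                alpha_grid = alpha_grid, seed = seed,
                missing_channels = missing_ch,
                error_convention = "population")
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> channels: %s (folds=%d, test=%.0f%%)\n",
              paste(names(x$channels), collapse = ", "),
              x$meta$cv_folds, 100 * x$meta$test_fraction))
  for (ch in names(x$channels)) {
    s <- x$stats[[ch]]
    cat(sprintf("  %s: alpha=%.3g  MAE=%.4g  RMSE=%.4g  R2=%.4g\n",
                ch, x$channels[[ch]]$alpha, s$mae, s$rmse, s$r2))
  }
  invisible(x)
}

#' Predict loads from resonance frequencies
#'
#' Per-sample affine evaluation of the three fitted channel maps.
#'
#' @param model a [fit_calibration()] result.
#' @param freqs matrix or data frame with columns `f0..f3` (Hz).
#' @return data frame with columns `Fx`, `Fz`, `Mx` (fitted channels
#'   only).
#' @export
predict_loads <- function(model, freqs) {
  stopifnot(inherits(model, "calibration_model"))
  freqs <- as.data.frame(freqs)
  if (!all(FREQ_COLUMNS %in% names(freqs))) {
    stop("freqs must contain columns f0..f3", call. = FALSE)
  }
  X <- as.matrix(freqs[, FREQ_COLUMNS])
  if (length(model$channels) == 0L) {
    stop("model has no fitted channels", call. = FALSE)
  }
  out <- lapply(names(model$channels), function(ch) {
    m <- model$channels[[ch]]
    drop(X %*% m$weights) + m$intercept
  })
  names(out) <- names(model$channels)
  as.data.frame(out)
}

#' Serialise a calibration model to JSON
#'
#' Writes weights, intercepts and chosen regularisation per channel plus
#' the fit metadata; [calibration_from_json()] restores a model usable by
#' [predict_loads()].
#'
#' @param model a `calibration_model`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
calibration_to_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- list(
    channels = lapply(model$channels, function(m) {
      list(weights = as.list(m$weights), intercept = m$intercept,
           alpha = m$alpha)
    }),
    stats = lapply(model$stats, function(s) {
      s[c("mu", "sigma", "mae", "rmse", "r2", "n")]
    }),
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_to_json
#' @export
calibration_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- lapply(p$channels, function(m) {
    list(weights = setNames(as.numeric(m$weights[FREQ_COLUMNS]),
                            FREQ_COLUMNS),
         intercept = m$intercept, alpha = m$alpha)
  })
  structure(list(channels = channels,
                 stats = lapply(p$stats, function(s) {
                   structure(as.list(s), class = "error_stats")
                 }),
                 meta = p$meta),
            class = "calibration_model")
}
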