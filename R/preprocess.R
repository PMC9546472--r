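# Smoothing and baseline-and-amplitude (BAMP) detrending. Thallus growth
# produces a continuously increasing raw signal, and free-running rhythms
# damp; the moving-average baseline removes the former and the moving-SD
# envelope rescales away the latter before any rhythm statistic is computed.

#' Detrending configuration
#'
#' @param smooth_window_hours moving-average smoothing window (default 5 h).
#' @param baseline_window_hours window of the moving-average baseline
#'   (default 24 h, one circadian cycle).
#' @param amplitude_window_hours window of the moving-SD amplitude envelope
#'   (default 24 h).
#' @param amplitude_floor minimum envelope value treated as rhythmic signal;
#'   the envelope is clamped from below before division.
#' @return an object of class `detrend_config`.
#' @export
detrend_config <- function(smooth_window_hours = 5,
                           baseline_window_hours = 24,
                           amplitude_window_hours = 24,
                           amplitude_floor = 1e-3) {
  stopifnot(smooth_window_hours > 0, baseline_window_hours > 0,
            amplitude_window_hours > 0, amplitude_floor > 0)
  structure(list(smooth_window_hours = smooth_window_hours,
                 baseline_window_hours = baseline_window_hours,
                 amplitude_window_hours = amplitude_window_hours,
                 amplitude_floor = amplitude_floor),
            class = "detrend_config")
}

# window length in samples: centered, odd, truncated at series edges
.window_samples <- function(window_hours, dt_hours, n) {
  w <- max(1L, round(window_hours / dt_hours))
  if (w %% 2 == 0) w <- w + 1L
  min(w, if (n %% 2 == 0) n - 1L else n)
}

#' Centered moving average with truncated edges
#'
#' Mean over a centered window of `window_hours`; at the series edges the
#' window truncates to the available samples (no padding or reflection), so
#' output length equals input length and a constant series is unchanged.
#'
#' @param series numeric signal vector.
#' @param window_hours window width in hours.
#' @param dt_hours sampling interval in hours.
#' @return smoothed vector, same length as `series`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 5, 1)  # first point: mean(1, 2, 3)
#' @export
moving_average <- function(series, window_hours = 5, dt_hours = 1) {
  if (length(series) == 0) stop("empty series")
  w <- .window_samples(window_hours, dt_hours, length(series))
  if (w <= 1) return(as.numeric(series))
  as.numeric(zoo::rollapply(zoo::zoo(series), width = w, FUN = mean,
                            align = "center", partial = TRUE))
}

# centered moving SD with truncated edges (denominator n-1); single-sample
# windows at degenerate lengths give 0, not NA
.moving_sd <- function(series, window_hours, dt_hours) {
  w <- .window_samples(window_hours, dt_hours, length(series))
  if (w <= 1) return(rep(0, length(series)))
  out <- as.numeric(zoo::rollapply(zoo::zoo(series), width = w,
                                   FUN = stats::sd, align = "center",
                                   partial = TRUE))
  out[is.na(out)] <- 0
  out
}

#' Baseline-and-amplitude (BAMP) detrending
#'
#' Removes the moving-average baseline and divides the residual by its
#' moving-SD amplitude envelope (clamped below at `amplitude_floor`),
#' yielding a dimensionless series with near-zero local mean and unit-scale
#' envelope. An all-constant input returns zeros and a warning.
#'
#' @param series numeric signal vector.
#' @param cfg a [detrend_config()].
#' @param dt_hours sampling interval in hours.
#' @return detrended vector, same length as `series`.
#' @export
bamp_detrend <- function(series, cfg = detrend_config(), dt_hours = 1) {
  stopifnot(inherits(cfg, "detrend_config"))
  n <- length(series)
  if (n < round(cfg$baseline_window_hours / dt_hours))
    stop("series shorter than the baseline window")
  if (isTRUE(all(series == series[1]))) {
    warning("degenerate input: constant series, returning zeros")
    return(rep(0, n))
  }
  baseline <- moving_average(series, cfg$baseline_window_hours, dt_hours)
  resid <- series - baseline
  envelope <- .moving_sd(resid, cfg$amplitude_window_hours, dt_hours)
  resid / pmax(envelope, cfg$amplitude_floor)
}

#' Normalize a series to its mean
#'
#' Ratio mode divides by the mean (raw intensity traces); centered mode
#' subtracts it (appropriate after BAMP detrending where the mean is already
#' near zero). The mode used is recorded as an attribute.
#'
#' @param series numeric vector.
#' @param mode `"ratio"` or `"centered"`.
#' @return normalized vector with attribute `"mode"`.
#' @export
normalize_to_mean <- function(series, mode = c("ratio", "centered")) {
  mode <- match.arg(mode)
  m <- mean(series, na.rm = TRUE)
  out <- if (mode == "ratio") {
    if (abs(m) < .Machine$double.eps * 100)
      stop("zero mean: ratio normalization undefined")
    series / m
  } else {
    series - m
  }
  attr(out, "mode") <- mode
  out
}

#' Preprocess every replicate of a panel
#'
#' Applies, in order: 5-h moving-average smoothing, BAMP detrending, and
#' mean-centering, replicate by replicate.
#'
#' @param panel a [time_series_set()].
#' @param cfg a [detrend_config()].
#' @return a new `ts_set` of detrended signals.
#' @export
preprocess_panel <- function(panel, cfg = detrend_config()) {
  stopifnot(inherits(panel, "ts_set"))
  dt <- panel_dt(panel)
  out <- t(apply(panel$signals, 1, function(y) {
    y <- moving_average(y, cfg$smooth_window_hours, dt)
    y <- bamp_detrend(y, cfg, dt)
    as.numeric(normalize_to_mean(y, "centered"))
  }))
  res <- time_series_set(panel$times, out, panel$replicate_ids,
                         panel$regime,
                         label = paste0(panel$label, " (detrended)"))
  # filter warm-up span: within half a baseline window of either end the
  # truncated windows distort the waveform; fits should discard it
  attr(res, "edge_hours") <- cfg$baseline_window_hours / 2
  res
}
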