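# Phase-synchronization analysis: the Kuramoto order parameter r of the
# circadian-normalized phases of the rhythmic replicates, recomputed over a
# sliding window by refitting FFT-NLLS on each window segment. r = 1 means
# absolute phase synchrony, r = 0 uniform phase dispersion; psi, the
# argument of the mean phasor, is the circular mean phase.

#' Map a phase in hours to an angle in radians
#'
#' `theta = 2 pi (phase mod scale) / scale`.
#'
#' @param phase_hours phase value(s) in hours.
#' @param scale_hours circle circumference in hours (default 24).
#' @return angle(s) in `[0, 2 pi)`.
#' @export
phase_to_angle <- function(phase_hours, scale_hours = 24) {
  stopifnot(scale_hours > 0)
  2 * pi * (phase_hours %% scale_hours) / scale_hours
}

#' Kuramoto order parameter
#'
#' `r e^{i psi} = mean(e^{i theta_j})`; returns the modulus `r` (the
#' synchronization index) and the argument `psi` in `[0, 2 pi)` (the mean
#' phase).
#'
#' @param angles vector of phase angles in radians (at least one).
#' @return list with elements `r` and `psi`.
#' @examples
#' kuramoto_order(phase_to_angle(c(2, 4, 6), 24))  # r ~ 0.911
#' @export
kuramoto_order <- function(angles) {
  if (length(angles) == 0) stop("empty angle vector")
  z <- mean(exp(1i * angles))
  list(r = Mod(z), psi = Arg(z) %% (2 * pi))
}

#' Sliding-window phase synchrony
#'
#' Over windows `[k step, k step + width]` (k = 0, 1, ... while the window
#' fits the recording), refits FFT-NLLS to the window segment of every
#' rhythmic replicate, drops fits whose status is not `ok` (per window, not
#' globally), and computes the Kuramoto order parameter and mean RAE of the
#' included fits. Phases are circadian-normalized to `phase_scale_hours`
#' before the angle mapping. A window in which no fit survives is reported
#' with `n_included = 0` and `r = NA`, never dropped.
#'
#' @param panel a detrended [time_series_set()].
#' @param calls a [detect_rhythms()] table for the same panel (only
#'   replicates with `rhythmic == TRUE` are refit). `NULL` includes all.
#' @param width_hours,step_hours window width and step (defaults 48 and 24).
#' @param from_hours start of the first window (default 0).
#' @param max_components,circadian_window passed to [fit_fft_nlls()].
#' @param phase_scale_hours circle scale for the angle mapping (default 24;
#'   set to the T-cycle length for ZTC panels).
#' @return data frame of class `synchrony_result` with columns
#'   `window_start_hours`, `window_end_hours`, `n_included`, `r`,
#'   `mean_phase_hours` (psi mapped back to hours), `mean_rae`.
#' @export
sliding_window_sync <- function(panel, calls = NULL, width_hours = 48,
                                step_hours = 24, from_hours = 0,
                                max_components = 1,
                                circadian_window = c(18, 34),
                                phase_scale_hours = 24) {
  stopifnot(inherits(panel, "ts_set"))
  span <- max(panel$times)
  if (span - from_hours < width_hours)
    stop("panel duration is shorter than one window")
  keep <- if (is.null(calls)) rep(TRUE, nrow(panel$signals))
          else panel$replicate_ids %in% calls$replicate_id[calls$rhythmic]
  starts <- seq(from_hours, span - width_hours, by = step_hours)
  out <- lapply(starts, function(s) {
    idx <- panel$times >= s & panel$times <= s + width_hours
    phases <- numeric(0)
    raes <- numeric(0)
    for (j in which(keep)) {
      f <- tryCatch(
        fit_fft_nlls(panel$signals[j, idx], panel$times[idx],
                     max_components = max_components,
                     circadian_window = circadian_window),
        error = function(e) NULL)
      if (!is.null(f) && identical(f$status, "ok")) {
        phases <- c(phases, circadian_phase(f, phase_scale_hours))
        raes <- c(raes, f$rae)
      }
    }
    if (length(phases) == 0)
      return(data.frame(window_start_hours = s,
                        window_end_hours = s + width_hours, n_included = 0L,
                        r = NA_real_, mean_phase_hours = NA_real_,
                        mean_rae = NA_real_))
    ko <- kuramoto_order(phase_to_angle(phases, phase_scale_hours))
    data.frame(window_start_hours = s, window_end_hours = s + width_hours,
               n_included = length(phases), r = ko$r,
               mean_phase_hours = ko$psi * phase_scale_hours / (2 * pi),
               mean_rae = mean(raes))
  })
  res <- do.call(rbind, out)
  class(res) <- c("synchrony_result", class(res))
  res
}
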