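# FFT-seeded multi-cosine nonlinear least squares: the chronobiology
# standard for estimating period, phase, amplitude, and relative amplitude
# error (RAE). Cosines are added one at a time, each seeded at the largest
# remaining periodogram peak, and all parameters are refit jointly; a
# component is kept only while its amplitude is distinguishable from zero
# at 1 sigma. Each component i contributes
#   A_i cos(2 pi t / tau_i) + B_i sin(2 pi t / tau_i),
# i.e. amplitude a_i = sqrt(A_i^2 + B_i^2) and peak time
# phi_i = (tau_i / 2 pi) atan2(B_i, A_i) mod tau_i.

# dominant periodogram period of a residual vector (DC excluded)
.fft_peak_period <- function(r, dt) {
  n <- length(r)
  P <- Mod(fft(r))^2
  k <- 2:(floor(n / 2) + 1)
  kbest <- k[which.max(P[k])]
  n * dt / (kbest - 1)
}

# refine a component period near the FFT seed by profiling: for fixed tau
# the best (offset, slope, A, B) is an exact linear LS problem, so scan tau
# on a grid spanning the periodogram's frequency resolution and return the
# tau and linear coefficients minimizing the RSS
.profile_component <- function(resid, t, tau0) {
  rss_at <- function(tau) {
    X <- cbind(1, t, cos(2 * pi * t / tau), sin(2 * pi * t / tau))
    f <- stats::lm.fit(X, resid)
    sum(f$residuals^2)
  }
  taus <- tau0 * seq(0.72, 1.4, length.out = 33)
  rss <- vapply(taus, rss_at, numeric(1))
  i <- which.min(rss)
  lo <- taus[max(1, i - 1)]; hi <- taus[min(length(taus), i + 1)]
  opt <- stats::optimize(rss_at, c(lo, hi))
  tau <- opt$minimum
  cf <- stats::lm.fit(cbind(1, t, cos(2 * pi * t / tau),
                            sin(2 * pi * t / tau)), resid)$coefficients
  list(tau = tau, c0 = unname(cf[1]), c1 = unname(cf[2]),
       A = unname(cf[3]), B = unname(cf[4]))
}

# model: residual linear trend (the pre-detrend line is refit jointly, so
# trend leaked into short segments cannot bias the periods) plus k cosines
.cos_formula <- function(k) {
  terms <- vapply(seq_len(k), function(i) {
    sprintf("A%d * cos(2 * pi * t / tau%d) + B%d * sin(2 * pi * t / tau%d)",
            i, i, i, i)
  }, character(1))
  stats::as.formula(paste("y ~ c0 + c1 * t +",
                          paste(terms, collapse = " + ")))
}

# joint NLS refit of k components; returns NULL on failure
.fit_k_cosines <- function(y, t, start, dt) {
  k <- (length(start) - 2) / 3
  # subnormal-scale start values destabilize the optimizer's internal
  # scaling; snap them to zero
  start[abs(start) < 1e-10 * max(abs(y), 1)] <- 0
  lower <- rep(-Inf, length(start))
  upper <- rep(Inf, length(start))
  names(lower) <- names(upper) <- names(start)
  tau_idx <- grep("^tau", names(start))
  lower[tau_idx] <- 2.5 * dt
  upper[tau_idx] <- 4 * diff(range(t))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      .cos_formula(k), data = list(y = y, t = t), start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      suppressWarnings(stats::nls(
        .cos_formula(k), data = list(y = y, t = t), start = as.list(start),
        lower = lower, upper = upper, algorithm = "port",
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE))),
      error = function(e) NULL)
  fit
}

# component table (amplitude/phase and 1-sigma SEs via the delta method from
# the linearized covariance at the optimum)
.component_table <- function(fit, k) {
  cf <- coef(fit)
  V <- tryCatch(suppressWarnings(vcov(fit)), error = function(e) NULL)
  out <- data.frame(period_hours = numeric(k), amplitude = numeric(k),
                    phase_hours = numeric(k), se_period = numeric(k),
                    se_amplitude = numeric(k), se_phase = numeric(k))
  for (i in seq_len(k)) {
    A <- cf[sprintf("A%d", i)]; B <- cf[sprintf("B%d", i)]
    tau <- cf[sprintf("tau%d", i)]
    a <- sqrt(A^2 + B^2)
    phi <- (tau / (2 * pi)) * atan2(B, A)
    out$period_hours[i] <- tau
    out$amplitude[i] <- a
    out$phase_hours[i] <- phi %% tau
    nm <- sprintf(c("A%d", "B%d", "tau%d"), i)
    if (!is.null(V) && all(nm %in% rownames(V)) && a > 0) {
      Vi <- V[nm, nm]
      g_amp <- c(A / a, B / a, 0)
      g_phi <- c(-B / a^2 * tau / (2 * pi), A / a^2 * tau / (2 * pi),
                 atan2(B, A) / (2 * pi))
      out$se_amplitude[i] <- sqrt(max(0, drop(t(g_amp) %*% Vi %*% g_amp)))
      out$se_phase[i] <- sqrt(max(0, drop(t(g_phi) %*% Vi %*% g_phi)))
      out$se_period[i] <- sqrt(max(0, Vi[3, 3]))
    } else {
      out$se_amplitude[i] <- NA_real_
      out$se_phase[i] <- NA_real_
      out$se_period[i] <- NA_real_
    }
  }
  out
}

#' Fit a sum of cosines by FFT-seeded nonlinear least squares
#'
#' Removes a linear trend, then iteratively (1) locates the largest
#' remaining periodogram peak, (2) adds a cosine seeded there, and (3)
#' refits offset and all component parameters jointly, stopping when
#' `max_components` is reached or the newly added component's amplitude is
#' not distinguishable from zero at 1 sigma. The circadian component is the
#' one with period inside `circadian_window` (largest amplitude if
#' several); its RAE is the ratio of the 1-sigma amplitude error to the
#' amplitude, clipped to [0, 1].
#'
#' @param series numeric signal vector.
#' @param times hour grid (t = 0 is entrained dawn).
#' @param max_components maximum number of cosine components (default 4).
#' @param circadian_window closed period window, hours (default 18-34).
#' @return object of class `rhythm_fit`: component table, index of the
#'   selected circadian component, `period_hours` with `se_period`,
#'   dawn-referenced `phase_hours` in `[0, period)`, `amplitude`, `rae`,
#'   residual `rss`, and `status` (`ok`, `no_circadian_component`, or
#'   `non_convergent`).
#' @export
fit_fft_nlls <- function(series, times, max_components = 4,
                         circadian_window = c(18, 34)) {
  stopifnot(length(series) == length(times), length(series) >= 48)
  dt <- diff(times[1:2])
  trend <- lm(series ~ times)
  y <- as.numeric(stats::residuals(trend))
  scale0 <- sd(y)
  empty <- structure(
    list(components = NULL, selected = NA_integer_,
         period_hours = NA_real_, se_period = NA_real_,
         phase_hours = NA_real_, amplitude = NA_real_, rae = NA_real_,
         rss = NA_real_, n = length(y), status = "non_convergent"),
    class = "rhythm_fit")
  if (scale0 < 1e-10 * max(1, abs(mean(series)))) return(empty)

  fit <- NULL
  start <- c(c0 = mean(y), c1 = 0)
  for (k in seq_len(max_components)) {
    resid <- if (is.null(fit)) y - mean(y) else as.numeric(stats::residuals(fit))
    if (sd(resid) < 1e-9 * scale0) break
    tau0 <- .fft_peak_period(resid, dt)
    prof <- .profile_component(resid, times, tau0)
    new <- setNames(c(prof$A, prof$B, prof$tau),
                    sprintf(c("A%d", "B%d", "tau%d"), k))
    start["c0"] <- start["c0"] + prof$c0
    start["c1"] <- start["c1"] + prof$c1
    cand <- .fit_k_cosines(y, times, c(start, new), dt)
    if (is.null(cand)) break
    comp <- .component_table(cand, k)
    amp_k <- comp$amplitude[k]
    se_k <- comp$se_amplitude[k]
    if (k > 1 && is.finite(se_k) && amp_k <= se_k) break  # new comp is noise
    fit <- cand
    start <- coef(cand)
  }
  if (is.null(fit)) return(empty)

  k_fit <- (length(coef(fit)) - 2) / 3
  comp <- .component_table(fit, k_fit)
  out <- empty
  out$components <- comp
  out$rss <- sum(stats::residuals(fit)^2)
  in_win <- which(comp$period_hours >= circadian_window[1] &
                    comp$period_hours <= circadian_window[2])
  if (length(in_win) == 0) {
    out$status <- "no_circadian_component"
    return(out)
  }
  sel <- in_win[which.max(comp$amplitude[in_win])]
  out$selected <- sel
  out$period_hours <- comp$period_hours[sel]
  out$se_period <- comp$se_period[sel]
  out$phase_hours <- comp$phase_hours[sel]
  out$amplitude <- comp$amplitude[sel]
  out$status <- "ok"
  out$rae <- relative_amplitude_error(out)
  out
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf("<rhythm_fit> status = %s", x$status))
  if (identical(x$status, "ok"))
    cat(sprintf(": period %.2f +/- %.3f h, phase %.2f h, amplitude %.3g, RAE %.3f",
                x$period_hours, x$se_period, x$phase_hours, x$amplitude,
                x$rae))
  cat("\n")
  invisible(x)
}

#' Relative amplitude error of the selected circadian component
#'
#' RAE is the ratio of the 1-sigma amplitude standard error to the fitted
#' amplitude, clipped to [0, 1]: 0 marks a robust non-damping rhythm, 1 an
#' amplitude statistically indistinguishable from zero.
#'
#' @param fit a `rhythm_fit` with `status == "ok"`.
#' @return RAE in [0, 1].
#' @export
relative_amplitude_error <- function(fit) {
  stopifnot(inherits(fit, "rhythm_fit"), identical(fit$status, "ok") ||
              !is.na(fit$selected))
  amp <- fit$components$amplitude[fit$selected]
  se <- fit$components$se_amplitude[fit$selected]
  if (!is.finite(amp) || amp == 0) stop("zero amplitude: RAE undefined")
  if (!is.finite(se)) return(1)
  min(1, max(0, se / amp))
}

#' Dawn-referenced circadian phase
#'
#' The raw phase is the time of the first fitted peak after dawn (t = 0),
#' modulo the fitted period. When `normalize_to_hours` is given (24 by
#' default) the phase is rescaled by `normalize_to_hours / period`,
#' yielding circadian-time hours in `[0, normalize_to_hours)`; pass
#' `normalize_to_hours = NULL` for the raw phase.
#'
#' @param fit a `rhythm_fit` with `status == "ok"`.
#' @param normalize_to_hours circadian scale (default 24), or `NULL`.
#' @return phase in hours.
#' @export
circadian_phase <- function(fit, normalize_to_hours = 24) {
  stopifnot(inherits(fit, "rhythm_fit"), identical(fit$status, "ok"))
  raw <- fit$phase_hours %% fit$period_hours
  if (is.null(normalize_to_hours)) return(raw)
  raw * normalize_to_hours / fit$period_hours
}

#' Fit every replicate of a panel
#'
#' Runs [fit_fft_nlls()] on each row of the panel and tabulates period,
#' phase (raw and circadian-normalized), amplitude, RAE, and fit status.
#'
#' @param panel a [time_series_set()] (normally detrended).
#' @param max_components,circadian_window passed to [fit_fft_nlls()].
#' @param normalize_to_hours circadian scale for the normalized phase.
#' @param edge_trim_hours span discarded at each end of the series before
#'   fitting. Detrending filters distort the waveform within half a
#'   baseline window of the ends (truncated windows), which biases period
#'   estimates; [preprocess_panel()] records that span and it is trimmed
#'   here by default. `0` fits the full series.
#' @return data frame, one row per replicate.
#' @export
fit_panel <- function(panel, max_components = 4, circadian_window = c(18, 34),
                      normalize_to_hours = 24, edge_trim_hours = NULL) {
  stopifnot(inherits(panel, "ts_set"))
  if (is.null(edge_trim_hours))
    edge_trim_hours <- attr(panel, "edge_hours") %||% 0
  keep <- panel$times >= min(panel$times) + edge_trim_hours &
    panel$times <= max(panel$times) - edge_trim_hours
  if (sum(keep) < 48) keep <- rep(TRUE, length(panel$times))
  rows <- lapply(seq_len(nrow(panel$signals)), function(j) {
    f <- fit_fft_nlls(panel$signals[j, keep], panel$times[keep],
                      max_components, circadian_window)
    ok <- identical(f$status, "ok")
    data.frame(
      replicate_id = panel$replicate_ids[j],
      period_hours = f$period_hours, se_period = f$se_period,
      phase_hours = if (ok) circadian_phase(f, NULL) else NA_real_,
      phase_ct_hours = if (ok) circadian_phase(f, normalize_to_hours)
                       else NA_real_,
      amplitude = f$amplitude, rae = f$rae, status = f$status,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
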