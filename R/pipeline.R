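# I/O and orchestration: CSV panel readers/writers, the pipeline
# configuration object, the one-call pipeline (preprocess -> detect -> fit
# -> synchrony) and the on-disk report. CSV is the only required format:
# DF and PAM panels are plain intensity tables.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline stages; echoed into the report so
#' a run can be reproduced bit-identically from `(input, config, seed)`.
#'
#' @param detrend a [detrend_config()].
#' @param q_threshold,period_range rhythmic-call thresholds
#'   (see [call_rhythmic()]).
#' @param n_perm Lomb-Scargle permutation count.
#' @param max_components,circadian_window FFT-NLLS settings
#'   (see [fit_fft_nlls()]).
#' @param sync_width_hours,sync_step_hours,sync_from_hours sliding-window
#'   geometry (see [sliding_window_sync()]).
#' @param sync_max_components components for the windowed refits.
#' @param phase_scale_hours circadian scale for phase angles.
#' @param seed master seed; all stage randomness is derived from it with
#'   [split_seed()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(detrend = detrend_config(), q_threshold = 0.001,
                            period_range = c(18, 34), n_perm = 200,
                            max_components = 4, circadian_window = c(18, 34),
                            sync_width_hours = 48, sync_step_hours = 24,
                            sync_from_hours = 0, sync_max_components = 1,
                            phase_scale_hours = 24, seed = 1) {
  stopifnot(inherits(detrend, "detrend_config"), q_threshold > 0,
            length(period_range) == 2, n_perm >= 1, max_components >= 1,
            sync_width_hours > 0, sync_step_hours > 0)
  structure(
    list(detrend = detrend, q_threshold = q_threshold,
         period_range = period_range, n_perm = n_perm,
         max_components = max_components,
         circadian_window = circadian_window,
         sync_width_hours = sync_width_hours,
         sync_step_hours = sync_step_hours,
         sync_from_hours = sync_from_hours,
         sync_max_components = sync_max_components,
         phase_scale_hours = phase_scale_hours, seed = seed),
    class = "pipeline_config")
}

# interpolate isolated single-sample gaps; longer gaps are an error
.fill_single_gaps <- function(y, times, id) {
  if (!anyNA(y)) return(list(y = y, n_filled = 0L))
  r <- rle(is.na(y))
  if (any(r$lengths[r$values] > 1))
    stop(sprintf("replicate '%s' has > 1 consecutive missing sample", id))
  filled <- as.numeric(zoo::na.approx(zoo::zoo(y, times), na.rm = FALSE,
                                      maxgap = 1, rule = 2))
  list(y = filled, n_filled = sum(is.na(y)))
}

#' Read a time-series panel from CSV
#'
#' Wide layout: first column is time in hours, remaining columns are
#' replicates. Long layout: columns time, replicate, value. Column names
#' can be remapped through `column_map` (elements `time`, `replicate`,
#' `value`), so files with arbitrary headers can be loaded. Non-uniform
#' grids and duplicated times are rejected; isolated single missing values
#' are linearly interpolated with a message, longer gaps are an error.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param regime a [light_regime()] annotation for the panel.
#' @param column_map optional named list remapping column names.
#' @param label signal label.
#' @return a [time_series_set()].
#' @export
read_timeseries_csv <- function(path, layout = c("wide", "long"),
                                regime = light_regime("FRL"),
                                column_map = NULL, label = "DF") {
  layout <- match.arg(layout)
  df <- read.csv(path, check.names = FALSE)
  if (layout == "long") {
    tc <- column_map$time %||% "time_h"
    rc <- column_map$replicate %||% "replicate"
    vc <- column_map$value %||% "value"
    if (!all(c(tc, rc, vc) %in% names(df)))
      stop("long layout needs columns: ", tc, ", ", rc, ", ", vc)
    wide <- stats::reshape(df[, c(tc, rc, vc)], idvar = tc, timevar = rc,
                           direction = "wide")
    names(wide) <- sub(paste0("^", vc, "\\."), "", names(wide))
    df <- wide[order(wide[[tc]]), , drop = FALSE]
    time_col <- tc
  } else {
    time_col <- column_map$time %||% names(df)[1]
    if (!time_col %in% names(df)) stop("time column not found: ", time_col)
  }
  times <- df[[time_col]]
  if (anyDuplicated(times))
    stop(sprintf("duplicated time point t = %g",
                 times[duplicated(times)][1]))
  reps <- setdiff(names(df), time_col)
  sig <- t(as.matrix(df[reps]))
  if (!is.numeric(sig)) stop("non-numeric signal cells in ", path)
  n_filled <- 0L
  for (j in seq_len(nrow(sig))) {
    g <- .fill_single_gaps(sig[j, ], times, reps[j])
    sig[j, ] <- g$y
    n_filled <- n_filled + g$n_filled
  }
  if (n_filled > 0)
    message(sprintf("interpolated %d isolated missing value(s)", n_filled))
  time_series_set(times, sig, replicate_ids = reps, regime = regime,
                  label = label)
}

#' Write a panel to wide CSV
#'
#' First column `time_h`, one column per replicate; inverse of
#' [read_timeseries_csv()] with the wide layout.
#'
#' @param panel a [time_series_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(panel, path) {
  stopifnot(inherits(panel, "ts_set"))
  df <- data.frame(time_h = panel$times, t(panel$signals),
                   check.names = FALSE)
  colnames(df) <- c("time_h", panel$replicate_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full rhythm-analysis pipeline on a panel
#'
#' Stages in order: moving-average smoothing and BAMP detrending (the
#' waveform track used for fitting and synchrony), rhythmicity calling
#' (LS + JTK on the linearly detrended raw signals, Fisher combination, BH
#' q-values; see [detect_rhythms()] for why the tests do not run on the
#' filtered track), FFT-NLLS parameter estimation, and sliding-window
#' Kuramoto synchrony of the rhythmic replicates. Deterministic given
#' `(panel, config)`; all stage randomness derives from `config$seed`.
#'
#' @param panel a raw [time_series_set()].
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`: `calls`, `fits`, `sync`
#'   tables, a `summary` list (n, n_rhythmic, rhythmic_fraction, mean
#'   period +/- SEM, mean RAE +/- SEM over rhythmic ok fits), the config
#'   echo, the seed, and the package version.
#' @export
run_pipeline <- function(panel, config = pipeline_config()) {
  stopifnot(inherits(panel, "ts_set"), inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 2)
  det <- tryCatch(preprocess_panel(panel, config$detrend),
                  error = function(e) stop("preprocess: ", conditionMessage(e)))
  calls <- tryCatch(
    detect_rhythms(panel, config$q_threshold, config$period_range,
                   n_perm = config$n_perm, seed = seeds[1]),
    error = function(e) stop("detect: ", conditionMessage(e)))
  fits <- tryCatch(
    fit_panel(det, config$max_components, config$circadian_window,
              config$phase_scale_hours),
    error = function(e) stop("fit: ", conditionMessage(e)))
  span <- max(det$times) - config$sync_from_hours
  sync <- if (span >= config$sync_width_hours) {
    tryCatch(
      sliding_window_sync(det, calls, config$sync_width_hours,
                          config$sync_step_hours, config$sync_from_hours,
                          config$sync_max_components,
                          config$circadian_window,
                          config$phase_scale_hours),
      error = function(e) stop("synchrony: ", conditionMessage(e)))
  } else {
    warning("panel shorter than one synchrony window: empty synchrony table")
    empty <- data.frame(window_start_hours = numeric(0),
                        window_end_hours = numeric(0),
                        n_included = integer(0), r = numeric(0),
                        mean_phase_hours = numeric(0),
                        mean_rae = numeric(0))
    class(empty) <- c("synchrony_result", class(empty))
    empty
  }
  ok <- fits$status == "ok" &
    fits$replicate_id %in% calls$replicate_id[calls$rhythmic]
  per <- fits$period_hours[ok]
  rae <- fits$rae[ok]
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  structure(
    list(calls = calls, fits = fits, sync = sync,
         summary = list(
           n = nrow(calls), n_rhythmic = sum(calls$rhythmic),
           rhythmic_fraction = mean(calls$rhythmic),
           mean_period_hours = if (length(per)) mean(per) else NA_real_,
           sem_period_hours = sem(per),
           mean_rae = if (length(rae)) mean(rae) else NA_real_,
           sem_rae = sem(rae)),
         config = config, seed = config$seed,
         version = as.character(utils::packageVersion("circasync"))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_report> %d replicates, %d rhythmic (%.0f%%)\n",
              s$n, s$n_rhythmic, 100 * s$rhythmic_fraction))
  if (!is.na(s$mean_period_hours))
    cat(sprintf("  mean period %.2f +/- %.2f h, mean RAE %.2f +/- %.2f\n",
                s$mean_period_hours, s$sem_period_hours, s$mean_rae,
                s$sem_rae))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `calls.csv`, `fits.csv`, `sync.csv`, `summary.json` (summary,
#' seed, version and a timestamp) and `config.yaml` with stable column
#' order.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  write.csv(report$calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  write.csv(report$fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  write.csv(report$sync, file.path(out_dir, "sync.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, seed = report$seed,
         version = report$version,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- report$config
  cfg_list <- lapply(unclass(cfg), function(x)
    if (inherits(x, "detrend_config")) unclass(x) else x)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
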