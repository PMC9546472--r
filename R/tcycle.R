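# T-cycle analysis and group statistics: phases recorded under zeitgeber
# cycles of length T are normalized to a common 24-h scale so their timing
# relative to the cycle can be compared across T, and rhythm parameters are
# compared across treatment groups by one-way ANOVA with Tukey's HSD and a
# compact letter display.

#' Normalize a T-cycle phase to the 24-h scale
#'
#' `phase24 = phase * 24 / T`. Phases outside `[0, T)` are reduced modulo T
#' first, with a warning.
#'
#' @param phase_hours phase value(s) within the T-cycle, hours.
#' @param T_hours zeitgeber cycle length.
#' @return phase(s) on the 24-h scale.
#' @examples
#' normalize_phase_to_24(14, 28)  # 12
#' @export
normalize_phase_to_24 <- function(phase_hours, T_hours) {
  stopifnot(T_hours > 0)
  if (any(phase_hours < 0 | phase_hours >= T_hours, na.rm = TRUE)) {
    warning("phase outside [0, T): reduced modulo T")
    phase_hours <- phase_hours %% T_hours
  }
  phase_hours * 24 / T_hours
}

#' Mean fitted period per T-cycle panel
#'
#' Runs the preprocessing, rhythmicity-calling and FFT-NLLS stages on each
#' panel and tabulates the mean fitted period (with SEM and count) over the
#' rhythmic, successfully fitted replicates.
#'
#' @param panels named list of [time_series_set()]s; names are the T-cycle
#'   lengths in hours (e.g. `list("20" = ..., "24" = ...)`).
#' @param cfg a [pipeline_config()]; its detection and fitting settings are
#'   used for every panel.
#' @return data frame with columns `T_hours`, `mean_period_hours`, `sem`,
#'   `n_rhythmic` and a logical `degenerate` flag for panels with no
#'   rhythmic replicate.
#' @export
period_vs_T <- function(panels, cfg = pipeline_config()) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  seeds <- split_seed(cfg$seed, length(panels))
  rows <- lapply(seq_along(panels), function(i) {
    panel <- panels[[i]]
    det <- preprocess_panel(panel, cfg$detrend)
    calls <- detect_rhythms(det, cfg$q_threshold, cfg$period_range,
                            n_perm = cfg$n_perm, seed = seeds[i])
    fits <- fit_panel(det, cfg$max_components, cfg$circadian_window)
    ok <- fits$status == "ok" &
      fits$replicate_id %in% calls$replicate_id[calls$rhythmic]
    per <- fits$period_hours[ok]
    data.frame(
      T_hours = as.numeric(names(panels)[i]),
      mean_period_hours = if (length(per)) mean(per) else NA_real_,
      sem = if (length(per) > 1) sd(per) / sqrt(length(per)) else NA_real_,
      n_rhythmic = length(per), degenerate = length(per) == 0)
  })
  do.call(rbind, rows)
}

# compact letter display by insert-and-absorb from a logical matrix of
# significant pairwise differences
.letter_display <- function(sig, labels) {
  k <- length(labels)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!sig[i, j]) next
      hit <- vapply(cols, function(ct) all(c(i, j) %in% ct), logical(1))
      if (!any(hit)) next
      kept <- cols[!hit]
      for (ct in cols[hit])
        kept <- c(kept, list(setdiff(ct, i)), list(setdiff(ct, j)))
      cols <- kept[lengths(kept) > 0]
      # absorb columns contained in another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] &&
              all(cols[[a]] %in% cols[[b]]) &&
              (length(cols[[a]]) < length(cols[[b]]) || a > b))
            keep[a] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(ct) g %in% ct, logical(1)))],
          collapse = "")
  }, character(1))
}

#' One-way ANOVA with Tukey's HSD and compact letters
#'
#' Compares a rhythm parameter (period, RAE, amplitude, normalized phase)
#' across groups: one-way ANOVA F test, Tukey HSD over all pairs at family
#' alpha, and a compact letter display in which groups sharing a letter are
#' not significantly different.
#'
#' @param values_by_group named list of numeric vectors, one per group
#'   (at least 2 groups of at least 2 values each).
#' @param alpha family-wise significance level (default 0.05).
#' @return object of class `group_comparison`: `group_labels`,
#'   `group_means`, `sem`, `n`, `F_statistic`, `p_anova`, `tukey_p`
#'   (pairwise matrix) and `tukey_letters`.
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(10, 11, 12)))
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group))
  if (length(values_by_group) < 2)
    stop("at least 2 groups are required")
  sizes <- lengths(values_by_group)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  labels <- names(values_by_group) %||%
    paste0("group", seq_along(values_by_group))
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(labels, sizes), levels = labels))
  if (var(df$value) == 0) stop("zero pooled variance")
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  k <- length(labels)
  pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  sig <- !is.na(pmat) & pmat < alpha
  structure(
    list(group_labels = labels,
         group_means = vapply(values_by_group, mean, numeric(1)),
         sem = vapply(values_by_group,
                      function(v) sd(v) / sqrt(length(v)), numeric(1)),
         n = sizes,
         F_statistic = tab[["F value"]][1], p_anova = tab[["Pr(>F)"]][1],
         tukey_p = pmat,
         tukey_letters = .letter_display(sig, labels), alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F = %.3g, p = %.3g\n",
              x$F_statistic, x$p_anova))
  print(data.frame(group = x$group_labels, mean = x$group_means,
                   sem = x$sem, n = as.integer(x$n),
                   letters = x$tukey_letters, row.names = NULL))
  invisible(x)
}
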