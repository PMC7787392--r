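#' Read a radiometer irradiance log
#'
#' Canonical dialect: tab-separated columns `time_s` and `irradiance_mW_cm2`.
#' Vendor exports can be adapted via `parser`, a function taking the file
#' path and returning a data frame with those two columns.
#'
#' @param path Log file path.
#' @param parser Optional function `path -> data.frame` for vendor formats.
#' @return A tibble with class `irradiance_log`: `time_s` (strictly
#'   increasing) and `irradiance_mW_cm2` (`>= 0`), at least 3 samples.
#' @export
read_irradiance_log <- function(path, parser = NULL) {
  df <- if (is.null(parser)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    as_tibble(parser(path))
  }
  as_irradiance_log(df)
}

#' Validate a data frame as an irradiance log
#'
#' @param df Data frame with `time_s` and `irradiance_mW_cm2` columns.
#' @return The validated tibble with class `irradiance_log` prepended.
#' @export
as_irradiance_log <- function(df) {
  if (!all(c("time_s", "irradiance_mW_cm2") %in% names(df))) {
    abort("irradiance log needs columns time_s and irradiance_mW_cm2")
  }
  if (nrow(df) < 3) abort("irradiance log needs at least 3 samples")
  if (any(diff(df$time_s) <= 0)) abort("time_s must be strictly increasing")
  if (any(df$irradiance_mW_cm2 < 0)) abort("irradiance must be >= 0")
  df <- as_tibble(df)
  class(df) <- c("irradiance_log", class(df))
  df
}

.window_idx <- function(n, window) {
  if (is.null(window)) seq_len(n)
  else seq.int(max(1L, window[1]), min(n, window[2]))
}

#' Integrate UV-C dose from an irradiance log
#'
#' Left-Riemann sum `sum(I_i * dt_i)` over logged intervals, so 1 mW/cm^2
#' held for 1 s contributes 1 mJ/cm^2. The final sample closes no interval
#' and contributes no area. Trapezoidal integration is available as an
#' option.
#'
#' @param log An `irradiance_log`.
#' @param window Optional 1-based iteration window `c(first, last)`.
#' @param method `"left"` (default) or `"trapezoid"`.
#' @return Dose in mJ/cm^2.
#' @export
integrate_dose <- function(log, window = NULL, method = c("left", "trapezoid")) {
  method <- match.arg(method)
  idx <- .window_idx(nrow(log), window)
  if (length(idx) < 2) {
    warn("window holds fewer than 2 samples; dose is 0")
    return(0)
  }
  t <- log$time_s[idx]
  irr <- log$irradiance_mW_cm2[idx]
  dt <- diff(t)
  if (method == "left") sum(irr[-length(irr)] * dt)
  else sum((irr[-length(irr)] + irr[-1]) / 2 * dt)
}

#' Detect lamp shutoff in an irradiance log
#'
#' Returns the 1-based index of the first sample whose irradiance drops,
#' relative to the previous sample, by more than `threshold` times the
#' maximum irradiance recorded in the log. Referencing the recorded maximum
#' (rather than a running maximum) keeps the detector from false-triggering
#' on noise early in warm-up, when the output is still small. Analysis
#' windows conventionally end two iterations before this index. If no such
#' drop exists the log is treated as ongoing and the log length is
#' returned.
#'
#' @param log An `irradiance_log`.
#' @param threshold Drop fraction of the recorded maximum (default 0.5).
#' @return Integer index `i_end`.
#' @export
detect_shutoff <- function(log, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  irr <- log$irradiance_mW_cm2
  drops <- c(FALSE, -diff(irr) > threshold * max(irr))
  if (any(drops)) which(drops)[1] else length(irr)
}

#' Lamp warm-up 10-90% rise time
#'
#' Time for the irradiance to rise from 10% to 90% of the maximum recorded
#' value, with linear interpolation between the bracketing samples at each
#' crossing.
#'
#' @param log An `irradiance_log`.
#' @return Rise time in seconds (0, with a warning, for a constant log).
#' @export
rise_time_10_90 <- function(log) {
  irr <- log$irradiance_mW_cm2
  t <- log$time_s
  imax <- max(irr)
  if (imax <= 0 || diff(range(irr)) == 0) {
    warn("degenerate (constant or zero) log: rise time is 0")
    return(0)
  }
  cross <- function(level) {
    i <- which(irr >= level)[1]
    if (i == 1) return(t[1])
    t[i - 1] + (level - irr[i - 1]) / (irr[i] - irr[i - 1]) * (t[i] - t[i - 1])
  }
  max(0, cross(0.9 * imax) - cross(0.1 * imax))
}

#' Lamp output degradation slope
#'
#' Ordinary least-squares slope of irradiance against time over the chosen
#' window, with its standard error.
#'
#' @param log An `irradiance_log`.
#' @param window Optional 1-based iteration window `c(first, last)`.
#' @return A tibble: `slope_mW_cm2_per_s`, `se`, `intercept`, `n`.
#' @export
degradation_slope <- function(log, window = NULL) {
  idx <- .window_idx(nrow(log), window)
  if (length(idx) < 3) abort("need at least 3 samples to fit a slope")
  fit <- lm(irradiance_mW_cm2 ~ time_s, data = log[idx, ])
  sm <- summary(fit)$coefficients
  tibble(slope_mW_cm2_per_s = sm["time_s", "Estimate"],
         se = sm["time_s", "Std. Error"],
         intercept = sm["(Intercept)", "Estimate"],
         n = length(idx))
}

#' Exposure-time estimates from snapshot irradiances
#'
#' Estimated time to reach a target dose computed as target / mean
#' irradiance, using (a) a start-of-exposure window (iterations 10-20 by
#' default) and (b) an end-of-exposure window (the last 11 iterations before
#' the detected shutoff). The discrepancy between the two quantifies the
#' error of extrapolating a single snapshot under unstable lamp output.
#'
#' @param log An `irradiance_log`.
#' @param target Target dose in mJ/cm^2 (default 1000, i.e. 1.0 J/cm^2).
#' @param start_window 1-based iteration window for the start estimate.
#' @param end_n Number of iterations before shutoff for the end estimate.
#' @param threshold Shutoff detection threshold (see [detect_shutoff()]).
#' @return A tibble: `t_est_start_s`, `t_est_end_s`, `mean_irr_start`,
#'   `mean_irr_end`, `i_end`.
#' @export
estimate_time_to_dose <- function(log, target = 1000,
                                  start_window = c(10L, 20L), end_n = 11L,
                                  threshold = 0.5) {
  stopifnot(target > 0)
  i_end <- detect_shutoff(log, threshold)
  irr <- log$irradiance_mW_cm2
  sidx <- .window_idx(nrow(log), start_window)
  eidx <- seq.int(max(1L, i_end - end_n), max(1L, i_end - 1L))
  m_start <- mean(irr[sidx])
  m_end <- mean(irr[eidx])
  if (m_start <= 0 || m_end <= 0) abort("window mean irradiance must be > 0")
  tibble(t_est_start_s = target / m_start, t_est_end_s = target / m_end,
         mean_irr_start = m_start, mean_irr_end = m_end, i_end = i_end)
}

#' Full lamp stability report
#'
#' Combines shutoff detection, warm-up rise time, degradation slope (over
#' the post-warm-up portion up to `i_end - 2`) and the start/end snapshot
#' exposure-time estimates into one row.
#'
#' @inheritParams estimate_time_to_dose
#' @return A one-row tibble: `i_end`, `rise_time_10_90_s`,
#'   `degradation_slope_mW_cm2_per_s`, `slope_se`, `dose_mJ_cm2`,
#'   `t_est_start_s`, `t_est_end_s`.
#' @export
stability_report <- function(log, target = 1000, threshold = 0.5,
                             start_window = c(10L, 20L), end_n = 11L) {
  i_end <- detect_shutoff(log, threshold)
  trimmed <- log[seq_len(max(3L, i_end - 2L)), ]
  rt <- rise_time_10_90(trimmed)
  peak_at <- which.max(trimmed$irradiance_mW_cm2)
  slope_win <- c(min(peak_at, nrow(trimmed) - 2L), nrow(trimmed))
  sl <- degradation_slope(trimmed, slope_win)
  te <- estimate_time_to_dose(log, target, start_window, end_n, threshold)
  tibble(i_end = i_end, rise_time_10_90_s = rt,
         degradation_slope_mW_cm2_per_s = sl$slope_mW_cm2_per_s,
         slope_se = sl$se,
         dose_mJ_cm2 = integrate_dose(log, c(1L, max(3L, i_end - 2L))),
         t_est_start_s = te$t_est_start_s, t_est_end_s = te$t_est_end_s)
}

#' Plot an irradiance log
#'
#' @param log An `irradiance_log`.
#' @param threshold Shutoff threshold used to mark `i_end - 2`.
#' @return A ggplot object.
#' @export
plot_irradiance_log <- function(log, threshold = 0.5) {
  i_end <- detect_shutoff(log, threshold)
  shown <- log[seq_len(max(3L, i_end - 2L)), ]
  ggplot2::ggplot(shown, ggplot2::aes(.data$time_s, .data$irradiance_mW_cm2)) +
    ggplot2::geom_line(color = "#2c3e50") +
    ggplot2::labs(x = "time (s)", y = "irradiance (mW/cm²)") +
    ggplot2::theme_minimal()
}
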