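#' Per-pulse record of cavitation areas
#'
#' Holds one laser event's calibrated area time series together with its
#' timing metadata, and derives the per-pulse maxima: `A_PB_max` and
#' `A_SC_max` over the first-pulse window, and for the dual-pulse (ASW)
#' modality `A_SC_max_2nd`, the SC maximum in the second-pulse window
#' `[t_d, t_d + second_window_us)`.
#'
#' @param pulse_id Identifier.
#' @param modality `"USP"` or `"ASW"`.
#' @param pulse_energy_mJ Per-pulse energy (mJ).
#' @param time_us,A_PB_mm2,A_SC_mm2 Area time series (equal lengths), e.g.
#'   from [areas_table()].
#' @param t_d_us Inter-pulse delay in microseconds; required for ASW and
#'   must be absent (`NULL`) for USP.
#' @param second_window_us Width of the second-pulse analysis window (us).
#' @return A list of class `pulse_record`.
#' @export
pulse_record <- function(pulse_id, modality = c("USP", "ASW"),
                         pulse_energy_mJ, time_us, A_PB_mm2, A_SC_mm2,
                         t_d_us = NULL, second_window_us = 200) {
  modality <- match.arg(modality)
  if (modality == "ASW" && is.null(t_d_us)) {
    stop("ASW records require 't_d_us'", call. = FALSE)
  }
  if (modality == "USP" && !is.null(t_d_us)) {
    stop("USP records must not carry 't_d_us'", call. = FALSE)
  }
  n <- length(time_us)
  if (length(A_PB_mm2) != n || length(A_SC_mm2) != n || n == 0) {
    stop("area series and times must have equal, non-zero length",
         call. = FALSE)
  }
  first_end <- if (modality == "ASW") t_d_us else Inf
  in_first <- time_us >= 0 & time_us < first_end
  rec <- list(
    pulse_id = pulse_id,
    modality = modality,
    pulse_energy_mJ = pulse_energy_mJ,
    t_d_us = t_d_us,
    time_us = time_us,
    A_PB_mm2 = A_PB_mm2,
    A_SC_mm2 = A_SC_mm2,
    A_PB_max = if (any(in_first)) max(A_PB_mm2[in_first]) else 0,
    A_SC_max = if (any(in_first)) max(A_SC_mm2[in_first]) else 0,
    A_SC_max_2nd = NA_real_
  )
  if (modality == "ASW") {
    in_second <- time_us >= t_d_us & time_us < t_d_us + second_window_us
    rec$A_SC_max_2nd <- if (any(in_second)) max(A_SC_mm2[in_second]) else 0
  }
  structure(rec, class = "pulse_record")
}

#' Windowed maxima of the area time series
#'
#' For each half-open window `[t_start, t_end)` returns the maximum of the
#' PB and SC area series over frames falling in the window; a window
#' containing no frames yields 0.
#'
#' @param result A [segment_sequence()] result (or any list with `time_us`,
#'   `A_PB_mm2`, `A_SC_mm2`).
#' @param windows List of length-2 numeric vectors `(t_start, t_end)` in
#'   microseconds; windows must not be inverted.
#' @return Data frame with one row per window: `t_start`, `t_end`,
#'   `A_PB_max`, `A_SC_max`.
#' @export
pulse_maxima <- function(result, windows) {
  if (is.numeric(windows) && length(windows) == 2L) windows <- list(windows)
  t <- result$time_us
  rows <- lapply(windows, function(wd) {
    if (length(wd) != 2L || wd[2] <= wd[1]) {
      stop("windows must be increasing (t_start, t_end) pairs", call. = FALSE)
    }
    sel <- t >= wd[1] & t < wd[2]
    data.frame(
      t_start = wd[1], t_end = wd[2],
      A_PB_max = if (any(sel)) max(result$A_PB_mm2[sel]) else 0,
      A_SC_max = if (any(sel)) max(result$A_SC_mm2[sel]) else 0
    )
  })
  do.call(rbind, rows)
}

maxima_stats <- function(x) {
  list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
       n = length(x))
}

#' Aggregate per-pulse maxima over repeated pulses
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-pulse maxima for each channel. The study reports these averages over
#' N > 30 pulses; a smaller sample triggers a warning but not an error.
#'
#' @param records List of [pulse_record()]s.
#' @param channels Record fields to aggregate.
#' @return Data frame with `channel`, `mean`, `sd`, `n`.
#' @export
aggregate_maxima <- function(records,
                             channels = c("A_PB_max", "A_SC_max")) {
  if (length(records) == 0L) stop("no pulse records", call. = FALSE)
  if (inherits(records, "pulse_record")) records <- list(records)
  if (length(records) <= 30L) {
    warning(sprintf("only %d pulses; reported averages use N > 30",
                    length(records)), call. = FALSE)
  }
  rows <- lapply(channels, function(ch) {
    x <- vapply(records, function(r) r[[ch]], numeric(1))
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop(sprintf("channel '%s' has no values", ch),
                              call. = FALSE)
    s <- maxima_stats(x)
    data.frame(channel = ch, mean = s$mean, sd = s$sd, n = s$n)
  })
  do.call(rbind, rows)
}

#' Delay-sweep curve of second-pulse secondary cavitation
#'
#' Groups dual-pulse (ASW) records by inter-pulse delay, aggregates
#' `A_SC_max_2nd` per delay, and locates the optimal delay (the grid point
#' with the largest mean). Records whose delay is off the grid are snapped
#' to the nearest grid point and flagged.
#'
#' @param records List of [pulse_record()]s; at least one must be ASW.
#' @param grid_us Delay grid in microseconds (default 200-650 in steps of
#'   10, see [delay_grid()]).
#' @return A list of class `sweep_curve`: `table` (data frame `t_d_us`,
#'   `mean`, `sd`, `n`, `n_snapped`) and `optimal_delay_us`.
#' @export
sweep_curve <- function(records, grid_us = delay_grid()) {
  if (inherits(records, "pulse_record")) records <- list(records)
  asw <- Filter(function(r) r$modality == "ASW", records)
  if (length(asw) == 0L) stop("no ASW records", call. = FALSE)
  td <- vapply(asw, function(r) r$t_d_us, numeric(1))
  snapped <- vapply(td, function(x) grid_us[which.min(abs(grid_us - x))],
                    numeric(1))
  n_snapped <- sum(snapped != td)
  if (n_snapped > 0) {
    warning(sprintf("%d record(s) off the delay grid were snapped",
                    n_snapped), call. = FALSE)
  }
  vals <- vapply(asw, function(r) r$A_SC_max_2nd, numeric(1))
  groups <- sort(unique(snapped))
  tab <- do.call(rbind, lapply(groups, function(g) {
    s <- maxima_stats(vals[snapped == g])
    data.frame(t_d_us = g, mean = s$mean, sd = s$sd, n = s$n)
  }))
  structure(list(
    table = tab,
    optimal_delay_us = tab$t_d_us[which.max(tab$mean)],
    n_snapped = n_snapped
  ), class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf(
    "sweep_curve: %d delays, optimal t_d = %g us (mean A_SC 2nd pulse = %.3g mm^2)\n",
    nrow(x$table), x$optimal_delay_us, max(x$table$mean)))
  invisible(x)
}
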