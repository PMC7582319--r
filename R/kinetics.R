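# Kinetic peak detection, measurement windows, acquisition planning.

#' Locate the kinetic peak of a luminescence trace
#'
#' Smooths the trace with a centered moving average (windows shrink at the
#' boundaries) and returns the argmax of the smoothed values. Ties are
#' broken in favor of the earliest time; a maximum at either end of the
#' series is flagged as a boundary peak (the true peak may lie outside the
#' measured range).
#'
#' @param trace A `wcb_trace` / data frame with columns `time_h`, `rlu`, or
#'   a numeric vector of values (then supply `times_h`).
#' @param smooth_window Odd moving-average width in samples (default 3).
#' @param times_h Times when `trace` is a bare numeric vector.
#' @return List: `peak_time_h`, `peak_value` (smoothed RLU at the peak),
#'   `index`, `boundary` (logical).
#' @export
find_peak <- function(trace, smooth_window = 3, times_h = NULL) {
  if (is.data.frame(trace)) {
    times_h <- trace$time_h
    values <- trace$rlu
  } else values <- trace
  n <- length(values)
  stopifnot(length(times_h) == n)
  if (n < 3) stop("need at least 3 points for peak detection")
  if (smooth_window %% 2 != 1) stop("smooth_window must be odd")
  if (smooth_window > n) stop("smooth_window exceeds series length")
  sm <- smooth_trace(values, smooth_window)
  idx <- which.max(sm)  # which.max takes the first (earliest) maximum
  list(peak_time_h = times_h[idx], peak_value = sm[idx], index = idx,
       boundary = idx %in% c(1L, n))
}

#' Centered moving average with shrinking boundary windows
#'
#' @param values Numeric vector.
#' @param window Odd window width.
#' @return Smoothed vector of the same length.
#' @export
smooth_trace <- function(values, window = 3) {
  stopifnot(window %% 2 == 1, window >= 1)
  h <- (window - 1) %/% 2
  n <- length(values)
  vapply(seq_len(n), function(i)
    mean(values[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Measurement window around a kinetic peak
#'
#' The smartphone measuring interval is the peak time +/- 1000 s, with the
#' start clamped at zero. Internal bounds are exact; the reported bounds
#' (`start_report_h`, `end_report_h`) are truncated to 0.1 h, matching how
#' such intervals are conventionally quoted.
#'
#' @param peak_time_h Peak time, hours (>= 0).
#' @param half_width_s Half-width of the window, seconds (default 1000).
#' @return List (class `wcb_window`): `center_h`, `start_h`, `end_h`
#'   (exact), `start_report_h`, `end_report_h` (0.1 h), `half_width_s`,
#'   `clamped`.
#' @examples
#' measurement_window(2.5)$start_report_h  # 2.2
#' measurement_window(2.3)$start_report_h  # 2.0
#' @export
measurement_window <- function(peak_time_h, half_width_s = 1000) {
  if (peak_time_h < 0) stop("peak time must be non-negative")
  hw_h <- half_width_s / 3600
  start <- max(0, peak_time_h - hw_h)
  end <- peak_time_h + hw_h
  structure(list(center_h = peak_time_h, start_h = start, end_h = end,
                 start_report_h = floor(start * 10) / 10,
                 end_report_h = floor(end * 10) / 10,
                 half_width_s = half_width_s,
                 clamped = peak_time_h < hw_h),
            class = "wcb_window")
}

#' @export
print.wcb_window <- function(x, ...) {
  cat(sprintf("<wcb_window> %.1f h to %.1f h (center %.2f h, +/- %d s)%s\n",
              x$start_report_h, x$end_report_h, x$center_h,
              round(x$half_width_s), if (x$clamped) " [clamped at 0]" else ""))
  invisible(x)
}

#' Explicit measurement window from stated bounds
#'
#' For strains whose published interval does not follow the +/- 1000 s rule
#' (e.g. the oxidant reporter, quoted as 0.3 h to 0.8 h).
#'
#' @param start_h,end_h Window bounds, hours (`start_h < end_h`).
#' @return A `wcb_window`.
#' @export
window_override <- function(start_h, end_h) {
  stopifnot(start_h >= 0, start_h < end_h)
  structure(list(center_h = (start_h + end_h) / 2, start_h = start_h,
                 end_h = end_h,
                 start_report_h = floor(start_h * 10) / 10,
                 end_report_h = floor(end_h * 10) / 10,
                 half_width_s = (end_h - start_h) * 3600 / 2,
                 clamped = FALSE),
            class = "wcb_window")
}

#' Plan the frames of an intervalometer acquisition
#'
#' After the shutter delay, frames repeat every
#' `integration_s + frame_interval_s` seconds for as long as a whole frame
#' fits in the measuring time:
#' `n = floor((measuring_time_s - shutter_delay_s) /
#' (integration_s + frame_interval_s))`. The published schedule
#' (2000 s, 3 s delay, 32 s integration, 1 s interval) yields 60 frames.
#'
#' @param schedule An [acquisition_schedule()].
#' @return List: `n_frames`, `start_times_s` (frame start offsets from the
#'   beginning of the measuring window; empty when the window is too short).
#' @examples
#' plan_acquisition(acquisition_schedule())$n_frames  # 60
#' @export
plan_acquisition <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  cycle <- schedule$integration_s + schedule$frame_interval_s
  n <- floor((schedule$measuring_time_s - schedule$shutter_delay_s) / cycle)
  n <- max(0L, as.integer(n))
  starts <- if (n > 0) schedule$shutter_delay_s + (seq_len(n) - 1) * cycle
            else numeric(0)
  list(n_frames = n, start_times_s = starts)
}

#' Mean signal over the measurement window
#'
#' Arithmetic mean of the per-frame net intensities whose frame start times
#' fall inside the window (frames belong to the window by their start time,
#' matching intervalometer semantics). This window mean is the final signal
#' readout for smartphone and CMOS measurements.
#'
#' @param net_intensities Per-frame net intensities.
#' @param times_h Frame start times, hours (absolute incubation time).
#' @param window A `wcb_window`.
#' @return Mean readout.
#' @export
window_mean_signal <- function(net_intensities, times_h, window) {
  stopifnot(length(net_intensities) == length(times_h),
            inherits(window, "wcb_window"))
  inside <- times_h >= window$start_h & times_h <= window$end_h
  if (!any(inside)) stop("no frames fall inside the measurement window")
  mean(net_intensities[inside])
}
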