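# Forward simulators: kinetic traces, smartphone frame stacks, CMOS streams.

# Logical mask (height x width matrix) of pixels whose centers fall within
# `radius` of (center_row, center_col); coordinates 0-based.
.disk_mask <- function(height, width, center_row, center_col, radius) {
  d2 <- outer((seq_len(height) - 1 - center_row)^2,
              (seq_len(width) - 1 - center_col)^2, "+")
  d2 <= radius^2
}

#' Simulate a kinetic luminescence trace
#'
#' Evaluates the noiseless kinetic model `baseline + induction * amplitude *
#' shape(t)` on the supplied time grid and applies multiplicative Gaussian
#' noise with coefficient of variation `noise_cv`. Negative noisy values are
#' clamped to zero (luminescence is non-negative).
#'
#' @param profile A [kinetic_profile()].
#' @param times_h Strictly increasing times, hours.
#' @param induction Induction factor (> 0) scaling the peak amplitude.
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param seed Integer seed; identical seeds give identical traces. `NULL`
#'   leaves the RNG state untouched.
#' @return A data frame (classes `wcb_trace`, `data.frame`) with columns
#'   `time_h` and `rlu`.
#' @examples
#' tv <- strain_library("TV1061")$profile
#' tr <- simulate_kinetic_trace(tv, seq(0, 6, by = 0.01))
#' tr$time_h[which.max(tr$rlu)]  # 2.5
#' @export
simulate_kinetic_trace <- function(profile, times_h, induction = 1,
                                   noise_cv = 0, seed = 0) {
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times_h must be strictly increasing")
  if (induction <= 0) stop("induction must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  v <- kinetic_value(profile, times_h, induction)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- pmax(0, v * (1 + noise_cv * stats::rnorm(length(v))))
  }
  structure(data.frame(time_h = times_h, rlu = v),
            class = c("wcb_trace", "data.frame"))
}

new_frame <- function(pixels, timestamp_s, bit_depth) {
  structure(list(pixels = pixels, timestamp_s = timestamp_s,
                 bit_depth = as.integer(bit_depth)),
            class = "wcb_frame")
}

#' @export
print.wcb_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<wcb_frame> %dx%d RGB, %d-bit, t = %.1f s\n",
              d[1], d[2], x$bit_depth, x$timestamp_s))
  invisible(x)
}

#' Render one RGB frame of glowing disks
#'
#' Expected counts inside disk i are `dark_level + gain * radiance_i *
#' exposure_s` in the green and blue channels; the red channel carries only
#' dark level and noise (lux emission is blue-green). Poisson shot noise is
#' applied to expected counts, then Gaussian read noise; noisy frames are
#' rounded to integer counts. All values are clipped to
#' `[0, 2^bit_depth - 1]`.
#'
#' @param layout A [disk_layout()].
#' @param disk_radiance One radiance (RLU) per disk.
#' @param exposure_s Exposure (integration) time, seconds (> 0).
#' @param sensor A [sensor_model()].
#' @param seed Integer seed (`NULL` to leave the RNG state alone).
#' @param timestamp_s Timestamp recorded on the frame, seconds.
#' @return A `wcb_frame` with a `height x width x 3` pixel array.
#' @export
render_frame <- function(layout, disk_radiance, exposure_s, sensor,
                         seed = 0, timestamp_s = 0) {
  stopifnot(inherits(layout, "disk_layout"), inherits(sensor, "sensor_model"),
            exposure_s > 0)
  if (length(disk_radiance) != n_disks(layout))
    stop("disk_radiance must have one value per disk in the layout")
  h <- layout$height; w <- layout$width
  px <- array(sensor$dark_level, dim = c(h, w, 3))
  for (i in seq_len(n_disks(layout))) {
    d <- layout$disks[i, ]
    m <- .disk_mask(h, w, d$center_row, d$center_col, d$radius)
    for (ch in 2:3) {
      plane <- px[, , ch]
      plane[m] <- plane[m] + sensor$gain_rgb[ch] * disk_radiance[i] * exposure_s
      px[, , ch] <- plane
    }
  }
  noisy <- sensor$shot_noise || sensor$read_noise_sd > 0
  if (noisy) {
    if (!is.null(seed)) set.seed(seed)
    if (sensor$shot_noise) px[] <- stats::rpois(length(px), px)
    if (sensor$read_noise_sd > 0)
      px[] <- px + stats::rnorm(length(px), sd = sensor$read_noise_sd)
    px[] <- round(px)
  }
  px[] <- pmin(pmax(px, 0), sensor$saturation)
  new_frame(px, timestamp_s, sensor$bit_depth)
}

#' Simulate a smartphone acquisition around the kinetic peak
#'
#' Plans frames with [plan_acquisition()], centers the measuring window at
#' `window_center_h`, evaluates each disk's kinetic radiance at each frame's
#' start timestamp, and renders every frame with [render_frame()]. One
#' kinetic profile and one induction factor apply per disk; inductions can
#' be given directly or taken from a [dose_response_spec()] (entry i maps to
#' disk i).
#'
#' @param schedule An [acquisition_schedule()].
#' @param profiles A single [kinetic_profile()] (recycled) or a list with
#'   one profile per disk.
#' @param layout A [disk_layout()].
#' @param sensor A [sensor_model()].
#' @param window_center_h Center of the measuring window, hours.
#' @param inductions Induction factor per disk; alternatively pass
#'   `dose_spec`.
#' @param dose_spec Optional [dose_response_spec()] whose entries (in order)
#'   give the per-disk inductions; its length must match the layout.
#' @param noise_cv Trace-level multiplicative noise CV applied to each
#'   frame's radiances (>= 0).
#' @param seed Integer seed for all noise in the acquisition.
#' @return A list (class `wcb_acquisition`) with `frames` (list of
#'   `wcb_frame`), `timestamps_s`, `layout`, and `truth` (inductions and the
#'   noiseless radiance matrix, frames x disks).
#' @export
simulate_acquisition <- function(schedule, profiles, layout, sensor,
                                 window_center_h, inductions = NULL,
                                 dose_spec = NULL, noise_cv = 0, seed = 0) {
  stopifnot(inherits(schedule, "acquisition_schedule"),
            inherits(layout, "disk_layout"))
  nd <- n_disks(layout)
  if (!is.null(dose_spec)) {
    stopifnot(inherits(dose_spec, "dose_response_spec"))
    inductions <- dose_spec$entries$induction_factor
  }
  if (is.null(inductions)) inductions <- rep(1, nd)
  if (length(inductions) != nd)
    stop("need one induction factor per disk (", nd, " disks, got ",
         length(inductions), ")")
  if (inherits(profiles, "kinetic_profile")) profiles <- rep(list(profiles), nd)
  stopifnot(length(profiles) == nd)
  plan <- plan_acquisition(schedule)
  if (plan$n_frames < 1)
    stop("acquisition schedule yields zero frames")
  t0_s <- window_center_h * 3600 - schedule$measuring_time_s / 2
  times_s <- t0_s + plan$start_times_s
  rad <- sapply(seq_len(nd), function(i)
    kinetic_value(profiles[[i]], times_s / 3600, inductions[i]))
  rad <- matrix(rad, nrow = plan$n_frames, ncol = nd)
  if (!is.null(seed)) set.seed(seed)
  rad_noisy <- rad
  if (noise_cv > 0)
    rad_noisy[] <- pmax(0, rad * (1 + noise_cv * stats::rnorm(length(rad))))
  frames <- lapply(seq_len(plan$n_frames), function(k)
    render_frame(layout, rad_noisy[k, ], schedule$integration_s, sensor,
                 seed = NULL, timestamp_s = times_s[k]))
  structure(list(frames = frames, timestamps_s = times_s, layout = layout,
                 schedule = schedule,
                 truth = list(inductions = inductions, radiance = rad)),
            class = "wcb_acquisition")
}

#' Simulate a multi-channel CMOS record stream
#'
#' Emits one 24x24-pixel record per channel every `period_s` seconds. The
#' expected pixel value of channel c at stream time t is
#' `background(T(t)) + gain * radiance_c(t) * integration_s`, where the
#' background is a known temperature-to-counts curve (the simulation ground
#' truth that [fit_background_curve()] must recover). Kinetics are evaluated
#' at `start_h + t/3600` hours; measurements conventionally start after 2 h
#' of incubation.
#'
#' @param duration_s Stream duration, seconds.
#' @param period_s Sampling period, seconds (> 0).
#' @param temperature_profile Either a single temperature (degrees C) or a
#'   function of stream time in seconds.
#' @param profiles List of [kinetic_profile()] (one per channel) or a single
#'   profile recycled; use amplitude 0 for dark channels.
#' @param background_truth A [background_curve()] or a numeric coefficient
#'   vector `(c0, c1, c2)` of the true temperature-to-counts polynomial.
#' @param sensor A [sensor_model()]; its green-channel gain is used (the
#'   CMOS sensor is monochrome), plus `read_noise_sd`/`shot_noise`.
#' @param inductions Induction factor per channel.
#' @param channels Number of channels (default 4, ids 0-3).
#' @param integration_s Integration time per record, seconds.
#' @param start_h Incubation time at stream start, hours.
#' @param seed Integer seed.
#' @return List of `cmos_record` objects, time-ordered.
#' @export
simulate_cmos_records <- function(duration_s, period_s, temperature_profile,
                                  profiles, background_truth, sensor,
                                  inductions = NULL, channels = 4L,
                                  integration_s = 1, start_h = 2, seed = 0) {
  stopifnot(period_s > 0, duration_s >= 0, channels >= 1,
            inherits(sensor, "sensor_model"))
  if (inherits(profiles, "kinetic_profile"))
    profiles <- rep(list(profiles), channels)
  stopifnot(length(profiles) == channels)
  if (is.null(inductions)) inductions <- rep(1, channels)
  stopifnot(length(inductions) == channels)
  if (is.numeric(background_truth))
    background_truth <- background_curve(background_truth)
  temp_fun <- if (is.function(temperature_profile)) temperature_profile
              else function(t) rep(temperature_profile, length(t))
  gain <- sensor$gain_rgb[2]
  times <- seq(0, duration_s, by = period_s)
  if (!is.null(seed)) set.seed(seed)
  noisy <- sensor$shot_noise || sensor$read_noise_sd > 0
  records <- vector("list", length(times) * channels)
  k <- 0L
  for (t in times) {
    temp <- temp_fun(t)
    bg <- predict(background_truth, temp)
    for (ch in seq_len(channels) - 1L) {
      sig <- kinetic_value(profiles[[ch + 1L]], start_h + t / 3600,
                           inductions[ch + 1L]) -
             profiles[[ch + 1L]]$baseline_rlu
      expected <- bg + gain * sig * integration_s
      px <- matrix(expected, 24, 24)
      if (noisy) {
        if (sensor$shot_noise) px[] <- stats::rpois(576, px)
        if (sensor$read_noise_sd > 0)
          px[] <- px + stats::rnorm(576, sd = sensor$read_noise_sd)
        px[] <- round(px)
      }
      px[] <- pmin(pmax(px, 0), sensor$saturation)
      k <- k + 1L
      records[[k]] <- cmos_record(t, temp, ch, px)
    }
  }
  records
}
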