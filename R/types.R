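#' Kinetic profile of a bioluminescent reporter strain
#'
#' Parametric single-peak luminescence kinetics: an asymmetric Gaussian in
#' time with separate rise and decay widths, sitting on a constant baseline.
#' The noiseless trace attains its maximum exactly at `peak_time_h` and
#' relaxes to `baseline_rlu` far from the peak.
#'
#' @param peak_time_h Time of the luminescence peak, hours (> 0).
#' @param peak_amplitude_rlu Amplitude added above baseline at the peak, in
#'   relative light units (RLU, >= 0). A dose-dependent induction factor
#'   multiplies this amplitude.
#' @param baseline_rlu Constant basal luminescence, RLU (>= 0). Default 0:
#'   basal glow is treated as part of the detector background so that
#'   induction ratios of background-subtracted readouts equal the
#'   ground-truth induction (see the methods vignette).
#' @param sigma_rise_h,sigma_decay_h Gaussian widths (hours, > 0) of the
#'   rising and decaying flank.
#' @param strain Optional strain label carried through reports.
#' @return An object of class `kinetic_profile`.
#' @examples
#' p <- kinetic_profile(peak_time_h = 2.5)
#' kinetic_value(p, c(0, 2.5, 6))
#' @export
kinetic_profile <- function(peak_time_h, peak_amplitude_rlu = 2000,
                            baseline_rlu = 0, sigma_rise_h = 0.7,
                            sigma_decay_h = 1.0, strain = NULL) {
  stopifnot(is.numeric(peak_time_h), length(peak_time_h) == 1L, peak_time_h > 0,
            peak_amplitude_rlu >= 0, baseline_rlu >= 0,
            sigma_rise_h > 0, sigma_decay_h > 0)
  structure(list(baseline_rlu = baseline_rlu,
                 peak_time_h = peak_time_h,
                 peak_amplitude_rlu = peak_amplitude_rlu,
                 sigma_rise_h = sigma_rise_h,
                 sigma_decay_h = sigma_decay_h,
                 strain = strain),
            class = "kinetic_profile")
}

#' Evaluate the noiseless kinetic model
#'
#' @param profile A [kinetic_profile()].
#' @param times_h Numeric vector of times in hours.
#' @param induction Induction factor multiplying the peak amplitude (> 0).
#' @return RLU values, same length as `times_h`.
#' @export
kinetic_value <- function(profile, times_h, induction = 1) {
  stopifnot(inherits(profile, "kinetic_profile"), induction > 0)
  dt <- times_h - profile$peak_time_h
  sigma <- ifelse(dt <= 0, profile$sigma_rise_h, profile$sigma_decay_h)
  shape <- exp(-dt^2 / (2 * sigma^2))
  profile$baseline_rlu + induction * profile$peak_amplitude_rlu * shape
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat(sprintf("<kinetic_profile%s> peak %.2f h, amplitude %.4g RLU, baseline %.4g RLU, sigmas (%.2f, %.2f) h\n",
              if (is.null(x$strain)) "" else paste0(" ", x$strain),
              x$peak_time_h, x$peak_amplitude_rlu, x$baseline_rlu,
              x$sigma_rise_h, x$sigma_decay_h))
  invisible(x)
}

#' Dose-response specification (ground truth for simulation)
#'
#' Describes one strain/toxicant/detector combination as a table of toxicant
#' concentrations (% v/v) and the induction factor each elicits. The control
#' (concentration 0) always has induction factor 1.
#'
#' @param strain,toxicant Labels.
#' @param detector One of `"plate-reader"`, `"smartphone"`, `"cmos"`.
#' @param concentration Strictly increasing concentrations, % v/v (>= 0).
#' @param induction_factor Induction factor per concentration (> 0); an
#'   entry at concentration 0 must have factor 1.
#' @return An object of class `dose_response_spec`.
#' @export
dose_response_spec <- function(strain, toxicant, detector, concentration,
                               induction_factor) {
  detector <- match.arg(detector, c("plate-reader", "smartphone", "cmos"))
  stopifnot(length(concentration) == length(induction_factor),
            all(concentration >= 0), all(induction_factor > 0))
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(concentration == 0 & induction_factor != 1))
    stop("the control entry (concentration 0) must have induction factor 1")
  structure(list(strain = strain, toxicant = toxicant, detector = detector,
                 entries = data.frame(concentration = concentration,
                                      induction_factor = induction_factor)),
            class = "dose_response_spec")
}

#' @export
print.dose_response_spec <- function(x, ...) {
  cat(sprintf("<dose_response_spec> %s / %s (%s)\n", x$strain, x$toxicant,
              x$detector))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Detector sensor model
#'
#' Photometric forward model shared by the smartphone and CMOS simulators:
#' expected counts are `dark_level + gain * radiance * exposure`, optionally
#' followed by Poisson shot noise, additive Gaussian read noise, rounding to
#' integer counts, and clipping to the bit depth. Rounding is applied only
#' when some noise source is active, so noiseless renders stay exactly
#' linear in radiance.
#'
#' @param bit_depth 8 or 16.
#' @param gain Counts per RLU per second; either a scalar (applied to the
#'   green and blue channels) or a length-3 `(R, G, B)` triple. Bacterial lux
#'   emission is blue-green, so the red channel never carries signal.
#' @param dark_level Constant dark offset, counts (>= 0).
#' @param read_noise_sd Gaussian read noise SD, counts (>= 0).
#' @param shot_noise Logical; apply Poisson noise to expected counts.
#' @param dark_current_per_degC_per_s Temperature coefficient of the dark
#'   signal (counts per degree C per second); used by the CMOS stream
#'   simulator only.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(bit_depth = 16, gain = 1, dark_level = 0,
                         read_noise_sd = 0, shot_noise = TRUE,
                         dark_current_per_degC_per_s = 0) {
  stopifnot(bit_depth %in% c(8L, 16L), all(gain >= 0),
            length(gain) %in% c(1L, 3L), dark_level >= 0, read_noise_sd >= 0,
            is.logical(shot_noise))
  gain_rgb <- if (length(gain) == 3L) as.numeric(gain) else c(0, gain, gain)
  structure(list(bit_depth = as.integer(bit_depth), gain_rgb = gain_rgb,
                 dark_level = dark_level, read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise,
                 dark_current_per_degC_per_s = dark_current_per_degC_per_s,
                 saturation = 2^bit_depth - 1),
            class = "sensor_model")
}

# mean G/B gain: the scale factor surviving the green-blue channel merge
merged_gain <- function(sensor) mean(sensor$gain_rgb[2:3])

#' Layout of filter-membrane disks in the image plane
#'
#' Pixel coordinates are 0-based, row-major, origin at the top-left pixel
#' center. A pixel belongs to a disk when its center lies within `radius` of
#' the disk center. Disks must lie fully inside the image and must not
#' overlap.
#'
#' @param height,width Image size in pixels.
#' @param center_row,center_col,radius Equal-length numeric vectors, one
#'   entry per disk.
#' @return An object of class `disk_layout`.
#' @export
disk_layout <- function(height, width, center_row, center_col, radius) {
  stopifnot(height >= 1, width >= 1,
            length(center_row) == length(center_col),
            length(center_row) == length(radius), all(radius > 0))
  if (any(center_row - radius < 0 | center_row + radius > height - 1 |
          center_col - radius < 0 | center_col + radius > width - 1))
    stop("every disk must lie fully inside the image bounds")
  n <- length(radius)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((center_row[i] - center_row[j])^2 +
                (center_col[i] - center_col[j])^2)
      if (d <= radius[i] + radius[j]) stop("disks must not overlap")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 disks = data.frame(center_row = center_row,
                                    center_col = center_col,
                                    radius = radius)),
            class = "disk_layout")
}

#' Regular grid of disks
#'
#' Convenience constructor placing `nrow * ncol` equally spaced disks.
#'
#' @param nrow,ncol Grid dimensions.
#' @param height,width Image size (pixels).
#' @param radius Disk radius (pixels); default 20 on a 480x640 frame.
#' @return A [disk_layout()].
#' @export
grid_layout <- function(nrow = 1, ncol = 3, height = 480, width = 640,
                        radius = 20) {
  rows <- (seq_len(nrow) - 0.5) / nrow * (height - 1)
  cols <- (seq_len(ncol) - 0.5) / ncol * (width - 1)
  g <- expand.grid(center_col = cols, center_row = rows)  # row-major order
  disk_layout(height, width, g$center_row, g$center_col,
              rep(radius, nrow(g)))
}

#' Number of disks in a layout
#' @param layout A [disk_layout()].
#' @return Integer disk count.
#' @export
n_disks <- function(layout) nrow(layout$disks)

#' Smartphone intervalometer acquisition schedule
#'
#' Defaults reproduce the published acquisition: 2000 s of measuring time, a
#' 3 s shutter delay, 32 s integration per frame and a 1 s frame interval,
#' which yields 60 frames (see [plan_acquisition()]).
#'
#' @param measuring_time_s,shutter_delay_s,integration_s,frame_interval_s
#'   Schedule parameters in seconds; all >= 0, integration > 0.
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(measuring_time_s = 2000, shutter_delay_s = 3,
                                 integration_s = 32, frame_interval_s = 1) {
  stopifnot(measuring_time_s >= 0, shutter_delay_s >= 0, integration_s > 0,
            frame_interval_s >= 0)
  structure(list(measuring_time_s = measuring_time_s,
                 shutter_delay_s = shutter_delay_s,
                 integration_s = integration_s,
                 frame_interval_s = frame_interval_s),
            class = "acquisition_schedule")
}

#' Bundled reporter strain library
#'
#' Default kinetic profiles and dose-response tables for the four E. coli
#' bioreporter strains: TV1061 and grpE::lux (cytotoxicants, ethanol),
#' DPD2794 (genotoxicants, chloroform) and soxS::lux (oxidants, hydrogen
#' peroxide). Peak times and induction factors are the published plate-reader
#' and smartphone values; they serve as simulation ground truth. soxS::lux
#' carries an explicit measurement-window override (0.3-0.8 h) instead of the
#' peak +/- 1000 s rule.
#'
#' @param strain One of `"TV1061"`, `"grpE"`, `"DPD2794"`, `"soxS"`.
#' @return A list with elements `profile` ([kinetic_profile()]), `doses`
#'   (named list of [dose_response_spec()] per detector) and optionally
#'   `window_override_h` (length-2 numeric, hours).
#' @export
strain_library <- function(strain = c("TV1061", "grpE", "DPD2794", "soxS")) {
  strain <- match.arg(strain)
  switch(strain,
    TV1061 = list(
      profile = kinetic_profile(peak_time_h = 2.5, sigma_rise_h = 0.7,
                                sigma_decay_h = 1.0, strain = "TV1061"),
      doses = list(
        `plate-reader` = dose_response_spec("TV1061", "ethanol", "plate-reader",
                                            c(1, 2, 3, 4, 5),
                                            c(30, 56, 114, 265, 366)),
        smartphone = dose_response_spec("TV1061", "ethanol", "smartphone",
                                        c(1, 2, 5), c(2.1, 3.1, 7.6)),
        cmos = dose_response_spec("TV1061", "ethanol", "cmos", 2, 2.0))),
    grpE = list(
      profile = kinetic_profile(peak_time_h = 2.3, sigma_rise_h = 0.7,
                                sigma_decay_h = 1.0, strain = "grpE::lux"),
      doses = list(
        `plate-reader` = dose_response_spec("grpE::lux", "ethanol",
                                            "plate-reader", c(1, 2, 3, 5),
                                            c(3.7, 8.5, 28.5, 38.5)),
        smartphone = dose_response_spec("grpE::lux", "ethanol", "smartphone",
                                        c(1, 2, 5), c(1.4, 1.7, 2.0)))),
    DPD2794 = list(
      profile = kinetic_profile(peak_time_h = 0.3, sigma_rise_h = 0.15,
                                sigma_decay_h = 0.3, strain = "DPD2794"),
      doses = list(
        `plate-reader` = dose_response_spec("DPD2794", "chloroform",
                                            "plate-reader",
                                            c(0.02, 0.04, 0.06, 0.15),
                                            c(2.1, 2.3, 5.3, 14.8)),
        smartphone = dose_response_spec("DPD2794", "chloroform", "smartphone",
                                        c(0.02, 0.06, 0.15),
                                        c(1.3, 1.4, 1.4)))),
    soxS = list(
      profile = kinetic_profile(peak_time_h = 0.55, sigma_rise_h = 0.2,
                                sigma_decay_h = 0.35, strain = "soxS::lux"),
      doses = list(
        `plate-reader` = dose_response_spec("soxS::lux", "H2O2",
                                            "plate-reader",
                                            c(0.0006, 0.0012, 0.0018, 0.02),
                                            c(2.4, 4.5, 11.1, 14.3)),
        smartphone = dose_response_spec("soxS::lux", "H2O2", "smartphone",
                                        c(0.0006, 0.0012, 0.0018),
                                        c(1.9, 2.5, 3.4))),
      window_override_h = c(0.3, 0.8)))
}
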