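# End-to-end orchestration: smartphone and CMOS analyses, fixture
# generation, run configuration and provenance.

# run a pipeline stage, tagging any error with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Load a run configuration from YAML
#'
#' Plain-text nested key/value configuration. A `layout` block
#' (`height`, `width`, `disks:` list of `center_row`, `center_col`,
#' `radius`) is converted to a [disk_layout()].
#'
#' @param path YAML file.
#' @return Named list; element `layout` is a `disk_layout` when present.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$layout)) {
    d <- cfg$layout$disks
    cfg$layout <- disk_layout(cfg$layout$height, cfg$layout$width,
                              vapply(d, `[[`, numeric(1), "center_row"),
                              vapply(d, `[[`, numeric(1), "center_col"),
                              vapply(d, `[[`, numeric(1), "radius"))
  }
  cfg
}

.write_provenance <- function(dir, config, seed) {
  prov <- list(package = "luxdisk",
               version = as.character(utils::packageVersion("luxdisk")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = seed, config = config)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
}

#' Run the smartphone analysis end to end
#'
#' For each condition: read frames, restrict to the measurement window when
#' one is configured, stack by averaging, merge green and blue, detect disk
#' ROIs (snapping to the layout hint when given), measure per-disk mean
#' intensities and subtract the background. Each disk is one replicate; the
#' stacked readout of frames inside the window is the window-mean signal.
#' Per-concentration induction factors are computed against the
#' concentration-0 control, with SNR (n >= 3) and one-way ANOVA + LSD
#' letters across conditions when replication allows. Any stage failure is
#' reported with its stage name.
#'
#' @param config Named list (or [read_run_config()] output) with elements:
#'   `conditions` (list of `list(name, concentration, frames_dir)`, one of
#'   them at concentration 0; a condition may carry an in-memory `frames`
#'   list instead of `frames_dir`), optional `layout` hint ([disk_layout()]),
#'   optional `window` (`wcb_window` or `list(peak_h)`), optional
#'   `background_rect`, optional `strain`, `toxicant`, `output_dir`,
#'   `seed`.
#' @return List: `intensities` (per condition/disk photometry), `readouts`
#'   (condition, concentration, disk, net), `dose_table`
#'   ([dose_response()]), `snr` (per concentration, NA when n < 3),
#'   `anova` (a `wcb_anova_lsd` or NULL), `results` (the summary table
#'   written as `results.csv`).
#' @export
run_smartphone_analysis <- function(config) {
  conds <- .stage("config", {
    stopifnot(length(config$conditions) >= 1)
    config$conditions
  })
  concs <- vapply(conds, function(cc) cc$concentration, numeric(1))
  if (!any(concs == 0))
    .stage("config", stop("missing control condition (concentration 0)"))
  window <- config$window
  if (is.list(window) && !inherits(window, "wcb_window") &&
      !is.null(window$peak_h))
    window <- measurement_window(window$peak_h)
  per_cond <- lapply(conds, function(cc) {
    frames <- .stage("read_frames",
                     if (!is.null(cc[["frames"]])) cc[["frames"]]
                     else read_frames(cc$frames_dir))
    if (!is.null(window)) {
      t_h <- vapply(frames, function(f) f$timestamp_s, numeric(1)) / 3600
      inside <- t_h >= window$start_h & t_h <= window$end_h
      if (!any(inside))
        .stage("window", stop("no frames inside the measurement window"))
      frames <- frames[inside]
    }
    stacked <- .stage("stack", stack_frames(frames))
    merged <- .stage("merge", merge_green_blue(stacked))
    rois <- .stage("detect", {
      r <- detect_disks(merged, hint = config$layout)
      if (nrow(r) == 0) stop("no disks detected")
      r
    })
    tab <- .stage("measure", measure_disks(merged, rois,
                                           background_rect = config$background_rect))
    tab$condition <- cc$name
    tab$concentration <- cc$concentration
    tab
  })
  intensities <- do.call(rbind, per_cond)
  readouts <- intensities[, c("condition", "concentration", "disk_id", "net")]
  control <- readouts$net[readouts$concentration == 0]
  treated <- readouts[readouts$concentration > 0,
                      c("concentration", "net")]
  names(treated) <- c("concentration", "readout")
  dose_table <- .stage("dose_response", dose_response(treated, control))
  snr <- vapply(dose_table$concentration, function(conc) {
    f <- if (conc == 0) control / mean(control)
         else treated$readout[treated$concentration == conc] / mean(control)
    if (length(f) >= 3 && stats::sd(f) > 0) signal_noise_ratio(f)
    else NA_real_
  }, numeric(1))
  groups <- split(readouts$net, readouts$concentration)
  anova <- if (length(groups) >= 3 && all(lengths(groups) >= 2))
    .stage("anova_lsd", anova_lsd(groups)) else NULL
  results <- data.frame(
    strain = if (is.null(config$strain)) NA_character_ else config$strain,
    toxicant = if (is.null(config$toxicant)) NA_character_ else config$toxicant,
    concentration = dose_table$concentration,
    induction = dose_table$induction, sem = dose_table$sem,
    n = dose_table$n, snr = snr,
    letters = if (is.null(anova)) NA_character_
              else anova$letters[as.character(dose_table$concentration)])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(intensities,
                     file.path(config$output_dir, "intensities.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    .write_provenance(config$output_dir,
                      config[setdiff(names(config), "layout")],
                      config$seed)
  }
  list(intensities = intensities, readouts = readouts,
       dose_table = dose_table, snr = snr, anova = anova, results = results)
}

#' Run the CMOS analysis end to end
#'
#' Parses the record stream and the dark stream, fits the
#' temperature-to-background standard curve from the dark records,
#' calibrates every record, computes the induction factor of the treated
#' channels against the control channels, and reconstructs the composite
#' image at the final timestamp.
#'
#' @param config Named list: `stream` (record file), `dark_stream` (dark
#'   record file), `treated_channels`, `control_channels` (integer vectors,
#'   ids 0-3), optional `degree` (background polynomial degree, default 2),
#'   `output_dir`, `seed`.
#' @return List: `curve`, `series` (calibrated data frame), `induction`,
#'   `composite` (48x48 matrix).
#' @export
run_cmos_analysis <- function(config) {
  records <- .stage("parse", parse_cmos_records(config$stream))
  dark <- .stage("parse_dark", parse_cmos_records(config$dark_stream))
  degree <- if (is.null(config$degree)) 2 else config$degree
  curve <- .stage("fit_background", fit_background_curve(dark, degree))
  series <- .stage("calibrate", calibrate_series(records, curve))
  chans <- vapply(records, function(r) r$channel, integer(1))
  treated <- records[chans %in% config$treated_channels]
  control <- records[chans %in% config$control_channels]
  induction <- .stage("induction", cmos_induction(treated, control, curve))
  ts <- vapply(records, function(r) r$timestamp_s, numeric(1))
  last <- records[ts == max(ts)]
  composite <- .stage("reconstruct", reconstruct_image(last))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(series, file.path(config$output_dir, "calibrated.csv"),
                     row.names = FALSE)
    rng <- max(composite, 1)
    tiff::writeTIFF(composite / rng,
                    file.path(config$output_dir, "composite.tif"),
                    bits.per.sample = 16L)
    .write_provenance(config$output_dir, config, config$seed)
  }
  list(curve = curve, series = series, induction = induction,
       composite = composite)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes frames (plus timestamp sidecars), kinetic trace CSVs, CMOS
#' streams and a ground-truth manifest (`truth.yaml`) for one of the
#' packaged scenarios, using the bundled strain library defaults. Two runs
#' with the same seed produce identical files.
#'
#' Scenarios: `"tv1061_ethanol_smartphone"` (control + 1/2/5 % v/v ethanol,
#' smartphone induction truths 2.1/3.1/7.6, 60 frames per condition),
#' `"grpe_ethanol_smartphone"` (truths 1.4/1.7/2.0), and
#' `"tv1061_ethanol_cmos"` (4-channel stream, treated-channel truth 2.0,
#' plus a dark stream for the background curve).
#'
#' @param scenario Scenario name.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The manifest list, invisibly.
#' @export
generate_fixtures <- function(scenario = c("tv1061_ethanol_smartphone",
                                           "grpe_ethanol_smartphone",
                                           "tv1061_ethanol_cmos"),
                              dir, seed = 0) {
  scenario <- match.arg(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (scenario %in% c("tv1061_ethanol_smartphone",
                      "grpe_ethanol_smartphone")) {
    strain <- if (startsWith(scenario, "tv1061")) "TV1061" else "grpE"
    lib <- strain_library(strain)
    spec <- lib$doses$smartphone
    schedule <- acquisition_schedule()
    layout <- grid_layout(nrow = 1, ncol = 3, height = 160, width = 220,
                          radius = 12)
    sensor <- sensor_model(bit_depth = 16, gain = 0.05, dark_level = 100,
                           read_noise_sd = 2, shot_noise = TRUE)
    conds <- rbind(data.frame(concentration = 0, induction_factor = 1),
                   spec$entries)
    times_h <- seq(0, 6, by = 0.05)
    for (i in seq_len(nrow(conds))) {
      name <- if (conds$concentration[i] == 0) "control"
              else paste0("c", conds$concentration[i])
      acq <- simulate_acquisition(
        schedule, lib$profile, layout, sensor,
        window_center_h = lib$profile$peak_time_h,
        inductions = rep(conds$induction_factor[i], n_disks(layout)),
        noise_cv = 0.02, seed = seed + i)
      write_frames(acq$frames, file.path(dir, paste0("frames_", name)))
      tr <- simulate_kinetic_trace(lib$profile, times_h,
                                   induction = conds$induction_factor[i],
                                   noise_cv = 0.05, seed = seed + 100 + i)
      write_trace_csv(tr, file.path(dir, paste0("trace_", name, ".csv")))
    }
    manifest <- list(
      scenario = scenario, seed = seed, strain = spec$strain,
      toxicant = spec$toxicant, detector = "smartphone",
      peak_time_h = lib$profile$peak_time_h,
      peak_amplitude_rlu = lib$profile$peak_amplitude_rlu,
      conditions = lapply(seq_len(nrow(conds)), function(i) list(
        name = if (conds$concentration[i] == 0) "control"
               else paste0("c", conds$concentration[i]),
        concentration = conds$concentration[i],
        induction_factor = conds$induction_factor[i])),
      schedule = unclass(schedule),
      sensor = list(bit_depth = sensor$bit_depth, gain = 0.05,
                    dark_level = sensor$dark_level,
                    read_noise_sd = sensor$read_noise_sd),
      layout = list(height = layout$height, width = layout$width,
                    disks = lapply(seq_len(n_disks(layout)), function(i)
                      as.list(layout$disks[i, ]))))
  } else {
    lib <- strain_library("TV1061")
    truth_induction <- lib$doses$cmos$entries$induction_factor[1]
    bg_truth <- c(200, 2, 0.05)
    sensor <- sensor_model(bit_depth = 16, gain = 0.2, dark_level = 0,
                           read_noise_sd = 2, shot_noise = TRUE)
    dark_profile <- kinetic_profile(peak_time_h = 1, peak_amplitude_rlu = 0)
    profiles <- list(lib$profile, lib$profile, dark_profile, dark_profile)
    stream <- simulate_cmos_records(
      duration_s = 2000, period_s = 20,
      temperature_profile = function(t) 25 + 5 * t / 2000,
      profiles = profiles, background_truth = bg_truth, sensor = sensor,
      inductions = c(1, truth_induction, 1, 1),
      start_h = lib$profile$peak_time_h - 1000 / 3600, seed = seed + 1)
    write_cmos_records(stream, file.path(dir, "stream.txt"))
    dark <- simulate_cmos_records(
      duration_s = 1000, period_s = 10,
      temperature_profile = function(t) 20 + 12 * t / 1000,
      profiles = dark_profile, background_truth = bg_truth, sensor = sensor,
      seed = seed + 2)
    write_cmos_records(dark, file.path(dir, "dark.txt"))
    manifest <- list(scenario = scenario, seed = seed, strain = "TV1061",
                     toxicant = "ethanol", detector = "cmos",
                     control_channel = 0L, treated_channel = 1L,
                     dark_channels = c(2L, 3L),
                     induction_truth = truth_induction,
                     background_truth = bg_truth,
                     sensor = list(gain = 0.2,
                                   read_noise_sd = sensor$read_noise_sd))
  }
  yaml::write_yaml(manifest, file.path(dir, "truth.yaml"))
  invisible(manifest)
}
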