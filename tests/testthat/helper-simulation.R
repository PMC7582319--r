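# Shared simulation helpers for the test suite. Everything is built in
# code; no stored fixtures.

tv_profile <- function() strain_library("TV1061")$profile

# quiet sensor for exact (noise-free) photometry checks
noiseless_sensor <- function(gain = 0.05, dark = 100, bit_depth = 16)
  sensor_model(bit_depth = bit_depth, gain = gain, dark_level = dark,
               read_noise_sd = 0, shot_noise = FALSE)

# small layout used across pipeline tests: two disks on a 100x160 frame
two_disk_layout <- function()
  grid_layout(nrow = 1, ncol = 2, height = 100, width = 160, radius = 10)

# brute-force circular-ROI mean, written as an explicit per-pixel loop so
# it stays independent of the vectorized implementation
brute_force_disk_mean <- function(image, center_row, center_col, radius) {
  total <- 0; count <- 0
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      if (sqrt((r - 1 - center_row)^2 + (c - 1 - center_col)^2) <= radius) {
        total <- total + image[r, c]
        count <- count + 1
      }
    }
  }
  total / count
}

# simulate one treated + control smartphone run and recover the induction
# factor through the full image pipeline (frames in memory)
recover_induction <- function(truth, noise_cv = 0, sensor = noiseless_sensor(),
                              schedule = acquisition_schedule(200, 3, 32, 1),
                              layout = two_disk_layout(), seed = 0,
                              profile = tv_profile()) {
  readout <- function(inductions, seed_offset) {
    acq <- simulate_acquisition(schedule, profile, layout, sensor,
                                window_center_h = profile$peak_time_h,
                                inductions = inductions,
                                noise_cv = noise_cv,
                                seed = seed + seed_offset)
    stacked <- stack_frames(acq$frames)
    merged <- merge_green_blue(stacked)
    tab <- measure_disks(merged, detect_disks(merged, hint = layout))
    mean(tab$net)
  }
  n <- n_disks(layout)
  readout(rep(truth, n), 0) / readout(rep(1, n), 1000)
}
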