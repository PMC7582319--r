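# Forward simulators: kinetic traces, frame rendering, acquisitions,
# CMOS streams.

test_that("zero-amplitude kinetics give a flat trace at baseline", {
  p <- kinetic_profile(peak_time_h = 2.5, peak_amplitude_rlu = 0,
                       baseline_rlu = 37)
  tr <- simulate_kinetic_trace(p, seq(0, 6, by = 0.5), induction = 14)
  expect_true(all(tr$rlu == 37))
})

test_that("noiseless TV1061 trace peaks at 2.5 h on a dense grid", {
  tr <- simulate_kinetic_trace(tv_profile(), seq(0, 6, by = 0.01))
  expect_equal(tr$time_h[which.max(tr$rlu)], 2.5)
})

test_that("noiseless trace maximum matches the closed-form shape value", {
  p <- kinetic_profile(peak_time_h = 1.7, peak_amplitude_rlu = 820,
                       baseline_rlu = 12, sigma_rise_h = 0.4,
                       sigma_decay_h = 0.9)
  for (ind in c(1, 2.5, 7.6)) {
    tr <- simulate_kinetic_trace(p, seq(0, 5, by = 0.001), induction = ind)
    # closed form: shape = 1 at the peak, so max = baseline + ind * amplitude
    expect_equal(max(tr$rlu), 12 + ind * 820, tolerance = 1e-12)
    # spot-check an off-peak point against a direct formula evaluation
    t0 <- 2.4  # on the decay flank
    expect_equal(tr$rlu[tr$time_h == t0],
                 12 + ind * 820 * exp(-(t0 - 1.7)^2 / (2 * 0.9^2)))
  }
})

test_that("trace preconditions are enforced", {
  p <- tv_profile()
  expect_error(simulate_kinetic_trace(p, c(1, 1, 2)), "strictly increasing")
  expect_error(simulate_kinetic_trace(p, 1:3, induction = -1), "positive")
})

test_that("simulators are deterministic under a fixed seed", {
  p <- tv_profile()
  a <- simulate_kinetic_trace(p, 0:10, noise_cv = 0.1, seed = 42)
  b <- simulate_kinetic_trace(p, 0:10, noise_cv = 0.1, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_kinetic_trace(p, 0:10, noise_cv = 0.1, seed = 43)))

  layout <- two_disk_layout()
  sensor <- sensor_model(gain = 0.1, dark_level = 50, read_noise_sd = 2)
  f1 <- render_frame(layout, c(100, 200), 32, sensor, seed = 7)
  f2 <- render_frame(layout, c(100, 200), 32, sensor, seed = 7)
  expect_identical(f1, f2)
  expect_false(identical(f1$pixels,
                         render_frame(layout, c(100, 200), 32, sensor,
                                      seed = 8)$pixels))
})

test_that("noiseless render is dark level plus gain*radiance*exposure in G/B", {
  layout <- disk_layout(40, 40, 20, 20, 8)
  sensor <- sensor_model(gain = 2, dark_level = 5, read_noise_sd = 0,
                         shot_noise = FALSE)
  f <- render_frame(layout, 10, exposure_s = 32, sensor)
  inside <- f$pixels[20 + 1, 20 + 1, ]
  corner <- f$pixels[1, 1, ]
  expect_equal(inside, c(5, 645, 645))    # 5 + 2 * 10 * 32
  expect_equal(corner, c(5, 5, 5))        # dark frame outside the disk
  # all radiances zero -> constant dark frame everywhere
  dark <- render_frame(layout, 0, 32, sensor)
  expect_true(all(dark$pixels == 5))
})

test_that("rendered noise moments match the Poisson + Gaussian model", {
  # one large disk gives ~1e4 in-disk pixels in a single draw
  layout <- disk_layout(128, 128, 63.5, 63.5, 57)
  sensor <- sensor_model(gain = 2, dark_level = 10, read_noise_sd = 3,
                         shot_noise = TRUE)
  f <- render_frame(layout, 10, exposure_s = 5, sensor, seed = 11)
  m <- f$pixels[, , 2][.mask <- outer((0:127 - 63.5)^2, (0:127 - 63.5)^2,
                                      "+") <= 57^2]
  n <- length(m)
  expect_gt(n, 1e4)
  expected <- 10 + 2 * 10 * 5
  v_model <- expected + 3^2 + 1 / 12       # shot + read + rounding
  expect_lt(abs(mean(m) - expected), 3 * sqrt(v_model / n))
  expect_lt(abs(stats::var(m) - v_model),
            3 * v_model * sqrt(2 / (n - 1)))
})

test_that("acquisition under the published schedule yields 60 timed frames", {
  layout <- disk_layout(20, 20, 10, 10, 3)
  sensor <- noiseless_sensor(gain = 0.01, dark = 10)
  acq <- simulate_acquisition(acquisition_schedule(), tv_profile(), layout,
                              sensor, window_center_h = 2.5)
  expect_length(acq$frames, 60)
  # window centered on the peak: first frame starts at center - 1000 s + delay
  expect_equal(acq$timestamps_s[1], 2.5 * 3600 - 1000 + 3)
  expect_equal(diff(acq$timestamps_s), rep(33, 59))
})

test_that("constant kinetics with noise off give identical frames", {
  layout <- disk_layout(20, 20, 10, 10, 3)
  p <- kinetic_profile(peak_time_h = 1, peak_amplitude_rlu = 0,
                       baseline_rlu = 40)
  acq <- simulate_acquisition(acquisition_schedule(200, 3, 32, 1), p, layout,
                              noiseless_sensor(gain = 0.1, dark = 10), 2.5)
  ref <- acq$frames[[1]]$pixels
  for (f in acq$frames) expect_identical(f$pixels, ref)
})

test_that("acquisition stacks are seed-reproducible", {
  layout <- disk_layout(20, 20, 10, 10, 3)
  sensor <- sensor_model(gain = 0.1, dark_level = 10, read_noise_sd = 1)
  args <- list(acquisition_schedule(150, 3, 32, 1), tv_profile(), layout,
               sensor, 2.5)
  a <- do.call(simulate_acquisition, c(args, list(seed = 5, noise_cv = 0.05)))
  b <- do.call(simulate_acquisition, c(args, list(seed = 5, noise_cv = 0.05)))
  d <- do.call(simulate_acquisition, c(args, list(seed = 6, noise_cv = 0.05)))
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
  expect_false(identical(lapply(a$frames, `[[`, "pixels"),
                         lapply(d$frames, `[[`, "pixels")))
  expect_error(simulate_acquisition(acquisition_schedule(10, 3, 32, 1),
                                    tv_profile(), layout, sensor, 2.5),
               "zero frames")
})

test_that("zero-signal constant-temperature CMOS records equal the truth curve", {
  dark <- kinetic_profile(peak_time_h = 1, peak_amplitude_rlu = 0)
  sensor <- sensor_model(gain = 0.2, read_noise_sd = 0, shot_noise = FALSE)
  recs <- simulate_cmos_records(100, 20, 26, dark, c(150, 3, 0.1), sensor)
  truth <- 150 + 3 * 26 + 0.1 * 26^2
  for (r in recs) expect_true(all(r$pixels == truth))
  ts <- vapply(recs, function(r) r$timestamp_s, numeric(1))
  expect_false(is.unsorted(ts))
})

test_that("noiseless CMOS record means reproduce a quadratic truth curve", {
  p <- tv_profile()
  sensor <- sensor_model(gain = 0.2, read_noise_sd = 0, shot_noise = FALSE)
  cf <- c(200, 2, 0.05)
  recs <- simulate_cmos_records(600, 60, function(t) 24 + 6 * t / 600,
                                p, cf, sensor, inductions = rep(2, 4),
                                integration_s = 1, start_h = 2)
  for (r in recs) {
    sig <- kinetic_value(p, 2 + r$timestamp_s / 3600, 2)
    # per-record mean minus gain*signal evaluates the curve at T exactly
    expect_equal(mean(r$pixels) - 0.2 * sig,
                 cf[1] + cf[2] * r$temperature_C + cf[3] * r$temperature_C^2,
                 tolerance = 1e-12)
  }
})

test_that("non-decreasing induction truths give non-decreasing window means", {
  # dose monotonicity is inherited by noiseless simulated readouts
  spec <- strain_library("TV1061")$doses$smartphone
  readouts <- vapply(c(1, spec$entries$induction_factor), function(ind)
    recover_induction(ind), numeric(1))
  expect_false(is.unsorted(readouts))
})

test_that("strain library carries the published peak times and dose tables", {
  expect_equal(strain_library("TV1061")$profile$peak_time_h, 2.5)
  expect_equal(strain_library("grpE")$profile$peak_time_h, 2.3)
  expect_equal(strain_library("DPD2794")$profile$peak_time_h, 0.3)
  tv <- strain_library("TV1061")$doses
  expect_equal(tv$`plate-reader`$entries$induction_factor,
               c(30, 56, 114, 265, 366))
  expect_equal(tv$smartphone$entries$induction_factor, c(2.1, 3.1, 7.6))
  expect_equal(strain_library("soxS")$window_override_h, c(0.3, 0.8))
})

test_that("layout and dose-spec invariants are enforced", {
  expect_error(disk_layout(50, 50, c(10, 20), c(10, 18), c(8, 8)),
               "overlap")
  expect_error(disk_layout(50, 50, 5, 5, 8), "inside")
  expect_error(dose_response_spec("s", "t", "smartphone", c(2, 1), c(2, 3)),
               "increasing")
  expect_error(dose_response_spec("s", "t", "smartphone", 0, 2), "factor 1")
})
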