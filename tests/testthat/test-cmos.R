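# CMOS record parsing, background standard curve, calibration,
# induction, image reconstruction.

dark_profile <- function() kinetic_profile(peak_time_h = 1,
                                           peak_amplitude_rlu = 0)

quiet_cmos_sensor <- function(gain = 0.2)
  sensor_model(gain = gain, read_noise_sd = 0, shot_noise = FALSE)

test_that("record streams round-trip losslessly through the text format", {
  recs <- simulate_cmos_records(90, 10, function(t) 24 + t / 30,
                                tv_profile(), c(150, 2, 0.01),
                                sensor_model(gain = 0.2, read_noise_sd = 1),
                                channels = 1L, seed = 5)
  expect_length(recs, 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_cmos_records(recs, path)
  back <- parse_cmos_records(path)
  expect_length(back, 10)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$timestamp_s, recs[[i]]$timestamp_s)
    expect_equal(back[[i]]$temperature_C, recs[[i]]$temperature_C)
    expect_equal(back[[i]]$channel, recs[[i]]$channel)
    expect_equal(back[[i]]$pixels, recs[[i]]$pixels)
  }
  expect_equal(parse_cmos_records(text = character(0)), list())
})

test_that("a parsed fixture record carries the written values", {
  line <- paste(c(12.5, 26.75, 2, rep(100, 576)), collapse = ",")
  rec <- parse_cmos_records(text = line)[[1]]
  expect_equal(rec$temperature_C, 26.75)
  expect_equal(rec$timestamp_s, 12.5)
  expect_equal(rec$channel, 2L)
  expect_true(all(rec$pixels == 100))
})

test_that("malformed lines abort the parse with their line numbers", {
  good <- paste(c(1, 25, 0, rep(10, 576)), collapse = ",")
  short <- paste(c(2, 25, 1, rep(10, 100)), collapse = ",")
  alpha <- paste(c(3, "warm", 1, rep(10, 576)), collapse = ",")
  expect_error(parse_cmos_records(text = c(good, short, good, alpha)),
               "2, 4")
  bad_chan <- paste(c(4, 25, 9, rep(10, 576)), collapse = ",")
  expect_error(parse_cmos_records(text = c(good, bad_chan)), "2")
})

test_that("constant dark records fit a constant background curve", {
  recs <- lapply(1:5, function(i)
    cmos_record(i, 20 + i, 0, matrix(111, 24, 24)))
  curve <- fit_background_curve(recs)
  expect_equal(curve$coefficients, c(111, 0, 0), tolerance = 1e-8)
  expect_equal(predict(curve, 23.7), 111, tolerance = 1e-8)
  expect_error(fit_background_curve(recs[1:2]), "3 distinct")
})

test_that("a known quadratic dark curve is recovered from noiseless records", {
  cf <- c(180, 1.5, 0.02)
  recs <- simulate_cmos_records(490, 10, function(t) 18 + t / 35,
                                dark_profile(), cf, quiet_cmos_sensor(),
                                channels = 1L)
  curve <- fit_background_curve(recs)
  expect_equal(curve$coefficients, cf, tolerance = 1e-6)
  expect_lt(curve$residual_sd, 1e-8)
})

test_that("fit residual SD tracks the noise of the per-record means", {
  cf <- c(300, 2, 0)
  sensor <- sensor_model(gain = 0.2, read_noise_sd = 24, shot_noise = FALSE)
  recs <- simulate_cmos_records(490, 10, function(t) 18 + t / 35,
                                dark_profile(), cf, sensor, channels = 1L,
                                seed = 9)
  expect_length(recs, 50)
  curve <- fit_background_curve(recs)
  # per-record scalar is a mean of 576 pixels: its SD is read_noise/24
  sigma_mean <- 24 / 24
  expect_lt(abs(curve$residual_sd - sigma_mean), 0.3 * sigma_mean)
})

test_that("calibration subtracts the predicted background", {
  curve <- background_curve(c(100, 2, 0), range_C = c(20, 30))
  rec <- cmos_record(0, 25, 0, matrix(150, 24, 24))
  expect_equal(calibrate_signal(rec, curve), 0)

  rec2 <- cmos_record(0, 25, 0, matrix(150 + 33, 24, 24))
  expect_equal(calibrate_signal(rec2, curve), 33)

  # additive invariance: same constant added to record and curve offset
  curve3 <- background_curve(c(100 + 7, 2, 0), range_C = c(20, 30))
  rec3 <- cmos_record(0, 25, 0, matrix(150 + 7, 24, 24))
  expect_equal(calibrate_signal(rec3, curve3), 0)

  expect_warning(calibrate_signal(cmos_record(0, 35, 0, matrix(180, 24, 24)),
                                  curve), "extrapolat")
})

test_that("noiseless CMOS induction equals the simulator ground truth", {
  cf <- c(200, 2, 0.05)
  sensor <- quiet_cmos_sensor()
  recs <- simulate_cmos_records(600, 30, function(t) 24 + 4 * t / 600,
                                tv_profile(), cf, sensor, channels = 2L,
                                inductions = c(1, 2),
                                start_h = 2.5 - 1000 / 3600)
  curve <- background_curve(cf)
  chans <- vapply(recs, function(r) r$channel, integer(1))
  ind <- cmos_induction(recs[chans == 1], recs[chans == 0], curve)
  expect_equal(ind, 2, tolerance = 1e-12)

  # treated = control -> exactly 1
  expect_equal(cmos_induction(recs[chans == 0], recs[chans == 0], curve), 1)

  # doubling the gain leaves the factor unchanged
  recs2 <- simulate_cmos_records(600, 30, function(t) 24 + 4 * t / 600,
                                 tv_profile(), cf, quiet_cmos_sensor(0.4),
                                 channels = 2L, inductions = c(1, 2),
                                 start_h = 2.5 - 1000 / 3600)
  chans2 <- vapply(recs2, function(r) r$channel, integer(1))
  expect_equal(cmos_induction(recs2[chans2 == 1], recs2[chans2 == 0], curve),
               2, tolerance = 1e-12)
})

test_that("reconstruction tiles channels row-major and round-trips", {
  recs <- lapply(0:3, function(ch)
    cmos_record(10, 25, ch, matrix(ch + 1, 24, 24)))
  comp <- reconstruct_image(recs)
  expect_equal(dim(comp), c(48, 48))
  expect_true(all(comp[1:24, 1:24] == 1))
  expect_true(all(comp[1:24, 25:48] == 2))
  expect_true(all(comp[25:48, 1:24] == 3))
  expect_true(all(comp[25:48, 25:48] == 4))

  # reconstruct-then-slice returns the original grids exactly
  set.seed(2)
  recs2 <- lapply(0:3, function(ch)
    cmos_record(10, 25, ch, matrix(rpois(576, 50), 24, 24)))
  comp2 <- reconstruct_image(recs2)
  expect_equal(comp2[1:24, 25:48], recs2[[2]]$pixels)
  expect_equal(comp2[25:48, 25:48], recs2[[4]]$pixels)

  expect_warning(single <- reconstruct_image(recs[1]), "missing channel")
  expect_true(all(single[25:48, ] == 0))
  expect_error(reconstruct_image(list(recs[[1]], recs[[1]])), "duplicate")
})
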