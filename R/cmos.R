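# Multi-channel CMOS record stream: parsing, temperature-calibrated dark
# background, signal calibration, induction, image reconstruction.

#' One CMOS record
#'
#' A single readout of the 4-channel ultra-low-light sensor: timestamp,
#' temperature, channel id (0-3) and a 24x24 pixel grid.
#'
#' @param timestamp_s Stream time, seconds.
#' @param temperature_C Sensor temperature, degrees C.
#' @param channel Channel id, integer 0-3.
#' @param pixels 24x24 numeric matrix of counts (>= 0).
#' @return Object of class `cmos_record`.
#' @export
cmos_record <- function(timestamp_s, temperature_C, channel, pixels) {
  stopifnot(length(channel) == 1, channel %in% 0:3,
            is.matrix(pixels), all(dim(pixels) == c(24, 24)),
            all(pixels >= 0))
  structure(list(timestamp_s = timestamp_s, temperature_C = temperature_C,
                 channel = as.integer(channel), pixels = pixels),
            class = "cmos_record")
}

#' @export
print.cmos_record <- function(x, ...) {
  cat(sprintf("<cmos_record> t = %.1f s, %.2f degC, channel %d, mean %.2f counts\n",
              x$timestamp_s, x$temperature_C, x$channel, mean(x$pixels)))
  invisible(x)
}

#' Write CMOS records as line-oriented text
#'
#' One record per line: `timestamp_s,temperature_C,channel,p0,...,p575`
#' (576 pixel counts, row-major).
#'
#' @param records List of `cmos_record`.
#' @param path Output file.
#' @export
write_cmos_records <- function(records, path) {
  lines <- vapply(records, function(r)
    paste(c(r$timestamp_s, r$temperature_C, r$channel,
            as.vector(t(r$pixels))), collapse = ","),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CMOS record stream
#'
#' Reads the line-oriented record format back into `cmos_record` objects in
#' file order. Malformed lines (wrong field count, non-numeric fields,
#' channel out of range) abort the parse with their line numbers listed.
#' Non-decreasing timestamps are verified; violations raise a warning.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of record lines (overrides `path`).
#' @return List of `cmos_record`.
#' @export
parse_cmos_records <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(fields) != 579)
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  bad <- sort(union(bad, which(vapply(vals, anyNA, logical(1)))))
  bad <- sort(union(bad, setdiff(which(!vapply(vals, function(v)
    length(v) == 579 && v[3] %in% 0:3, logical(1))), bad)))
  if (length(bad) > 0)
    stop("malformed CMOS record line(s): ", paste(bad, collapse = ", "))
  records <- lapply(vals, function(v)
    cmos_record(v[1], v[2], v[3], matrix(v[-(1:3)], 24, 24, byrow = TRUE)))
  ts <- vapply(records, function(r) r$timestamp_s, numeric(1))
  if (is.unsorted(ts))
    warning("CMOS record timestamps are not non-decreasing")
  records
}

#' Temperature-to-background standard curve
#'
#' Polynomial (degree <= 2) mapping sensor temperature to the expected dark
#' background in counts, with its valid temperature range and the residual
#' SD of the fit. Construct directly from known coefficients or fit from
#' dark records with [fit_background_curve()].
#'
#' @param coefficients Numeric `(c0, c1, c2)`; shorter vectors are padded
#'   with zeros.
#' @param range_C Valid temperature range, degrees C.
#' @param residual_sd Residual SD of the fit (0 for an exact curve).
#' @return Object of class `background_curve`.
#' @export
background_curve <- function(coefficients, range_C = c(-Inf, Inf),
                             residual_sd = 0) {
  coefficients <- c(as.numeric(coefficients), 0, 0)[1:3]
  structure(list(coefficients = coefficients, range_C = range_C,
                 residual_sd = residual_sd),
            class = "background_curve")
}

#' @export
predict.background_curve <- function(object, temperature_C, ...) {
  cf <- object$coefficients
  cf[1] + cf[2] * temperature_C + cf[3] * temperature_C^2
}

#' @export
print.background_curve <- function(x, ...) {
  cat(sprintf("<background_curve> %.6g + %.6g T + %.6g T^2 (valid %.4g..%.4g degC, residual SD %.4g)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$range_C[1], x$range_C[2], x$residual_sd))
  invisible(x)
}

#' Fit the dark-background standard curve
#'
#' Least-squares polynomial (default degree 2) of the per-record mean pixel
#' value against the record temperature, fitted to dark (no-signal)
#' records. The per-record scalar is the mean over the 24x24 grid: the
#' sensor is used as a photometer, one value per channel readout.
#'
#' @param dark_records List of `cmos_record` with no bacterial signal.
#' @param degree Polynomial degree (1 or 2; default 2).
#' @return A [background_curve()] with the fitted coefficients, the
#'   temperature range of the data, and the residual SD.
#' @export
fit_background_curve <- function(dark_records, degree = 2) {
  stopifnot(degree %in% 1:2)
  temps <- vapply(dark_records, function(r) r$temperature_C, numeric(1))
  if (length(unique(temps)) < 3)
    stop("need dark records at >= 3 distinct temperatures")
  y <- vapply(dark_records, function(r) mean(r$pixels), numeric(1))
  fit <- stats::lm(y ~ stats::poly(temps, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  # suppressWarnings: a zero-residual (perfect) fit is a legitimate outcome
  # for noiseless dark data and needs no "unreliable summary" notice
  res_sd <- if (length(y) > degree + 1)
    suppressWarnings(summary(fit)$sigma) else 0
  curve <- background_curve(cf, range_C = range(temps), residual_sd = res_sd)
  grid <- seq(curve$range_C[1], curve$range_C[2], length.out = 101)
  if (any(predict(curve, grid) < 0))
    warning("fitted background curve goes negative inside its valid range")
  curve
}

#' Calibrate one record against the background curve
#'
#' Net signal = mean pixel value minus the curve-predicted background at
#' the record's temperature. Temperatures outside the curve's valid range
#' are extrapolated with a warning; negative nets are retained and
#' reported via a message.
#'
#' @param record A `cmos_record`.
#' @param curve A [background_curve()].
#' @return Net signal (counts; may be negative).
#' @export
calibrate_signal <- function(record, curve) {
  stopifnot(inherits(record, "cmos_record"),
            inherits(curve, "background_curve"))
  t <- record$temperature_C
  if (t < curve$range_C[1] || t > curve$range_C[2])
    warning(sprintf("temperature %.2f degC outside the curve range; extrapolating", t))
  net <- mean(record$pixels) - predict(curve, t)
  if (net < 0) message("negative net CMOS signal retained")
  net
}

#' Calibrated time series for a record stream
#'
#' @param records List of `cmos_record`.
#' @param curve A [background_curve()].
#' @return Data frame `timestamp_s, channel, temperature_C, raw_mean,
#'   background, net`.
#' @export
calibrate_series <- function(records, curve) {
  do.call(rbind, lapply(records, function(r) {
    bg <- predict(curve, r$temperature_C)
    data.frame(timestamp_s = r$timestamp_s, channel = r$channel,
               temperature_C = r$temperature_C, raw_mean = mean(r$pixels),
               background = bg, net = mean(r$pixels) - bg)
  }))
}

#' CMOS induction factor
#'
#' Mean calibrated (background-subtracted) signal of the treated records
#' divided by that of the control records.
#'
#' @param treated_records,control_records Non-empty lists of `cmos_record`.
#' @param curve A [background_curve()].
#' @return Induction factor.
#' @export
cmos_induction <- function(treated_records, control_records, curve) {
  if (length(treated_records) == 0 || length(control_records) == 0)
    stop("treated and control record series must be non-empty")
  net <- function(recs) mean(vapply(recs, function(r)
    mean(r$pixels) - predict(curve, r$temperature_C), numeric(1)))
  bc <- net(control_records)
  if (bc <= 0) stop("control signal Bc must be positive")
  induction_factor(net(treated_records), bc)
}

#' Reconstruct a composite image from one timestamp's records
#'
#' Tiles the 24x24 channel grids into a 48x48 composite, row-major by
#' channel id (0 top-left, 1 top-right, 2 bottom-left, 3 bottom-right).
#' Missing channels are zero-filled with a warning; a duplicated channel is
#' an error.
#'
#' @param records List of `cmos_record` sharing one timestamp (1-4
#'   channels).
#' @return 48x48 numeric matrix.
#' @export
reconstruct_image <- function(records) {
  stopifnot(length(records) >= 1, length(records) <= 4)
  chans <- vapply(records, function(r) r$channel, integer(1))
  if (anyDuplicated(chans))
    stop("duplicate channel for one timestamp: ",
         paste(chans[duplicated(chans)], collapse = ", "))
  if (length(unique(vapply(records, function(r) r$timestamp_s,
                           numeric(1)))) > 1)
    stop("records must share one timestamp")
  missing <- setdiff(0:3, chans)
  if (length(missing) > 0)
    warning("missing channel(s) zero-filled: ",
            paste(missing, collapse = ", "))
  composite <- matrix(0, 48, 48)
  slots <- list(`0` = list(1:24, 1:24), `1` = list(1:24, 25:48),
                `2` = list(25:48, 1:24), `3` = list(25:48, 25:48))
  for (r in records) {
    s <- slots[[as.character(r$channel)]]
    composite[s[[1]], s[[2]]] <- r$pixels
  }
  composite
}
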