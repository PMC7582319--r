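# File formats: frame stacks (TIFF/PNG + timestamp sidecar), trace CSVs.

#' Write a frame stack to disk
#'
#' One image file per frame named `frame_0000.tif` (16-bit RGB TIFF) or
#' `frame_0000.png` (8-bit PNG), plus a sidecar `timestamps.csv` with
#' columns `index,time_s`. Pixel counts are scaled by the bit depth to the
#' [0, 1] range the image writers expect.
#'
#' @param frames List of `wcb_frame`.
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` (16-bit) or `"png"` (8-bit).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    scaled <- pmin(pmax(f$pixels / (2^f$bit_depth - 1), 0), 1)
    fn <- file.path(dir, sprintf("frame_%04d.%s", k - 1L,
                                 if (format == "tiff") "tif" else "png"))
    if (format == "tiff")
      tiff::writeTIFF(scaled, fn, bits.per.sample = 16L)
    else png::writePNG(scaled, fn)
  }
  ts <- data.frame(index = seq_along(frames) - 1L,
                   time_s = vapply(frames, function(f) f$timestamp_s,
                                   numeric(1)))
  utils::write.csv(ts, file.path(dir, "timestamps.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a frame stack from disk
#'
#' Reads every `frame_*.tif`/`frame_*.png` in the directory (in index
#' order) together with the `timestamps.csv` sidecar, undoing the [0, 1]
#' scaling of [write_frames()].
#'
#' @param dir Directory written by [write_frames()].
#' @param bit_depth Bit depth used to rescale to counts (default 16 for
#'   TIFF, 8 for PNG).
#' @return List of `wcb_frame`.
#' @export
read_frames <- function(dir, bit_depth = NULL) {
  files <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.(tif|png)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame files found in ", dir)
  ts_path <- file.path(dir, "timestamps.csv")
  ts <- if (file.exists(ts_path)) utils::read.csv(ts_path)
        else data.frame(index = seq_along(files) - 1L, time_s = 0)
  is_png <- grepl("\\.png$", files[1])
  if (is.null(bit_depth)) bit_depth <- if (is_png) 8L else 16L
  lapply(seq_along(files), function(k) {
    px <- if (is_png) png::readPNG(files[k]) else tiff::readTIFF(files[k])
    new_frame(px * (2^bit_depth - 1), ts$time_s[k], bit_depth)
  })
}

#' Write / read a kinetic trace CSV
#'
#' Traces use the two-column format `time_h,rlu`.
#'
#' @param trace Data frame with `time_h`, `rlu`.
#' @param path CSV path.
#' @return The path (write) or a `wcb_trace` data frame (read).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_h", "rlu") %in% names(trace)))
  utils::write.csv(trace[, c("time_h", "rlu")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "rlu") %in% names(df)))
  structure(df, class = c("wcb_trace", "data.frame"))
}
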