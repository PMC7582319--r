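# Smartphone image chain: stack, merge G+B, detect disks, photometry.

#' Average a list of frames into one stacked image
#'
#' Per-pixel, per-channel arithmetic mean computed in real arithmetic (the
#' result is never re-quantized; rounding at this stage would bias low-light
#' photometry). Stacking N frames reduces uncorrelated background noise by
#' about sqrt(N).
#'
#' @param frames Non-empty list of `wcb_frame` objects with identical
#'   dimensions and bit depth.
#' @return A list (class `wcb_stack`) with `pixels` (real-valued
#'   `height x width x 3` array), `n_frames`, `timestamps_s`, `bit_depth`.
#' @export
stack_frames <- function(frames) {
  if (length(frames) < 1) stop("need at least one frame")
  stopifnot(all(vapply(frames, inherits, logical(1), "wcb_frame")))
  dims <- lapply(frames, function(f) dim(f$pixels))
  if (length(unique(dims)) != 1)
    stop("all frames in a stack must share dimensions")
  depths <- vapply(frames, function(f) f$bit_depth, integer(1))
  if (length(unique(depths)) != 1)
    stop("all frames in a stack must share bit depth")
  acc <- Reduce(`+`, lapply(frames, function(f) f$pixels))
  structure(list(pixels = acc / length(frames), n_frames = length(frames),
                 timestamps_s = vapply(frames, function(f) f$timestamp_s,
                                       numeric(1)),
                 bit_depth = depths[1]),
            class = "wcb_stack")
}

#' @export
print.wcb_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<wcb_stack> %dx%d, mean of %d frames\n", d[1], d[2],
              x$n_frames))
  invisible(x)
}

#' Merge the green and blue channels
#'
#' Returns the per-pixel arithmetic mean of the G and B channels as a
#' single-channel image; the red channel is discarded entirely (bacterial
#' lux emission is blue-green, so R carries no signal).
#'
#' @param image A `wcb_stack`, `wcb_frame`, or a `height x width x 3` array.
#' @return A numeric matrix (single-channel image).
#' @export
merge_green_blue <- function(image) {
  px <- if (inherits(image, c("wcb_stack", "wcb_frame"))) image$pixels
        else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("merge_green_blue requires a 3-channel image")
  (px[, , 2] + px[, , 3]) / 2
}

#' Detect disk regions in a single-channel image
#'
#' Thresholds at `median + k_mad * mad` of all pixel values (MAD scaled by
#' the usual 1.4826 consistency constant), labels connected components, and
#' fits each a centroid plus equivalent-radius circle
#' (`radius = sqrt(area / pi)`). When a layout hint is supplied, each
#' detected region snaps to the nearest hinted disk center within two hint
#' radii, adopting the hinted center and radius exactly. ROIs are returned
#' sorted row-major (by center row, then column).
#'
#' @param image Numeric matrix (e.g. from [merge_green_blue()]).
#' @param hint Optional [disk_layout()] with the expected disk positions.
#' @param k_mad Detection threshold in MADs above the median (default 5;
#'   robust at the very low SNR of stacked low-light images).
#' @param min_area Minimum component area in pixels (suppresses hot-pixel
#'   specks).
#' @return Data frame of ROIs: `center_row`, `center_col`, `radius`
#'   (0-based pixel coordinates); zero rows for a blank image.
#' @export
detect_disks <- function(image, hint = NULL, k_mad = 5, min_area = 5) {
  stopifnot(is.matrix(image), length(image) > 0)
  thr <- stats::median(image) + k_mad * stats::mad(image)
  bw <- image > thr
  empty <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      radius = numeric(0))
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw * 1)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  area <- tabulate(labs)
  keep <- which(area >= min_area)
  if (length(keep) == 0) return(empty)
  rois <- data.frame(
    center_row = tapply(idx[, 1] - 1, labs, mean)[as.character(keep)],
    center_col = tapply(idx[, 2] - 1, labs, mean)[as.character(keep)],
    radius = sqrt(area[keep] / pi))
  if (!is.null(hint)) {
    stopifnot(inherits(hint, "disk_layout"))
    for (i in seq_len(nrow(rois))) {
      d <- sqrt((hint$disks$center_row - rois$center_row[i])^2 +
                (hint$disks$center_col - rois$center_col[i])^2)
      j <- which.min(d)
      if (d[j] <= 2 * hint$disks$radius[j]) rois[i, ] <- hint$disks[j, ]
    }
    rois <- unique(rois)
  }
  # row-major order robust to sub-pixel centroid jitter: bucket rows that
  # are closer than a typical radius, then sort by column within a bucket
  ord <- order(rois$center_row)
  rows <- rois$center_row[ord]
  bucket <- cumsum(c(1, diff(rows) > stats::median(rois$radius)))
  rois <- rois[ord, , drop = FALSE][order(bucket, rois$center_col[ord]), ,
                                    drop = FALSE]
  rownames(rois) <- NULL
  rois
}

#' Mean intensity inside a circular ROI
#'
#' Arithmetic mean of the pixels whose centers lie within `radius` of the
#' ROI center (0-based coordinates, the same membership rule as the disk
#' renderer).
#'
#' @param image Numeric matrix.
#' @param center_row,center_col,radius ROI circle (pixels); alternatively
#'   pass a one-row data frame / list as `center_row`.
#' @return Mean intensity (counts); attribute `n_pixels` carries the pixel
#'   count.
#' @export
measure_disk_intensity <- function(image, center_row, center_col = NULL,
                                   radius = NULL) {
  stopifnot(is.matrix(image))
  if (is.list(center_row)) {
    roi <- center_row
    center_row <- roi$center_row; center_col <- roi$center_col
    radius <- roi$radius
  }
  stopifnot(length(center_row) == 1, radius > 0)
  h <- nrow(image); w <- ncol(image)
  if (center_row - radius < 0 || center_row + radius > h - 1 ||
      center_col - radius < 0 || center_col + radius > w - 1)
    stop("ROI must lie fully inside the image")
  m <- .disk_mask(h, w, center_row, center_col, radius)
  if (!any(m)) stop("ROI contains no pixel centers")
  structure(mean(image[m]), n_pixels = sum(m))
}

#' Estimate the image background level
#'
#' Default: the median of all pixels farther than `margin_factor` times each
#' disk's radius from every detected disk center (a robust stand-in for the
#' manual background selection of the bench procedure). A rectangular
#' background region, if given, overrides the automatic rule.
#'
#' @param image Numeric matrix.
#' @param rois Data frame of disk ROIs (as from [detect_disks()]).
#' @param rect Optional `c(row0, col0, row1, col1)` inclusive 0-based
#'   rectangle to use instead.
#' @param margin_factor Exclusion margin in units of disk radius.
#' @return Background level (counts).
#' @export
estimate_background <- function(image, rois, rect = NULL, margin_factor = 2) {
  stopifnot(is.matrix(image))
  if (!is.null(rect)) {
    stopifnot(length(rect) == 4)
    sub <- image[(rect[1]:rect[3]) + 1, (rect[2]:rect[4]) + 1]
    return(stats::median(sub))
  }
  keep <- matrix(TRUE, nrow(image), ncol(image))
  for (i in seq_len(nrow(rois)))
    keep <- keep & !.disk_mask(nrow(image), ncol(image),
                               rois$center_row[i], rois$center_col[i],
                               margin_factor * rois$radius[i])
  if (!any(keep)) stop("no background pixels left outside the disk margins")
  stats::median(image[keep])
}

#' Subtract the background level from a signal mean
#'
#' Net intensity `signal_mean - background_mean`. Negative results are
#' returned unchanged (clamping would bias induction factors upward near
#' the detection limit) and reported via a message.
#'
#' @param signal_mean,background_mean Mean intensities, counts.
#' @return Net intensity (counts; may be negative).
#' @export
subtract_background <- function(signal_mean, background_mean) {
  stopifnot(is.finite(signal_mean), is.finite(background_mean))
  net <- signal_mean - background_mean
  if (any(net < 0))
    message("negative net intensity retained (signal below background)")
  net
}

#' Per-disk photometry table for one image
#'
#' Measures every ROI, estimates (or accepts) a background level, and
#' returns the standard per-disk result table.
#'
#' @param image Numeric matrix.
#' @param rois ROI data frame (see [detect_disks()]).
#' @param background Optional fixed background level; default computed with
#'   [estimate_background()].
#' @param background_rect Optional rectangle forwarded to
#'   [estimate_background()].
#' @return Data frame `disk_id, center_row, center_col, radius, mean,
#'   n_pixels, background, net`.
#' @export
measure_disks <- function(image, rois, background = NULL,
                          background_rect = NULL) {
  stopifnot(nrow(rois) >= 1)
  if (is.null(background))
    background <- estimate_background(image, rois, rect = background_rect)
  res <- lapply(seq_len(nrow(rois)), function(i) {
    m <- measure_disk_intensity(image, rois[i, ])
    data.frame(disk_id = i, center_row = rois$center_row[i],
               center_col = rois$center_col[i], radius = rois$radius[i],
               mean = as.numeric(m), n_pixels = attr(m, "n_pixels"),
               background = background,
               net = subtract_background(as.numeric(m), background))
  })
  do.call(rbind, res)
}
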