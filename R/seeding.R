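#' Quantize an orientation angle into equal-width bins
#'
#' Orientation uniqueness on a discrete image is decided on quantized
#' angles: the range \[-90, 90) degrees is split into `bin_count` equal
#' bins and a pixel's bin is `floor((theta + 90) / 180 * bin_count)`,
#' clamped into `[0, bin_count - 1]`.
#'
#' @param theta Numeric vector of angles in degrees, each in \[-90, 90).
#' @param bin_count Number of bins, at least 2.
#' @return Integer vector of 0-based bin indices.
#' @export
#' @examples
#' quantize_orientation(c(-90, 0, 89.999), 180)
quantize_orientation <- function(theta, bin_count) {
  if (any(is.na(theta))) {
    stop_mnctess("orientation is undefined (NA) for some input", "undefined_theta")
  }
  bin_count <- as.integer(bin_count)
  if (bin_count < 2L) stop_mnctess("bin_count must be >= 2", "bad_config")
  if (any(theta < -90 | theta >= 90)) {
    stop_mnctess("theta must lie in [-90, 90)", "bad_config")
  }
  pmax(0L, pmin(bin_count - 1L, as.integer(floor((theta + 90) / 180 * bin_count))))
}

#' Select generating points with unique gradient orientation
#'
#' Implements the weeding construction that seeds the tessellation: pixels
#' whose quantized gradient-orientation angle is not unique in the image
#' are discarded, so every generating point carries a distinct orientation
#' description.
#'
#' Two modes are available. `"strict"` keeps exactly the pixels whose bin
#' is occupied by no other defined pixel (the literal rule; it can empty
#' the set on smooth images). `"representative"` (default) keeps, for each
#' occupied bin, the single pixel with the largest gradient magnitude
#' (ties broken by smallest `(y, x)`), which preserves one delegate per
#' orientation while remaining robust. If more than `max_points` bins are
#' occupied, the points with largest magnitude are kept (same tie rule).
#'
#' @param gfield A [gradient_field()].
#' @param bins Number of orientation bins (default 1024).
#' @param mode `"representative"` or `"strict"`.
#' @param max_points Cap on the number of returned points (default 300).
#' @param min_points Minimum acceptable number of points (default 4);
#'   fewer raises a `mnctess_error_few_points` condition, signalling an
#'   image too degenerate to tessellate.
#' @return Tibble ordered by `(y, x)` with columns `x`, `y` (0-based pixel
#'   indices), `theta` (degrees), `bin`, `magnitude`, and attributes
#'   `bin_count` and `mode`.
#' @export
#' @examples
#' img <- make_blob_image(width = 32, height = 32,
#'                        blobs = tibble::tibble(x = 16, y = 16,
#'                                               sigma = 6, amplitude = 1))
#' pts <- select_generating_points(gradient_field(img), bins = 64)
#' nrow(pts)  # one point per occupied orientation bin
select_generating_points <- function(gfield, bins = 1024L,
                                     mode = c("representative", "strict"),
                                     max_points = 300L, min_points = 4L) {
  mode <- match.arg(mode)
  px <- tidy.gradient_field(gfield)
  px <- dplyr::filter(px, .data$defined)
  if (nrow(px) < min_points) {
    stop_mnctess(sprintf("only %d pixels have a defined orientation (min %d)",
                         nrow(px), min_points), "few_points")
  }
  px$bin <- quantize_orientation(px$theta, bins)

  sel <- if (mode == "strict") {
    dplyr::filter(dplyr::group_by(px, .data$bin), dplyr::n() == 1L) |>
      dplyr::ungroup()
  } else {
    px |>
      dplyr::arrange(dplyr::desc(.data$magnitude), .data$y, .data$x) |>
      dplyr::distinct(.data$bin, .keep_all = TRUE)
  }
  if (nrow(sel) > max_points) {
    sel <- sel |>
      dplyr::arrange(dplyr::desc(.data$magnitude), .data$y, .data$x) |>
      dplyr::slice_head(n = max_points)
  }
  if (nrow(sel) < min_points) {
    stop_mnctess(sprintf("selection kept %d points, fewer than min_points = %d",
                         nrow(sel), min_points), "few_points")
  }
  out <- sel |>
    dplyr::arrange(.data$y, .data$x) |>
    dplyr::select("x", "y", "theta", "bin", "magnitude")
  attr(out, "bin_count") <- as.integer(bins)
  attr(out, "mode") <- mode
  out
}
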