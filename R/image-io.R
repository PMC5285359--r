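#' Create a 2D scalar image from a numeric matrix
#'
#' The package represents a grayscale image as a plain numeric matrix with
#' rows indexed by the pixel row `y` (top row first) and columns by the
#' pixel column `x`. All pixel coordinates exposed to the user are 0-based:
#' pixel `(x, y)` is `values[y + 1, x + 1]`.
#'
#' @param values Numeric matrix of finite intensities, at least 2 x 2.
#' @param source Optional provenance string (file path etc.), stored as an
#'   attribute.
#' @return A `scalar_image`: the matrix with class and provenance attributes.
#' @export
#' @examples
#' img <- as_scalar_image(matrix(0:3, 2, 2, byrow = TRUE))
#' image_dim(img)
as_scalar_image <- function(values, source = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop_mnctess("image must be at least 2 x 2 pixels", "bad_image")
  }
  if (!all(is.finite(values))) {
    stop_mnctess("image intensities must all be finite", "bad_image")
  }
  structure(values, class = c("scalar_image", "matrix", "array"),
            source = source)
}

#' Image dimensions in pixels
#' @param img A `scalar_image` or numeric matrix.
#' @return Named vector `c(width = , height = )`.
#' @export
image_dim <- function(img) {
  c(width = ncol(img), height = nrow(img))
}

#' Read a 2D grayscale image from PNG, TIFF or NIfTI
#'
#' PNG and TIFF rasters are decoded as-is (16-bit images arrive rescaled to
#' \[0, 1\] by the readers, which is irrelevant downstream: gradient
#' orientation is invariant to intensity scaling). Multi-channel rasters are
#' reduced with the `channel` rule. NIfTI volumes require explicit 0-based
#' slice indices selecting one 2D slab.
#'
#' @param path File path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param channel For multi-channel rasters: `"luminance"` (Rec. 601
#'   weights 0.299/0.587/0.114 on the first three channels), `"mean"`, or a
#'   0-based channel index.
#' @param axis,slice For NIfTI: the axis collapsed (`"x"`, `"y"` or `"z"`)
#'   and the 0-based slice index along it.
#' @param time For 4D NIfTI: 0-based timepoint index.
#' @return A [as_scalar_image()] matrix; provenance (path and any slice
#'   selection) is kept in the `source` attribute.
#' @export
read_scalar_image <- function(path, channel = "luminance",
                              axis = "z", slice = NULL, time = NULL) {
  if (!file.exists(path)) {
    stop_mnctess(paste0("file not found: ", path), "unreadable")
  }
  lower <- tolower(path)
  arr <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    return(read_nifti_slice(path, axis = axis, slice = slice, time = time))
  } else {
    stop_mnctess(paste0("unsupported image format: ", path), "unreadable")
  }
  as_scalar_image(collapse_channels(arr, channel), source = path)
}

collapse_channels <- function(arr, channel) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) != 3L) {
    stop_mnctess("raster must be 2D or 2D multi-channel", "unreadable")
  }
  nc <- dim(arr)[3]
  if (is.numeric(channel)) {
    k <- as.integer(channel)
    if (k < 0L || k >= nc) {
      stop_mnctess(sprintf("channel index %d out of range [0, %d]", k, nc - 1L),
                   "bad_selection")
    }
    return(arr[, , k + 1L])
  }
  switch(match.arg(channel, c("luminance", "mean")),
    luminance = {
      if (nc < 3L) return(arr[, , 1L])
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    },
    mean = apply(arr, c(1, 2), mean)
  )
}

read_nifti_slice <- function(path, axis = "z", slice = NULL, time = NULL) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) == 4L) {
    if (is.null(time)) {
      stop_mnctess("4D NIfTI needs a 0-based `time` index", "bad_selection")
    }
    t1 <- as.integer(time) + 1L
    if (t1 < 1L || t1 > d[4]) {
      stop_mnctess(sprintf("time index %d out of range [0, %d]", time, d[4] - 1L),
                   "bad_selection")
    }
    vol <- vol[, , , t1]
    d <- dim(vol)
  }
  if (length(d) != 3L) {
    stop_mnctess("NIfTI volume must be 3D or 4D", "unreadable")
  }
  if (is.null(slice)) {
    stop_mnctess("NIfTI needs a 0-based `slice` index", "bad_selection")
  }
  ax <- match.arg(axis, c("x", "y", "z"))
  k <- match(ax, c("x", "y", "z"))
  k1 <- as.integer(slice) + 1L
  if (k1 < 1L || k1 > d[k]) {
    stop_mnctess(sprintf("slice index %d out of range [0, %d]", slice, d[k] - 1L),
                 "bad_selection")
  }
  slab <- switch(ax, x = vol[k1, , ], y = vol[, k1, ], z = vol[, , k1])
  # NIfTI slabs index (i, j); present j as the image row so that the slab
  # transposes into the row-by-column raster convention.
  as_scalar_image(t(slab),
                  source = sprintf("%s[axis=%s,slice=%d%s]", path, ax,
                                   as.integer(slice),
                                   if (is.null(time)) ""
                                   else sprintf(",time=%d", as.integer(time))))
}
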