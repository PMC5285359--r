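#' Per-pixel intensity gradient and orientation field
#'
#' Estimates the partial derivatives Gx = d img/dx (along columns) and
#' Gy = d img/dy (along rows) by central differences on interior pixels and
#' one-sided differences on the borders, then derives the gradient
#' orientation angle theta = arctan(Gy / Gx), evaluated as the two-argument
#' arctangent of (Gy, Gx) folded into \[-90, 90) degrees so the vertical
#' limit Gx = 0 needs no division. Pixels where Gx = Gy = 0 have no
#' orientation: they are flagged in the `defined` mask and carry `NA` theta.
#'
#' @param img A [as_scalar_image()] matrix (or plain numeric matrix).
#' @return A `gradient_field`: list with numeric matrices `gx`, `gy`,
#'   `theta` (degrees, `NA` where undefined), logical matrix `defined`, and
#'   `width`/`height`.
#' @export
#' @examples
#' ramp <- as_scalar_image(outer(0:7, 0:7, function(y, x) 2 * x))
#' gf <- gradient_field(ramp)
#' unique(gf$theta[gf$defined])  # 0 degrees everywhere
gradient_field <- function(img) {
  img <- as_scalar_image(unclass(img))
  v <- unclass(img)
  h <- nrow(v); w <- ncol(v)

  gx <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (v[, 3:w, drop = FALSE] - v[, 1:(w - 2), drop = FALSE]) / 2
  gx[, 1] <- v[, 2] - v[, 1]
  gx[, w] <- v[, w] - v[, w - 1]

  gy <- matrix(0, h, w)
  gy[2:(h - 1), ] <- (v[3:h, , drop = FALSE] - v[1:(h - 2), , drop = FALSE]) / 2
  gy[1, ] <- v[2, ] - v[1, ]
  gy[h, ] <- v[h, ] - v[h - 1, ]

  defined <- !(gx == 0 & gy == 0)
  theta <- matrix(NA_real_, h, w)
  theta[defined] <- fold_orientation(atan2(gy[defined], gx[defined]) * 180 / pi)

  structure(list(gx = gx, gy = gy, theta = theta, defined = defined,
                 width = w, height = h),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d pixels, %d with defined orientation\n",
              x$width, x$height, sum(x$defined)))
  invisible(x)
}

#' Tidy a gradient field into a long pixel table
#'
#' @param x A `gradient_field`.
#' @param ... Unused.
#' @return Tibble with one row per pixel: 0-based `x`, `y`, then `gx`,
#'   `gy`, `theta` (degrees, `NA` if undefined), `magnitude`, `defined`.
#' @method tidy gradient_field
#' @export
tidy.gradient_field <- function(x, ...) {
  px <- rep(0:(x$width - 1L), each = x$height)
  py <- rep(0:(x$height - 1L), times = x$width)
  gx <- as.vector(x$gx)
  gy <- as.vector(x$gy)
  th <- as.vector(x$theta)
  def <- as.vector(x$defined)
  tibble(x = px, y = py, gx = gx, gy = gy, theta = th,
         magnitude = sqrt(gx^2 + gy^2), defined = def)
}
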