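#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
NULL

# Geometric tolerance for point-equality tests, in pixels.
GEOM_TOL <- 1e-9
# Minimum shared-boundary length for two regions to count as edge-sharing.
EDGE_EPS <- 1e-9

#' Fold an angle into the orientation range [-90, 90) degrees
#'
#' Gradient orientation is a line direction, not a vector direction: theta
#' and theta + 180 describe the same orientation. All orientation angles in
#' the package live in the half-open range \code{[-90, 90)} degrees, the
#' range of \code{atan(Gy/Gx)} extended continuously through the vertical
#' (\code{Gx = 0}) limit.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector folded into \code{[-90, 90)}.
#' @export
#' @examples
#' fold_orientation(c(-90, 0, 90, 135, 270))
fold_orientation <- function(theta) {
  f <- ((theta + 90) %% 180) - 90
  # %% can return 180 - eps rounding artifacts; keep the range half-open
  f[f >= 90] <- f[f >= 90] - 180
  f
}

#' Circular difference between two orientation angles
#'
#' Distance on the orientation circle of period 180 degrees, so that
#' -89 and +89 degrees are 2 degrees apart.
#'
#' @param a,b Numeric vectors of angles in degrees.
#' @return Nonnegative numeric vector, at most 90.
#' @export
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# log(sum(exp(x))) without overflow/underflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Signed shoelace area of polygon vertices (n x 2 matrix); positive = CCW.
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Polygon centroid (n x 2 matrix), standard area-weighted formula.
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < GEOM_TOL) return(colMeans(v))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Canonical vertex order: counter-clockwise, starting at the
# lexicographically smallest (x, then y) vertex. Gives bit-stable output.
normalize_polygon <- function(v) {
  if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  start <- order(v[, 1], v[, 2])[1]
  if (start > 1) {
    idx <- c(start:nrow(v), seq_len(start - 1))
    v <- v[idx, , drop = FALSE]
  }
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

stop_mnctess <- function(msg, class, ...) {
  abort(msg, class = c(paste0("mnctess_error_", class), "mnctess_error"), ...)
}
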