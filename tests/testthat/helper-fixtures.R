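# Shared in-code fixtures for the test suite.

# Synthetic gradient field with prescribed orientations at given pixels
# (all other pixels flat). Useful for exercising seeding logic exactly.
synthetic_gradient_field <- function(width, height, px, py, theta_deg,
                                     magnitude = 1) {
  gx <- gy <- matrix(0, height, width)
  magnitude <- rep_len(magnitude, length(px))
  for (k in seq_along(px)) {
    rad <- theta_deg[k] * pi / 180
    gx[py[k] + 1, px[k] + 1] <- magnitude[k] * cos(rad)
    gy[py[k] + 1, px[k] + 1] <- magnitude[k] * sin(rad)
  }
  defined <- !(gx == 0 & gy == 0)
  theta <- matrix(NA_real_, height, width)
  theta[defined] <- mnctess::fold_orientation(atan2(gy[defined], gx[defined]) * 180 / pi)
  structure(list(gx = gx, gy = gy, theta = theta, defined = defined,
                 width = width, height = height),
            class = "gradient_field")
}

# 3 x 3 grid of evenly spaced points in a 30 x 30 rectangle: the centre
# region has exactly the 4 orthogonal neighbours (diagonals touch at a
# vertex only).
grid9_tiling <- function() {
  pts <- expand.grid(x = c(5, 15, 25), y = c(5, 15, 25))
  build_tessellation(pts, 30, 30)
}

# Centre point ringed by six satellites, plus four far corners: the centre
# cell has degree 6 (the unique maximum), the MNC regions are small and the
# non-MNC corner regions large, with comparable set sizes (7 vs 4).
clustered_grid_tiling <- function(d = 5) {
  ang <- (0:5) * pi / 3
  pts <- data.frame(
    x = c(15, 15 + d * cos(ang), 6, 24, 6, 24),
    y = c(15, 15 + d * sin(ang), 6, 6, 24, 24)
  )
  build_tessellation(pts, 30, 30)
}

# Descriptor table builder for unit-level temporal tests.
descriptor_row <- function(frame, theta, degree, id = 1L, time = frame / 10) {
  tibble::tibble(frame_index = as.integer(frame), time_label = time,
                 nucleus_id = as.integer(id), nucleus_x = 1, nucleus_y = 1,
                 nucleus_theta = theta, degree = as.integer(degree),
                 centroid_x = 1, centroid_y = 1, nucleus_area = 4)
}
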