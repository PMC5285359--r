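# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, direct formulas, exhaustive search.

# Elementwise finite differences with explicit loops.
oracle_gradient <- function(v) {
  h <- nrow(v); w <- ncol(v)
  gx <- gy <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      gx[r, cc] <- if (cc == 1) v[r, 2] - v[r, 1]
        else if (cc == w) v[r, w] - v[r, w - 1]
        else (v[r, cc + 1] - v[r, cc - 1]) / 2
      gy[r, cc] <- if (r == 1) v[2, cc] - v[1, cc]
        else if (r == h) v[h, cc] - v[h - 1, cc]
        else (v[r + 1, cc] - v[r - 1, cc]) / 2
    }
  }
  list(gx = gx, gy = gy)
}

# Histogram-style binning via interval edges.
oracle_bin <- function(theta, bins) {
  edges <- seq(-90, 90, length.out = bins + 1)
  pmin(findInterval(theta, edges, rightmost.closed = FALSE) - 1L, bins - 1L)
}

# Nearest-generating-point label for each sample point; ties get NA.
oracle_nearest <- function(px, py, sx, sy, tie_tol = 1e-9) {
  d2 <- outer(px, sx, function(a, b) (a - b)^2) +
    outer(py, sy, function(a, b) (a - b)^2)
  lab <- max.col(-d2, ties.method = "first")
  if (length(sx) > 1) {
    d <- sqrt(d2)
    best <- d[cbind(seq_along(px), lab)]
    d[cbind(seq_along(px), lab)] <- Inf
    second <- apply(d, 1, min)
    lab[second - best < tie_tol] <- NA_integer_
  }
  lab
}

# Region membership of sample points by half-plane sign tests against each
# CCW polygon (boundary-inclusive; first containing region wins).
oracle_region_label <- function(tiling, px, py, tol = 1e-7) {
  lab <- rep(NA_integer_, length(px))
  for (i in seq_along(tiling$regions)) {
    v <- tiling$regions[[i]]
    n <- nrow(v)
    inside <- rep(TRUE, length(px))
    for (e in seq_len(n)) {
      a <- v[e, ]; b <- v[if (e == n) 1 else e + 1, ]
      inside <- inside &
        ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) >= -tol)
    }
    lab[is.na(lab) & inside] <- i
  }
  lab
}

# Length of the shared Voronoi boundary of points i and j: 1D clipping of
# their perpendicular bisector against the bounds and every other point's
# half-plane. Zero when the locus is empty or a single point.
oracle_bisector_length <- function(sx, sy, i, j, width, height) {
  mx <- (sx[i] + sx[j]) / 2; my <- (sy[i] + sy[j]) / 2
  ux <- -(sy[j] - sy[i]); uy <- sx[j] - sx[i]
  nrm <- sqrt(ux^2 + uy^2); ux <- ux / nrm; uy <- uy / nrm
  lo <- -Inf; hi <- Inf
  # bounds: 0 <= mx + t ux <= width, 0 <= my + t uy <= height
  for (cons in list(c(ux, mx, 0), c(-ux, -mx, -width),
                    c(uy, my, 0), c(-uy, -my, -height))) {
    a <- cons[1]; b <- cons[2]; lim <- cons[3]
    # a * t + b >= lim
    if (abs(a) < 1e-15) {
      if (b < lim) return(0)
    } else if (a > 0) {
      lo <- max(lo, (lim - b) / a)
    } else {
      hi <- min(hi, (lim - b) / a)
    }
  }
  # other points: |P - s_k|^2 >= |P - s_i|^2 for P = m + t u
  for (k in seq_along(sx)) {
    if (k == i || k == j) next
    ax <- sx[k] - sx[i]; ay <- sy[k] - sy[i]
    a <- 2 * (ux * ax + uy * ay)
    b <- (sx[k]^2 + sy[k]^2 - sx[i]^2 - sy[i]^2) - 2 * (mx * ax + my * ay)
    # a * t <= b
    if (abs(a) < 1e-15) {
      if (b < 0) return(0)
    } else if (a > 0) {
      hi <- min(hi, b / a)
    } else {
      lo <- max(lo, b / a)
    }
  }
  max(0, hi - lo)
}

# Exact adjacency: pairs whose shared boundary has positive length.
oracle_adjacency_exact <- function(sx, sy, width, height, eps = 1e-9) {
  n <- length(sx)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_bisector_length(sx, sy, i, j, width, height) > eps) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}

# Rasterized-label dilation: nearest-point labels on a supersampled grid,
# adjacency = 4-neighbour contact between distinct labels.
oracle_adjacency_dilation <- function(sx, sy, width, height, sub = 4L) {
  gx <- seq(0.5 / sub, width - 0.5 / sub, by = 1 / sub)
  gy <- seq(0.5 / sub, height - 0.5 / sub, by = 1 / sub)
  lab <- matrix(0L, length(gy), length(gx))
  for (cc in seq_along(gx)) {
    d2 <- sapply(seq_along(sx), function(k) (gx[cc] - sx[k])^2 + (gy - sy[k])^2)
    lab[, cc] <- max.col(-d2, ties.method = "first")
  }
  prs <- rbind(
    cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1])),
    cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ]))
  )
  prs <- prs[prs[, 1] != prs[, 2], , drop = FALSE]
  unique(cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2])))
}

# Direct (non-log-space) Renyi entropy.
oracle_renyi <- function(p, beta) (1 / (1 - beta)) * log2(sum(p^beta))

# Exhaustive minimal-total-deviation antipodal matching for small n.
oracle_antipodal <- function(n) {
  sep <- function(i, j) {
    s <- (abs(i - j) %% n) * 360 / n
    min(s, 360 - s)
  }
  best <- NULL; best_cost <- Inf
  recurse <- function(avail, acc, cost) {
    if (length(avail) < 2) {
      if (cost < best_cost - 1e-12) { best_cost <<- cost; best <<- acc }
      return(invisible())
    }
    i <- avail[1]
    # i may stay unpaired only if the matching can still reach max size
    if (length(avail) %% 2 == 1) {
      recurse(avail[-1], acc, cost)
    }
    for (j in avail[-1]) {
      recurse(setdiff(avail, c(i, j)), rbind(acc, c(i, j)),
              cost + abs(sep(i, j) - 180))
    }
  }
  recurse(0:(n - 1), NULL, 0)
  list(pairs = best[order(best[, 1]), , drop = FALSE], cost = best_cost)
}

# Deterministic random point set for tessellation property tests.
random_points <- function(seed, n, width = 64, height = 64, margin = 1) {
  withr::with_seed(seed, {
    data.frame(x = stats::runif(n, margin, width - margin),
               y = stats::runif(n, margin, height - margin))
  })
}
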