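#' Synthetic blob image with known gradient structure
#'
#' Sum of isotropic Gaussian bumps evaluated at 0-based pixel coordinates,
#' plus seeded Gaussian noise. Gaussian blobs have analytic radial
#' gradients, so the orientation field is predictable: left of a blob
#' centre theta is 0 degrees, above it -90, and so on. They stand in for
#' smooth activation foci in real imaging slices.
#'
#' @param width,height Image size in pixels.
#' @param blobs Data frame with columns `x`, `y` (0-based centre, inside
#'   the image), `sigma` (> 0, pixels), `amplitude`.
#' @param noise_sd Standard deviation of added Gaussian noise (>= 0).
#' @param seed Integer seed; identical config + seed gives identical
#'   images.
#' @return A [as_scalar_image()] matrix.
#' @export
make_blob_image <- function(width = 64L, height = 64L, blobs,
                            noise_sd = 0, seed = 0L) {
  blobs <- as_tibble(blobs)
  stopifnot(all(c("x", "y", "sigma") %in% names(blobs)))
  if (!"amplitude" %in% names(blobs)) blobs$amplitude <- 1
  if (any(blobs$sigma <= 0)) stop_mnctess("sigma must be > 0", "bad_config")
  if (any(blobs$x < 0 | blobs$x >= width | blobs$y < 0 | blobs$y >= height)) {
    stop_mnctess("blob centre outside image bounds", "bad_config")
  }
  if (noise_sd < 0) stop_mnctess("noise_sd must be >= 0", "bad_config")
  xs <- matrix(rep(0:(width - 1L), each = height), height, width)
  ys <- matrix(rep(0:(height - 1L), times = width), height, width)
  v <- matrix(0, height, width)
  for (k in seq_len(nrow(blobs))) {
    v <- v + blobs$amplitude[k] *
      exp(-((xs - blobs$x[k])^2 + (ys - blobs$y[k])^2) / (2 * blobs$sigma[k]^2))
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(width * height, sd = noise_sd), height, width)
    })
  }
  as_scalar_image(v, source = sprintf("blob[seed=%d]", as.integer(seed)))
}

#' Seeded random blob configuration
#'
#' Draws blob centres, widths and amplitudes deterministically from the
#' seed: centres uniform in the central region (12 px margin), sigma in
#' \[4, 9\] px, amplitude in \[0.6, 1\]. These are the study conditions of
#' the canonical fixture suite.
#'
#' @param seed Integer seed.
#' @param n_blobs Number of blobs (default 3).
#' @param width,height Image size.
#' @return Tibble of blob parameters usable as `blobs` in
#'   [make_blob_image()].
#' @export
random_blob_config <- function(seed, n_blobs = 3L, width = 64L, height = 64L) {
  withr::with_seed(as.integer(seed) * 2L + 1L, {
    tibble(
      x = stats::runif(n_blobs, 12, width - 13),
      y = stats::runif(n_blobs, 12, height - 13),
      sigma = stats::runif(n_blobs, 4, 9),
      amplitude = stats::runif(n_blobs, 0.6, 1)
    )
  })
}

#' Canonical seeded fixture suite
#'
#' Twenty 64 x 64 three-blob images, seeds 0 to 19, noise sd 0.01: the
#' fixed conditions under which the package's qualitative entropy claims
#' are evaluated.
#'
#' @param seeds Integer seeds (default `0:19`).
#' @param width,height,n_blobs,noise_sd Image generation parameters.
#' @return Named list of images (`"seed_0"`, ...).
#' @export
blob_suite <- function(seeds = 0:19, width = 64L, height = 64L,
                       n_blobs = 3L, noise_sd = 0.01) {
  imgs <- lapply(seeds, function(s) {
    make_blob_image(width, height,
                    random_blob_config(s, n_blobs, width, height),
                    noise_sd = noise_sd, seed = s)
  })
  names(imgs) <- paste0("seed_", seeds)
  imgs
}

frame_seed <- function(seed, frame, attempt = 0L) {
  (abs(as.integer(seed)) %% 100000L) * 20000L + frame * 50L + attempt
}

jitter_blobs <- function(base_blobs, width, height, seed) {
  withr::with_seed(seed, {
    n <- nrow(base_blobs)
    ang <- stats::runif(n, 0, 2 * pi)
    mag <- stats::runif(n, 3, 6)  # >= 3 px, enough to move every descriptor
    dplyr::mutate(base_blobs,
                  x = pmin(pmax(.data$x + mag * cos(ang), 1), width - 2),
                  y = pmin(pmax(.data$y + mag * sin(ang), 1), height - 2))
  })
}

#' Frame sequence with planted repeated frames
#'
#' Builds an ordered sequence of blob images in which the frames of each
#' planted pair are byte-identical while every other frame is a jittered
#' variant (blob centres displaced by seeded offsets of at least 3 px).
#' When `verify` is on (the default) the generator additionally runs the
#' tessellation pipeline on every frame and deterministically re-jitters
#' any frame whose maximal-cluster descriptors accidentally match another
#' frame within `tol` degrees and equal degree - so the planted pairs are
#' provably the only matching descriptions in the sequence.
#'
#' @param n_frames Number of frames (>= 2).
#' @param repeat_pairs List of 0-based index pairs `c(i, j)`, `i < j`,
#'   pairwise disjoint.
#' @param seed Integer master seed.
#' @param width,height,n_blobs,noise_sd Image generation parameters.
#' @param tol,degree_exact Matching rule the verification guards against
#'   (defaults as in [match_descriptions()]).
#' @param verify Run the pipeline-backed uniqueness check (default TRUE).
#' @param max_attempts Re-jitter budget per frame.
#' @param ... Tessellation options forwarded to [tessellate_image()]
#'   during verification.
#' @return List with `images` (list of frames) and `manifest` (tibble
#'   `frame_index`, `time_label` in seconds at 0.1 s per frame,
#'   `repeat_of` - `NA` or the earlier index the frame copies).
#' @export
make_repeat_sequence <- function(n_frames = 13L, repeat_pairs = list(c(1L, 12L)),
                                 seed = 0L, width = 64L, height = 64L,
                                 n_blobs = 3L, noise_sd = 0.01,
                                 tol = 2, degree_exact = TRUE,
                                 verify = TRUE, max_attempts = 25L, ...) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop_mnctess("need at least 2 frames", "few_frames")
  idx <- unlist(repeat_pairs)
  if (length(idx) != length(unique(idx))) {
    stop_mnctess("repeat pairs must be disjoint", "bad_config")
  }
  if (any(idx < 0L | idx >= n_frames)) {
    stop_mnctess("repeat pair index out of range", "bad_config")
  }
  copy_of <- rep(NA_integer_, n_frames)
  for (pr in repeat_pairs) copy_of[max(pr) + 1L] <- as.integer(min(pr))

  base_blobs <- random_blob_config(seed, n_blobs, width, height)
  attempts <- integer(n_frames)
  gen_frame <- function(f) {
    s <- frame_seed(seed, f, attempts[f + 1L])
    make_blob_image(width, height,
                    jitter_blobs(base_blobs, width, height, s),
                    noise_sd = noise_sd, seed = s + 7L)
  }
  images <- vector("list", n_frames)
  for (f in 0:(n_frames - 1L)) {
    images[[f + 1L]] <- if (!is.na(copy_of[f + 1L])) {
      images[[copy_of[f + 1L] + 1L]]
    } else {
      gen_frame(f)
    }
  }

  if (verify) {
    planted <- if (length(repeat_pairs)) {
      dplyr::bind_rows(lapply(repeat_pairs, function(pr) {
        tibble(i = min(pr), j = max(pr))
      }))
    } else {
      tibble(i = integer(0), j = integer(0))
    }
    for (round in seq_len(max_attempts)) {
      frames <- dplyr::bind_rows(lapply(seq_len(n_frames), function(k) {
        describe_frame(tessellate_image(images[[k]], ...),
                       frame_index = k - 1L, time_label = (k - 1L) / 10)
      }))
      mm <- match_descriptions(frames, tol = tol, degree_exact = degree_exact)
      extra <- dplyr::anti_join(dplyr::distinct(mm, .data$i, .data$j),
                                planted, by = c("i", "j"))
      if (nrow(extra) == 0L) break
      # regenerate the later frame of each spurious match (never a planted copy)
      redo <- unique(vapply(seq_len(nrow(extra)), function(r) {
        cand <- c(extra$j[r], extra$i[r])
        cand[is.na(copy_of[cand + 1L]) & !(cand %in% unlist(repeat_pairs))][1]
      }, numeric(1)))
      redo <- redo[!is.na(redo)]
      if (length(redo) == 0L) {
        stop_mnctess("planted frames match each other beyond the plan",
                     "bad_config")
      }
      for (f in redo) {
        attempts[f + 1L] <- attempts[f + 1L] + 1L
        images[[f + 1L]] <- gen_frame(f)
      }
      if (round == max_attempts) {
        stop_mnctess("could not separate descriptors within attempt budget",
                     "fixture_failure")
      }
    }
  }

  list(
    images = images,
    manifest = tibble(frame_index = 0:(n_frames - 1L),
                      time_label = (0:(n_frames - 1L)) / 10,
                      repeat_of = copy_of)
  )
}

#' Frame sequence with a translating dominant blob
#'
#' One dominant blob moves `dx_per_frame` pixels per frame along x.
#' Ground-truth centroids are the blob centres, so downstream trajectory
#' recovery can be scored against known spacing. By default the sequence
#' is noise-free: with an integer `dx_per_frame` each frame is then an
#' exact translate of the previous one, so the recovered trajectory
#' spacing is exact up to border effects. With `noise_sd > 0` the noise
#' is reseeded per frame; because cluster maximality is an argmax over
#' near-tied degrees, refreshed noise makes the principal cluster hop
#' between cells of the dense seed annulus, and recovered trajectories
#' wander by several pixels around the true track.
#'
#' @param n_frames Number of frames.
#' @param dx_per_frame Horizontal displacement per frame in pixels.
#' @param seed Integer seed.
#' @param width,height Image size.
#' @param start_x,y0 Initial blob centre.
#' @param sigma,amplitude Blob shape.
#' @param noise_sd Per-frame noise sd.
#' @return List with `images` and `truth` (tibble `frame_index`, `x`, `y`).
#' @export
make_translating_sequence <- function(n_frames = 10L, dx_per_frame = 2,
                                      seed = 0L, width = 64L, height = 64L,
                                      start_x = 20, y0 = 32, sigma = 8,
                                      amplitude = 1, noise_sd = 0) {
  xs <- start_x + dx_per_frame * (0:(n_frames - 1L))
  if (any(xs < 0 | xs >= width)) {
    stop_mnctess("trajectory leaves the image bounds", "bad_config")
  }
  images <- lapply(seq_len(n_frames), function(k) {
    make_blob_image(width, height,
                    tibble(x = xs[k], y = y0, sigma = sigma,
                           amplitude = amplitude),
                    noise_sd = noise_sd, seed = frame_seed(seed, k - 1L))
  })
  list(images = images,
       truth = tibble(frame_index = 0:(n_frames - 1L), x = xs, y = y0))
}
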