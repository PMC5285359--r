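#' Describe the maximal nucleus clusters of one temporal frame
#'
#' Each maximal nucleus cluster is summarised by the feature vector used
#' for temporal matching: the gradient orientation of its nucleus
#' generating point and its adjacent-region count, plus the nucleus
#' centroid and area for trajectory export.
#'
#' @param tiling A `voronoi_tiling`, typically from [tessellate_image()]
#'   so that nucleus orientations are available.
#' @param mncs Maximal clusters; computed from the tiling when omitted.
#' @param frame_index 0-based position of the frame in its sequence.
#' @param time_label Optional time in seconds.
#' @return Tibble, one row per maximal cluster in
#'   [find_maximal_nucleus_clusters()] order: `frame_index`, `time_label`,
#'   `nucleus_id`, `nucleus_x`, `nucleus_y` (seed coordinates),
#'   `nucleus_theta` (degrees, `NA` for purely geometric tilings),
#'   `degree`, `centroid_x`, `centroid_y`, `nucleus_area`.
#' @export
describe_frame <- function(tiling, mncs = NULL, frame_index = 0L,
                           time_label = NA_real_) {
  if (is.null(mncs)) mncs <- find_maximal_nucleus_clusters(tiling)
  cent <- t(vapply(mncs$nucleus_id,
                   function(i) polygon_centroid(tiling$regions[[i]]),
                   numeric(2)))
  theta <- if ("theta" %in% names(tiling$points)) {
    tiling$points$theta[mncs$nucleus_id]
  } else {
    rep(NA_real_, nrow(mncs))
  }
  tibble(
    frame_index = as.integer(frame_index),
    time_label = as.numeric(time_label),
    nucleus_id = mncs$nucleus_id,
    nucleus_x = tiling$points$x[mncs$nucleus_id],
    nucleus_y = tiling$points$y[mncs$nucleus_id],
    nucleus_theta = theta,
    degree = mncs$degree,
    centroid_x = cent[, 1],
    centroid_y = cent[, 2],
    nucleus_area = tiling$areas[mncs$nucleus_id]
  )
}

check_frames <- function(frames) {
  if (!all(c("frame_index", "nucleus_theta", "degree") %in% names(frames))) {
    stop_mnctess("frames must be a bind of describe_frame() tables", "bad_frames")
  }
  if (length(unique(frames$frame_index)) < 2L) {
    stop_mnctess("need at least 2 frames", "few_frames")
  }
  invisible(frames)
}

#' Matching MNC descriptions across frames
#'
#' Two frames carry a matching description when some maximal cluster in
#' one and some maximal cluster in the other agree in their feature
#' vectors: nucleus orientation within `tol` degrees (circular difference
#' on the folded \[-90, 90) range) and, when `degree_exact`, identical
#' adjacent-region counts. Centroids and areas are deliberately not part
#' of the match: the comparison is between descriptions, not positions.
#'
#' @param frames Row-bound [describe_frame()] tables covering >= 2 frames.
#' @param tol Orientation tolerance in degrees (default 2).
#' @param degree_exact Require equal degrees (default `TRUE`).
#' @return Tibble of matching descriptor pairs ordered by `(i, j)`
#'   (frame indices, `i < j`): `i`, `j`, `time_i`, `time_j`, `id_i`,
#'   `id_j` (nucleus region ids), `delta_theta`, `degree_i`, `degree_j`.
#'   Zero rows when nothing matches.
#' @export
match_descriptions <- function(frames, tol = 2, degree_exact = TRUE) {
  check_frames(frames)
  if (tol < 0) stop_mnctess("tol must be >= 0", "bad_config")
  a <- dplyr::select(frames, i = "frame_index", time_i = "time_label",
                     id_i = "nucleus_id", theta_i = "nucleus_theta",
                     degree_i = "degree")
  b <- dplyr::select(frames, j = "frame_index", time_j = "time_label",
                     id_j = "nucleus_id", theta_j = "nucleus_theta",
                     degree_j = "degree")
  out <- tidyr::crossing(a, b) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(delta_theta = orientation_diff(.data$theta_i, .data$theta_j)) |>
    dplyr::filter(.data$delta_theta <= tol)
  if (degree_exact) out <- dplyr::filter(out, .data$degree_i == .data$degree_j)
  dplyr::arrange(out, .data$i, .data$j, .data$id_i, .data$id_j) |>
    dplyr::select("i", "j", "time_i", "time_j", "id_i", "id_j",
                  "delta_theta", "degree_i", "degree_j")
}

#' Antipodal frame pairs on the temporal circle
#'
#' Frames are placed uniformly, in order, on a circle (time passing
#' clockwise along the circumference). For an even number of frames the
#' pure antipodal pairs are exactly `(i, i + n/2)` at 180 degrees
#' separation. For odd n no pair is exactly antipodal; frames are paired
#' greedily in index order with the unpaired partner minimizing
#' `|separation - 180|` (ties to the smallest index), each frame used at
#' most once, leaving one frame unpaired.
#'
#' @param n_frames Number of frames (>= 2), or a [describe_frame()] bind
#'   from which the frame count is taken.
#' @return Tibble of 0-based frame-index pairs: `i`, `j` (`i < j`),
#'   `separation_deg` (angular separation on the circle).
#' @export
#' @examples
#' antipodal_pairs(12)  # (0,6) (1,7) ... (5,11)
antipodal_pairs <- function(n_frames) {
  if (is.data.frame(n_frames)) {
    n_frames <- length(unique(n_frames$frame_index))
  }
  n <- as.integer(n_frames)
  if (n < 2L) stop_mnctess("need at least 2 frames", "few_frames")
  sep <- function(i, j) {
    s <- (abs(i - j) %% n) * 360 / n
    pmin(s, 360 - s)
  }
  if (n %% 2L == 0L) {
    i <- 0:(n %/% 2L - 1L)
    return(tibble(i = i, j = i + n %/% 2L, separation_deg = 180))
  }
  paired <- logical(n)
  res <- list()
  for (i in 0:(n - 1L)) {
    if (paired[i + 1L]) next
    cand <- setdiff(which(!paired) - 1L, i)
    if (length(cand) == 0L) break
    dev <- abs(sep(i, cand) - 180)
    j <- cand[order(dev, cand)[1L]]
    paired[c(i, j) + 1L] <- TRUE
    res[[length(res) + 1L]] <- c(i, j)
  }
  m <- do.call(rbind, res)
  tibble(i = m[, 1], j = m[, 2], separation_deg = sep(m[, 1], m[, 2]))
}

#' Principal-MNC centroid trajectory of a sequence
#'
#' For each frame, the principal maximal cluster (highest degree, ties
#' broken by nucleus `(y, x)`) contributes its centroid, giving the
#' trajectory table that external trajectory comparisons consume.
#'
#' @inheritParams match_descriptions
#' @return Tibble in time order: `frame_index`, `time_label`,
#'   `centroid_x`, `centroid_y`, `degree`.
#' @export
centroid_trajectory <- function(frames) {
  check_frames(frames)
  frames |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$nucleus_y,
                   .data$nucleus_x, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame_index) |>
    dplyr::select("frame_index", "time_label", "centroid_x", "centroid_y",
                  "degree")
}
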