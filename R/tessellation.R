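#' Bounded Voronoi tessellation of a rectangle
#'
#' Tiles the rectangle `[0, width] x [0, height]` with the Voronoi regions
#' V(s) of the generating points: V(s) is the set of points of the
#' rectangle at least as near to s as to any other generating point
#' (Euclidean metric). Unbounded cells are clipped to the rectangle, so
#' every region is a convex polygon and the region areas partition the
#' rectangle area. The Delaunay/Dirichlet computation is delegated to
#' \pkg{deldir}; this wrapper fixes the bounded-cell, adjacency and
#' ordering conventions used throughout the package.
#'
#' Two regions are recorded as adjacent ("strongly near") when their
#' shared boundary segment is longer than `1e-9` pixels; contact at a
#' single vertex, as in co-circular configurations, is not adjacency.
#'
#' @param points Data frame with numeric columns `x`, `y`: generating
#'   point coordinates, all inside the rectangle. Extra columns (e.g.
#'   `theta`, `bin`, `magnitude` from [select_generating_points()]) are
#'   carried along. At least 2 points, no two closer than `1e-9`.
#' @param width,height Rectangle extent in pixels.
#' @return A `voronoi_tiling`: list with `width`, `height`, `points`
#'   (tibble, one row per region id in input order), `regions` (list of
#'   convex-polygon vertex matrices, counter-clockwise from the
#'   lexicographically smallest vertex), `areas` (shoelace areas), and
#'   `adjacency` (tibble of region-id pairs `i < j`).
#' @export
#' @examples
#' tl <- build_tessellation(data.frame(x = c(2, 8), y = c(5, 5)), 10, 10)
#' region_areas(tl)          # 50 50
#' region_adjacency(tl)      # regions 1 and 2 share the bisector edge
build_tessellation <- function(points, width, height) {
  points <- as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop_mnctess("points must have x and y columns", "bad_points")
  }
  n <- nrow(points)
  if (n < 2L) stop_mnctess("need at least 2 generating points", "few_points")
  if (any(points$x < 0 | points$x > width | points$y < 0 | points$y > height)) {
    stop_mnctess("all points must lie inside the bounds rectangle", "bad_points")
  }
  dup <- duplicated(round(cbind(points$x, points$y) / GEOM_TOL))
  if (any(dup)) {
    stop_mnctess("duplicate generating points (within 1e-9 px)", "duplicate_points")
  }

  dd <- deldir::deldir(points$x, points$y, rw = c(0, width, 0, height),
                       suppressMsge = TRUE, round = FALSE)
  tiles <- deldir::tile.list(dd)
  # deldir preserves input order when all points are distinct
  regions <- unname(lapply(tiles, function(tl) {
    normalize_polygon(cbind(tl$x, tl$y))
  }))
  areas <- unname(vapply(regions, function(v) abs(signed_area(v)), numeric(1)))

  seg <- dd$dirsgs
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  keep <- len > EDGE_EPS
  adjacency <- tibble(
    i = pmin(seg$ind1[keep], seg$ind2[keep]),
    j = pmax(seg$ind1[keep], seg$ind2[keep]),
    edge_length = len[keep]
  ) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(edge_length = sum(.data$edge_length), .groups = "drop") |>
    dplyr::arrange(.data$i, .data$j)

  structure(list(width = width, height = height, points = points,
                 regions = regions, areas = areas, adjacency = adjacency),
            class = "voronoi_tiling")
}

#' @export
print.voronoi_tiling <- function(x, ...) {
  cat(sprintf("<voronoi_tiling> %g x %g px, %d regions, %d adjacent pairs\n",
              x$width, x$height, length(x$regions), nrow(x$adjacency)))
  invisible(x)
}

#' Region area in square pixels
#'
#' Shoelace area of the clipped region polygon.
#'
#' @param tiling A [build_tessellation()] result.
#' @param id Region id (1-based row of `tiling$points`).
#' @return Nonnegative area.
#' @export
region_area <- function(tiling, id) {
  check_region_id(tiling, id)
  tiling$areas[id]
}

#' All region areas
#' @inheritParams region_area
#' @return Numeric vector of areas, one per region.
#' @export
region_areas <- function(tiling) tiling$areas

#' Edge-sharing adjacency relation of a tiling
#'
#' @inheritParams region_area
#' @return Tibble with one row per unordered adjacent pair: `i`, `j`
#'   (`i < j`) and `edge_length`, the length of the shared boundary.
#' @export
region_adjacency <- function(tiling) tiling$adjacency

#' Ids of the regions strongly near a region
#' @inheritParams region_area
#' @return Sorted integer vector of neighbouring region ids.
#' @export
region_neighbors <- function(tiling, id) {
  check_region_id(tiling, id)
  adj <- tiling$adjacency
  sort(c(adj$j[adj$i == id], adj$i[adj$j == id]))
}

check_region_id <- function(tiling, id) {
  if (any(id < 1L | id > length(tiling$regions))) {
    stop_mnctess("unknown region id", "bad_id")
  }
}

#' Nucleus cluster of a region
#'
#' The nucleus cluster of a region is the region itself (the nucleus)
#' together with all regions strongly near it, i.e. sharing a boundary
#' edge of positive length.
#'
#' @inheritParams region_area
#' @return One-row tibble: `nucleus_id`, `degree` (number of adjacent
#'   regions), `adjacent_ids` (list column), `is_maximal` (whether the
#'   degree attains the tiling-wide maximum).
#' @export
nucleus_cluster <- function(tiling, id) {
  check_region_id(tiling, id)
  adj_ids <- region_neighbors(tiling, id)
  degs <- cluster_degrees(tiling)
  tibble(nucleus_id = as.integer(id), degree = length(adj_ids),
         adjacent_ids = list(adj_ids),
         is_maximal = length(adj_ids) == max(degs))
}

# Degree (adjacent-region count) of every region.
cluster_degrees <- function(tiling) {
  adj <- tiling$adjacency
  tabulate(c(adj$i, adj$j), nbins = length(tiling$regions))
}

#' Maximal nucleus clusters of a tiling
#'
#' A maximal nucleus cluster (MNC) is a nucleus cluster whose nucleus has
#' the highest number of strongly-near regions in the whole tiling. Ties
#' are real - many images carry more than one MNC - so all clusters
#' attaining the maximum degree are returned.
#'
#' @inheritParams region_area
#' @return Tibble, one row per MNC, ordered by (degree desc, nucleus
#'   `(y, x)`): columns as in [nucleus_cluster()].
#' @export
#' @examples
#' pts <- expand.grid(x = c(5, 15, 25), y = c(5, 15, 25))
#' tl <- build_tessellation(pts, 30, 30)
#' find_maximal_nucleus_clusters(tl)  # the centre region, degree 4
find_maximal_nucleus_clusters <- function(tiling) {
  degs <- cluster_degrees(tiling)
  top <- which(degs == max(degs))
  ord <- order(tiling$points$y[top], tiling$points$x[top])
  top <- top[ord]
  tibble(nucleus_id = as.integer(top), degree = degs[top],
         adjacent_ids = lapply(top, function(i) region_neighbors(tiling, i)),
         is_maximal = TRUE)
}

#' Tessellate an image end-to-end
#'
#' Convenience composition: gradient field, orientation-unique generating
#' points, bounded Voronoi tessellation. Generating points are placed at
#' pixel centres, i.e. pixel `(x, y)` seeds the point `(x + 0.5, y + 0.5)`
#' in the `[0, width] x [0, height]` rectangle.
#'
#' @param img Image matrix ([as_scalar_image()] or plain).
#' @inheritParams select_generating_points
#' @return A `voronoi_tiling` whose `points` tibble keeps the pixel
#'   indices as `pixel_x`, `pixel_y` and the seed coordinates as `x`, `y`,
#'   plus `theta`, `bin`, `magnitude`.
#' @export
tessellate_image <- function(img, bins = 1024L,
                             mode = c("representative", "strict"),
                             max_points = 300L, min_points = 4L) {
  gf <- gradient_field(img)
  pts <- select_generating_points(gf, bins = bins, mode = match.arg(mode),
                                  max_points = max_points,
                                  min_points = min_points)
  pts <- dplyr::mutate(pts, pixel_x = .data$x, pixel_y = .data$y,
                       x = .data$x + 0.5, y = .data$y + 0.5)
  build_tessellation(pts, gf$width, gf$height)
}

#' Tidy a tiling into a per-region table
#'
#' @param x A `voronoi_tiling`.
#' @param ... Unused.
#' @return Tibble with one row per region: `id`, the generating-point
#'   columns, `area`, `degree`, `is_mnc` (member of any maximal nucleus
#'   cluster, nucleus or adjacent).
#' @method tidy voronoi_tiling
#' @export
tidy.voronoi_tiling <- function(x, ...) {
  degs <- cluster_degrees(x)
  mncs <- find_maximal_nucleus_clusters(x)
  in_mnc <- sort(unique(c(mncs$nucleus_id, unlist(mncs$adjacent_ids))))
  out <- dplyr::mutate(x$points, id = dplyr::row_number(), .before = 1)
  out$area <- x$areas
  out$degree <- degs
  out$is_mnc <- out$id %in% in_mnc
  out
}

#' One-row summary of a tiling
#'
#' @param x A `voronoi_tiling`.
#' @param ... Unused.
#' @return Tibble: region count, adjacency count, max degree, number of
#'   maximal nucleus clusters, total area.
#' @method glance voronoi_tiling
#' @export
glance.voronoi_tiling <- function(x, ...) {
  degs <- cluster_degrees(x)
  tibble(n_regions = length(x$regions), n_adjacent_pairs = nrow(x$adjacency),
         max_degree = max(degs), n_mnc = sum(degs == max(degs)),
         total_area = sum(x$areas))
}

#' Export a tiling as a JSON string or file
#'
#' Serializes points, polygon vertex lists, adjacency pairs and maximal
#' nucleus cluster ids; the export round-trips the quantities needed to
#' recompute entropy profiles.
#'
#' @param tiling A `voronoi_tiling`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
tiling_to_json <- function(tiling, path = NULL) {
  mncs <- find_maximal_nucleus_clusters(tiling)
  obj <- list(
    width = tiling$width, height = tiling$height,
    points = tiling$points,
    areas = tiling$areas,
    regions = lapply(tiling$regions, function(v) unname(v)),
    adjacency = tiling$adjacency,
    mnc_ids = mncs$nucleus_id
  )
  # I(17) significant digits: lossless round-trip for IEEE doubles
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
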