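test_that("two points split the rectangle along the perpendicular bisector", {
  tl <- build_tessellation(data.frame(x = c(2, 8), y = c(5, 5)), 10, 10)
  expect_equal(region_areas(tl), c(50, 50))
  adj <- region_adjacency(tl)
  expect_equal(nrow(adj), 1L)
  expect_equal(adj$edge_length, 10)
  # both regions tie at degree 1, so both are maximal
  mncs <- find_maximal_nucleus_clusters(tl)
  expect_equal(mncs$nucleus_id, c(1L, 2L))
  expect_equal(mncs$degree, c(1L, 1L))
})

test_that("four symmetric points give four squares without diagonal adjacency", {
  pts <- data.frame(x = c(2.5, 7.5, 2.5, 7.5), y = c(2.5, 2.5, 7.5, 7.5))
  tl <- build_tessellation(pts, 10, 10)
  expect_equal(region_areas(tl), rep(25, 4))
  adj <- region_adjacency(tl)
  pairs <- paste(adj$i, adj$j)
  # the four bisectors meet at the centre point: side contacts only
  expect_setequal(pairs, c("1 2", "1 3", "2 4", "3 4"))
  expect_false(any(pairs %in% c("1 4", "2 3")))
})

test_that("the centre of a 3x3 grid is the unique degree-4 maximal nucleus", {
  tl <- grid9_tiling()
  # region 5 is the centre point (15, 15)
  cl <- nucleus_cluster(tl, 5L)
  expect_equal(cl$degree, 4L)
  expect_setequal(cl$adjacent_ids[[1]], c(2L, 4L, 6L, 8L))
  expect_true(cl$is_maximal)
  mncs <- find_maximal_nucleus_clusters(tl)
  expect_equal(mncs$nucleus_id, 5L)
})

test_that("degenerate inputs are rejected", {
  expect_error(build_tessellation(data.frame(x = 5, y = 5), 10, 10),
               class = "mnctess_error_few_points")
  expect_error(
    build_tessellation(data.frame(x = c(1, 1 + 1e-12), y = c(1, 1)), 10, 10),
    class = "mnctess_error_duplicate_points")
  expect_error(build_tessellation(data.frame(x = c(2, 11), y = c(2, 2)), 10, 10),
               class = "mnctess_error_bad_points")
  tl <- grid9_tiling()
  expect_error(region_area(tl, 10L), class = "mnctess_error_bad_id")
  expect_error(nucleus_cluster(tl, 0L), class = "mnctess_error_bad_id")
})

test_that("collinear points tile the rectangle as parallel strips", {
  tl <- build_tessellation(data.frame(x = c(2, 4, 6, 8), y = rep(5, 4)), 10, 10)
  expect_equal(region_areas(tl), c(30, 20, 20, 30))
  expect_equal(nrow(region_adjacency(tl)), 3L)
})

test_that("random tilings satisfy partition, nearest-point and convexity invariants", {
  pc <- expand.grid(x = 0:63 + 0.5, y = 0:63 + 0.5)
  for (seed in 1:8) {
    pts <- random_points(3200 + seed, 10 + 5 * seed)
    tl <- build_tessellation(pts, 64, 64)
    # partition of the rectangle
    expect_lt(abs(sum(region_areas(tl)) - 64 * 64) / (64 * 64), 1e-6)
    # membership by polygon test equals nearest-generator labelling
    nn <- oracle_nearest(pc$x, pc$y, pts$x, pts$y)
    lab <- oracle_region_label(tl, pc$x, pc$y)
    ok <- !is.na(nn)
    expect_gte(mean(lab[ok] == nn[ok]), 0.995)
    for (i in seq_along(tl$regions)) {
      v <- tl$regions[[i]]
      # convexity: all cross products of the CCW walk are non-negative
      nv <- nrow(v)
      nxt <- c(2:nv, 1); nx2 <- c(3:nv, 1, 2)
      cr <- (v[nxt, 1] - v[, 1]) * (v[nx2, 2] - v[nxt, 2]) -
        (v[nxt, 2] - v[, 2]) * (v[nx2, 1] - v[nxt, 1])
      expect_true(all(cr >= -1e-9))
      # canonical storage: CCW starting at the lexicographically smallest vertex
      expect_identical(order(v[, 1], v[, 2])[1], 1L)
      # region contains its generating point
      expect_true(!is.na(oracle_region_label(
        structure(list(regions = tl$regions[i]), class = "voronoi_tiling"),
        pts$x[i], pts$y[i])))
    }
  }
})

test_that("adjacency and maximal clusters equal exhaustive geometric oracles", {
  for (seed in 1:8) {
    n <- 10 + 5 * seed
    pts <- random_points(3300 + seed, n)
    tl <- build_tessellation(pts, 64, 64)
    ex <- oracle_adjacency_exact(pts$x, pts$y, 64, 64)
    impl <- as.matrix(region_adjacency(tl)[, c("i", "j")])
    expect_equal(unname(impl[order(impl[, 1], impl[, 2]), , drop = FALSE]),
                 ex[order(ex[, 1], ex[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    deg <- tabulate(c(ex[, 1], ex[, 2]), nbins = n)
    for (id in seq_len(n)) {
      expect_equal(nucleus_cluster(tl, id)$degree, deg[id])
    }
    mncs <- find_maximal_nucleus_clusters(tl)
    expect_equal(sort(mncs$nucleus_id), which(deg == max(deg)))
    # symmetric, irreflexive by construction
    adj <- region_adjacency(tl)
    expect_true(all(adj$i < adj$j))
  }
})

test_that("shoelace areas match subsampled pixel counting within 2 percent", {
  sub <- 4
  g <- seq(0.5 / sub, 64 - 0.5 / sub, by = 1 / sub)
  pc <- expand.grid(x = g, y = g)
  pts <- random_points(777, 20)
  tl <- build_tessellation(pts, 64, 64)
  nn <- oracle_nearest(pc$x, pc$y, pts$x, pts$y, tie_tol = 0)
  raster_area <- tabulate(nn, nbins = 20) / sub^2
  big <- region_areas(tl) >= 20  # pixel counting is meaningless for slivers
  expect_true(any(big))
  expect_lt(max(abs(raster_area[big] - region_areas(tl)[big]) /
                  region_areas(tl)[big]), 0.02)
})

test_that("tiling JSON export round-trips the entropy inputs", {
  tl <- clustered_grid_tiling()
  path <- withr::local_tempfile(fileext = ".json")
  tiling_to_json(tl, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$areas, region_areas(tl))
  expect_equal(back$mnc_ids, find_maximal_nucleus_clusters(tl)$nucleus_id)
  # profile recomputed from exported areas is bit-identical
  prof <- entropy_profile(tl)
  ids <- sort(unique(c(back$mnc_ids,
                       unlist(find_maximal_nucleus_clusters(tl)$adjacent_ids))))
  p_mnc <- region_probability(back$areas[ids])
  p_non <- region_probability(back$areas[-ids])
  h <- vapply(prof$profile$beta, function(b) renyi_entropy(p_mnc, b), numeric(1))
  expect_identical(h, prof$profile$h_mnc)
})
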