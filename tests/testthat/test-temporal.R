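test_that("frame descriptors summarise the maximal clusters deterministically", {
  tl <- grid9_tiling()
  d <- describe_frame(tl, frame_index = 0L, time_label = 0.1)
  expect_equal(nrow(d), 1L)
  expect_equal(d$degree, 4L)
  expect_equal(c(d$centroid_x, d$centroid_y), c(15, 15))
  expect_equal(d$time_label, 0.1)

  # ties propagate: both regions of a 2-point tiling are described
  tl2 <- build_tessellation(data.frame(x = c(2, 8), y = c(5, 5)), 10, 10)
  d2 <- describe_frame(tl2, frame_index = 3L)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$frame_index, c(3L, 3L))
})

test_that("matching descriptions finds planted repeats and nothing else", {
  # 13 frames labelled 0.1..1.3 s; frames 1 and 12 carry identical features
  thetas <- seq(-80, 80, length.out = 13)
  frames <- dplyr::bind_rows(lapply(0:12, function(f) {
    descriptor_row(f, theta = if (f == 12) thetas[2] else thetas[f + 1],
                   degree = if (f == 12) 5L else 5L + (f %% 3L),
                   time = (f + 1) / 10)
  }))
  frames$degree[2] <- 5L  # frame index 1
  mm <- match_descriptions(frames, tol = 2, degree_exact = TRUE)
  expect_equal(dplyr::distinct(mm, i, j), tibble::tibble(i = 1L, j = 12L))
  expect_equal(mm$time_i, 0.2)
  expect_equal(mm$time_j, 1.3)
})

test_that("saturated and empty matching cases behave", {
  same <- dplyr::bind_rows(lapply(0:4, function(f)
    descriptor_row(f, theta = 10, degree = 4L)))
  mm <- match_descriptions(same, tol = 0)
  expect_equal(nrow(mm), choose(5, 2))
  apart <- dplyr::bind_rows(lapply(0:4, function(f)
    descriptor_row(f, theta = -80 + 30 * f, degree = 3L + f)))
  expect_equal(nrow(match_descriptions(apart, tol = 2)), 0L)
})

test_that("matching is circular at the orientation wrap and monotone in tol", {
  fr <- dplyr::bind_rows(descriptor_row(0, theta = -89.5, degree = 4L),
                         descriptor_row(1, theta = 89.5, degree = 4L),
                         descriptor_row(2, theta = 60, degree = 4L))
  expect_equal(nrow(match_descriptions(fr, tol = 2)), 1L)  # wrap distance 1
  m1 <- match_descriptions(fr, tol = 2)
  m2 <- match_descriptions(fr, tol = 40)
  expect_true(nrow(m2) > nrow(m1))
  key <- function(m) paste(m$i, m$j)
  expect_true(all(key(m1) %in% key(m2)))
  # degree filter is an AND with the angle rule
  fr$degree[3] <- 9L
  m3 <- match_descriptions(fr, tol = 180 / 2, degree_exact = TRUE)
  expect_false(any(m3$i == 2 | m3$j == 2))
})

test_that("antipodal pairing is exact for even counts", {
  ap <- antipodal_pairs(12)
  expect_equal(ap$i, 0:5)
  expect_equal(ap$j, 6:11)
  expect_true(all(ap$separation_deg == 180))
  ap2 <- antipodal_pairs(2)
  expect_equal(nrow(ap2), 1L)
  expect_equal(c(ap2$i, ap2$j), c(0L, 1L))
})

test_that("odd-count antipodal pairing attains the exhaustive optimum", {
  for (n in c(3, 5, 7, 9, 11, 13, 15)) {
    ap <- antipodal_pairs(n)
    expect_equal(nrow(ap), (n - 1) %/% 2)
    expect_equal(length(unique(c(ap$i, ap$j))), n - 1L)  # each frame at most once
    cost <- sum(abs(ap$separation_deg - 180))
    or <- oracle_antipodal(n)
    expect_equal(cost, or$cost, tolerance = 1e-9)
  }
})

test_that("trajectories are constant for static input and exact for translation", {
  tr0 <- make_translating_sequence(4, 0, seed = 3)
  f0 <- dplyr::bind_rows(lapply(seq_along(tr0$images), function(k)
    describe_frame(tessellate_image(tr0$images[[k]]), frame_index = k - 1L)))
  tj0 <- centroid_trajectory(f0)
  expect_equal(length(unique(tj0$centroid_x)), 1L)
  expect_equal(length(unique(tj0$centroid_y)), 1L)

  tr <- make_translating_sequence(8, 2, seed = 3)
  fr <- dplyr::bind_rows(lapply(seq_along(tr$images), function(k)
    describe_frame(tessellate_image(tr$images[[k]]), frame_index = k - 1L)))
  tj <- centroid_trajectory(fr)
  expect_equal(nrow(tj), 8L)
  expect_true(all(diff(tj$centroid_x) > 0))
  # noise-free integer translation: recovered spacing is exact well inside
  # the +-1.5 px tolerance budgeted for tessellation jitter
  expect_lt(stats::median(abs(diff(tj$centroid_x) - 2)), 0.1)
  expect_lt(max(abs(diff(tj$centroid_y))), 0.1)
})

test_that("trajectory tables round-trip through CSV", {
  tr <- make_translating_sequence(4, 2, seed = 5)
  fr <- dplyr::bind_rows(lapply(seq_along(tr$images), function(k)
    describe_frame(tessellate_image(tr$images[[k]]), frame_index = k - 1L,
                   time_label = (k - 1) / 10)))
  tj <- centroid_trajectory(fr)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tj, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(tibble::as_tibble(back), tj, tolerance = 1e-12)
})

test_that("match sets grow monotonically with tolerance on pipeline output", {
  seqr <- make_repeat_sequence(5, list(c(0L, 4L)), seed = 2, verify = FALSE)
  fr <- dplyr::bind_rows(lapply(seq_along(seqr$images), function(k)
    describe_frame(tessellate_image(seqr$images[[k]]), frame_index = k - 1L)))
  key <- function(m) paste(m$i, m$j, m$id_i, m$id_j)
  m_small <- match_descriptions(fr, tol = 1)
  m_big <- match_descriptions(fr, tol = 10)
  expect_true(all(key(m_small) %in% key(m_big)))
})
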