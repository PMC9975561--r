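test_that("point-simplex distance matches closed forms and a grid oracle", {
  # containment
  expect_identical(point_simplex_distance(c(0.2, 0.2),
                                          tri(c(0, 0), c(1, 0), c(0, 1))), 0)
  # perpendicular to an endpoint-adjacent region of a segment
  expect_equal(point_simplex_distance(c(0, 2), rbind(c(0, 0), c(1, 0))), 2)
  # off a triangle's corner: 3/sqrt(2), cross-checked by a dense grid oracle
  s <- tri(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(point_simplex_distance(c(2, 2), s), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(grid_simplex_distance(c(2, 2), s, n = 400), 3 / sqrt(2),
               tolerance = 1e-3)
  # random agreement with the grid oracle, 2D segments and triangles
  set.seed(5)
  for (i in 1:15) {
    v <- matrix(rnorm(6), 3, 2)
    p <- rnorm(2, sd = 2)
    expect_equal(point_simplex_distance(p, v), grid_simplex_distance(p, v),
                 tolerance = 2e-2)
  }
  expect_error(point_simplex_distance(c(0, 0, 0), rbind(c(0, 0), c(1, 0))),
               class = "dualex_invalid_argument")
})

test_that("3D point-simplex distance handles tetrahedra and faces", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_identical(point_simplex_distance(c(0.2, 0.2, 0.2), tet), 0)
  expect_equal(point_simplex_distance(c(-1, 0, 0), tet), 1)
  expect_equal(point_simplex_distance(c(1, 1, 1), tet), sqrt(3) * (2 / 3),
               tolerance = 1e-9) # distance to the x+y+z=1 face plane point
})

test_that("locate_point returns all containing simplices", {
  wc <- unit_square_complex()
  expect_identical(locate_point(wc, c(0.75, 0.25)), 1L)   # strict interior
  expect_identical(locate_point(wc, c(0.25, 0.75)), 2L)
  expect_identical(locate_point(wc, c(0.5, 0.5)), c(1L, 2L)) # shared diagonal
  expect_identical(locate_point(wc, c(2, 2)), integer(0))
})

test_that("absorption Case 1 reweights without touching geometry", {
  wc <- unit_square_complex(c(1, 2))
  r <- absorb_point(wc, c(0.75, 0.25))
  expect_identical(r$weights, c(2, 2))
  expect_identical(r$simplices, wc$simplices)   # bit-identical geometry
  r2 <- absorb_point(wc, c(0.5, 0.5))           # shared boundary: both +1
  expect_identical(r2$weights, c(2, 3))
  expect_identical(attr(r, "case"), 1)
})

test_that("absorption Case 2 extends convexly with weight-1 simplices", {
  # collinear extension of a 1-complex
  wc <- weighted_complex(list(rbind(c(0, 0), c(1, 0))), 3)
  r <- absorb_point(wc, c(2, 0))
  expect_identical(r$weights, c(3, 1))
  expect_equal(r$simplices[[2]], rbind(c(1, 0), c(2, 0)), ignore_attr = TRUE)
  # 2D extension keeps old simplices and weights intact
  wc <- unit_square_complex(c(5, 7))
  r <- absorb_point(wc, c(2, 0.5))
  expect_identical(r$weights[1:2], c(5, 7))
  expect_identical(r$simplices[1:2], wc$simplices)
  expect_true(all(r$weights[-(1:2)] == 1))
  expect_identical(attr(r, "case"), 2)
  validate_complex(r)
  # union equals hull of old vertices plus p (area accounting)
  V <- rbind(do.call(rbind, wc$simplices), c(2, 0.5))
  expect_equal(complex_area(r), hull_area(V), tolerance = 1e-9)
  expect_error(absorb_point(wc, c(NA, 1)), class = "dualex_invalid_argument")
})

test_that("absorbing outside the affine span raises intrinsic dimension", {
  wc <- weighted_complex(list(rbind(c(0, 0), c(1, 0)),
                              rbind(c(1, 0), c(2, 0))), c(3, 1))
  r <- absorb_point(wc, c(1, 1))
  expect_identical(attr(r, "case"), "2-cone")
  expect_true(all(vapply(r$simplices, nrow, 1L) == 3L))
  expect_true(all(r$weights == 1))
  validate_complex(r)
  # a single point grows into a segment
  p0 <- weighted_complex(list(rbind(c(1, 2))), 1)
  r2 <- absorb_point(p0, c(3, 2))
  expect_identical(vapply(r2$simplices, nrow, 1L), 2L)
})

test_that("absorption preserves convexity, homogeneity, and monotone growth", {
  set.seed(33)
  for (rep in 1:6) {
    wc <- weighted_complex(list(rbind(c(0, 0), c(1, 0), c(0, 1))), 1)
    prev_vertices <- complex_vertices(wc)
    prev_total <- sum(wc$weights)
    for (i in 1:12) {
      p <- runif(2, -3, 4)
      wc <- absorb_point(wc, p)
      validate_complex(wc)   # convex union + homogeneity
      # total weight strictly increases
      expect_gt(sum(wc$weights), prev_total)
      prev_total <- sum(wc$weights)
      # the point-set never shrinks: all previous vertices still covered
      for (j in seq_len(nrow(prev_vertices)))
        expect_gt(length(locate_point(wc, prev_vertices[j, ])), 0)
      prev_vertices <- complex_vertices(wc)
      # union is exactly the hull of its vertices (area accounting)
      expect_equal(complex_area(wc), hull_area(prev_vertices), tolerance = 1e-8)
    }
  }
})

test_that("distance zero coincides with membership in a located simplex", {
  set.seed(44)
  wc <- random_grown_complex(12)
  for (i in 1:100) {
    p <- runif(2, -3, 4)
    d <- vapply(wc$simplices, function(s) point_simplex_distance(p, s), 0)
    loc <- locate_point(wc, p)
    expect_identical(length(loc) > 0, any(d <= 1e-9))
  }
})

test_that("absorb_trace updates every frame and increments the iteration", {
  frames <- list(unit_square_complex(), unit_square_complex(c(2, 2)))
  sil <- silhouette("w", frames, iteration = 3L)
  m <- trajectory(rbind(c(0.5, 0.25), c(0.25, 0.5)))  # interior at both t
  s2 <- absorb_trace(sil, m)
  expect_identical(s2$iteration, 4L)
  expect_identical(attr(s2, "cases"), c(1L, 1L))
  for (t in 1:2) {
    expect_identical(s2$frames[[t]]$simplices, frames[[t]]$simplices)
    expect_identical(sum(s2$frames[[t]]$weights), sum(frames[[t]]$weights) + 1)
  }
  # the weighted-centroid path is interior: Case 1 at every t
  cen <- do.call(rbind, lapply(sil$frames, dualex:::complex_centroid))
  s3 <- absorb_trace(sil, trajectory(cen))
  expect_identical(attr(s3, "cases"), c(1L, 1L))
  # a single exterior point triggers Case 2 only at its own frame
  m2 <- trajectory(rbind(c(0.5, 0.25), c(5, 5)))
  s4 <- absorb_trace(sil, m2)
  expect_identical(attr(s4, "cases"), c(1L, 2L))
  expect_identical(length(s4$frames[[1]]$simplices), 2L)
  expect_gt(length(s4$frames[[2]]$simplices), 2L)
  # trace of the wrong length is resampled onto the silhouette's T
  m3 <- trajectory(rbind(c(0.5, 0.25), c(0.5, 0.4), c(0.25, 0.5)))
  expect_identical(absorb_trace(sil, m3)$iteration, 4L)
})

test_that("silhouette JSON round trip is exact", {
  set.seed(55)
  wc <- random_grown_complex(8)
  sil <- silhouette("word-1", list(wc, unit_square_complex(c(pi, 1 / 3))),
                    iteration = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  save_silhouette(sil, path)
  s2 <- load_silhouette(path)
  expect_identical(s2$concept, "word-1")
  expect_identical(s2$iteration, 7L)
  for (t in 1:2) {
    expect_identical(s2$frames[[t]]$weights, sil$frames[[t]]$weights)
    expect_equal(s2$frames[[t]]$simplices, sil$frames[[t]]$simplices,
                 ignore_attr = TRUE, tolerance = 0)
  }
  # truncated file fails with a schema error
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), bad)
  expect_error(load_silhouette(bad), class = "dualex_schema_error")
})
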