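# tiny expressive lexicon over a shared map, with exemplars at controlled
# distances from a reference path
tiny_lexicon <- function(n = 4, seed = 1) {
  set.seed(seed)
  words <- list()
  for (i in seq_len(n)) {
    path <- cbind(c(0, 5) + i, c(0, 0))
    frames <- list(unit_square_complex(c(i, 1)),
                   unit_square_complex(c(1, i + 1)))
    words[[sprintf("w%02d", i)]] <- list(
      silhouette = silhouette(sprintf("w%02d", i), frames),
      exemplar = exemplar(sprintf("w%02d", i), path))
  }
  lexicon(words)
}

test_that("neighbour ranking orders by perceptual distance with stable ties", {
  lex <- tiny_lexicon(4)
  target <- exemplar("new", cbind(c(0, 5), c(0, 0)))  # w's offset by i in x
  nb <- rank_neighbors(target, lex, 4)
  expect_identical(nb$concept, c("w01", "w02", "w03", "w04"))
  expect_equal(nb$distance, 1:4)
  # exact-match target ranks first at distance 0
  nb1 <- rank_neighbors(lex$expressive$w02$exemplar, lex, 1)
  expect_identical(nb1$concept, "w02")
  expect_identical(nb1$distance, 0)
  # full ordering matches a brute-force sort oracle
  set.seed(3)
  target2 <- exemplar("new", matrix(rnorm(4, sd = 3), 2, 2))
  d <- vapply(lex$expressive, function(w)
    trajectory_distance(w$exemplar$trajectory, target2$trajectory), 0)
  expect_identical(rank_neighbors(target2, lex, 4)$concept,
                   names(sort(d)))
  expect_error(rank_neighbors(target, lex, 9),
               class = "dualex_insufficient_vocabulary")
})

test_that("silhouette alignment resamples to the longest by frame lookup", {
  f <- unit_square_complex()
  s3 <- silhouette("a", list(f, unit_square_complex(c(2, 1)), f))
  s5 <- silhouette("b", rep(list(f), 5))
  al <- align_silhouettes(list(s3, s5))
  expect_length(al[[1]]$frames, 5)
  expect_length(al[[2]]$frames, 5)
  # index map oracle: nearest original frame at uniform parameters
  idx <- floor(1 + (0:4) * (3 - 1) / (5 - 1) + 0.5)
  for (t in 1:5)
    expect_identical(al[[1]]$frames[[t]]$weights, s3$frames[[idx[t]]]$weights)
  # equal lengths untouched; single silhouette untouched
  expect_identical(align_silhouettes(list(s5))[[1]], s5)
  al2 <- align_silhouettes(list(s3, s3))
  expect_identical(al2[[1]], s3)
})

test_that("weight scaling matches the worked example exactly", {
  s <- scale_weights(list(c(3, 4), c(5, 8), c(2, 1)))
  expect_identical(s$weights, list(c(6, 8), c(5, 8), c(8, 4)))
  expect_identical(s$global_max, 8)
  ex <- asil_scaling_example()
  expect_identical(ex$scaled, list(c(6, 8), c(5, 8), c(8, 4)))
  expect_identical(ex$global_max, 8)
})

test_that("weight scaling equalises maxima and is scale invariant", {
  set.seed(12)
  for (i in 1:10) {
    ws <- lapply(seq_len(sample(2:4, 1)), function(j) runif(sample(1:5, 1), 0.1, 9))
    s <- scale_weights(ws)
    maxima <- vapply(s$weights, max, 0)
    expect_equal(maxima, rep(s$global_max, length(ws)))
    # relative weights preserved within each silhouette
    for (j in seq_along(ws))
      expect_equal(s$weights[[j]] / max(s$weights[[j]]), ws[[j]] / max(ws[[j]]))
    # multiplying one input by c > 0 leaves the normalised pattern
    # unchanged (and the output itself whenever the global maximum is
    # unaffected, e.g. shrinking a silhouette)
    ws2 <- ws; ws2[[1]] <- ws2[[1]] * 3.7
    s2 <- scale_weights(ws2)
    expect_equal(lapply(s2$weights, function(w) w / s2$global_max),
                 lapply(s$weights, function(w) w / s$global_max))
    # rescaling a silhouette that does not hold the global maximum leaves
    # the entire scaled output unchanged
    jm <- which.max(vapply(ws, max, 0))
    jo <- setdiff(seq_along(ws), jm)[1]
    ws3 <- ws; ws3[[jo]] <- ws3[[jo]] * 0.5
    expect_equal(scale_weights(ws3)$weights, s$weights)
  }
  # single silhouette: unchanged
  expect_equal(scale_weights(list(c(2, 5)))$weights[[1]], c(2, 5))
})

test_that("combining identical frames sums weights over one region", {
  f1 <- weighted_complex(list(rbind(c(0, 0), c(2, 0), c(0, 2))), 3)
  f2 <- weighted_complex(list(rbind(c(0, 0), c(2, 0), c(0, 2))), 5)
  out <- combine_frames(list(f1, f2))
  expect_equal(complex_area(out), 2, tolerance = 1e-9)
  # every piece of the triangle carries weight 3 + 5
  expect_true(all(abs(out$weights - 8) < 1e-9))
  validate_complex(out)
})

test_that("combining disjoint frames keeps own weights and fills gaps with 1", {
  f1 <- weighted_complex(list(rbind(c(0, 0), c(1, 0), c(0, 1))), 4)
  f2 <- weighted_complex(list(rbind(c(5, 0), c(6, 0), c(6, 1))), 9)
  out <- combine_frames(list(f1, f2))
  validate_complex(out)
  # piecewise weight function: 4 on source 1, 9 on source 2, 1 on the gap
  set.seed(2)
  V <- unique(do.call(rbind, c(f1$simplices, f2$simplices)))
  checked <- 0
  for (i in 1:300) {
    lam <- stats::rexp(nrow(V)); lam <- lam / sum(lam)
    p <- colSums(V * lam)
    d1 <- point_simplex_distance(p, f1$simplices[[1]])
    d2 <- point_simplex_distance(p, f2$simplices[[1]])
    loc <- locate_point(out, p)
    if (length(loc) != 1) next   # skip points on internal boundaries
    in1 <- d1 <= 1e-9; in2 <- d2 <= 1e-9
    if (min(d1, d2) < 1e-6 && !in1 && !in2) next
    expected <- if (in1 && in2) 13 else if (in1) 4 else if (in2) 9 else 1
    expect_equal(out$weights[loc], expected)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("combined weight mass satisfies the covering-sum volume identity", {
  # exact accounting: sum(w * area) over the output equals the sum of
  # scaled source masses plus 1 * uncovered hull area, cross-checked by
  # Monte-Carlo integration of the piecewise weight function
  set.seed(31)
  f1 <- weighted_complex(list(rbind(c(0, 0), c(3, 0), c(1, 2)),
                              rbind(c(0, 0), c(1, 2), c(-1, 2))), c(3, 4))
  f2 <- weighted_complex(list(rbind(c(1, 0), c(4, 1), c(2, 3))), 5)
  sc <- scale_weights(list(f1, f2))
  out <- combine_frames(sc)
  validate_complex(out)
  lhs <- sum(out$weights * vapply(out$simplices, tri_area, 0))
  # Monte-Carlo oracle over the hull bounding box
  V <- unique(do.call(rbind, c(f1$simplices, f2$simplices)))
  n_mc <- 40000
  P <- cbind(runif(n_mc, min(V[, 1]), max(V[, 1])),
             runif(n_mc, min(V[, 2]), max(V[, 2])))
  box_area <- diff(range(V[, 1])) * diff(range(V[, 2]))
  wfun <- vapply(seq_len(n_mc), function(i) {
    p <- P[i, ]
    cov1 <- vapply(sc$frames[[1]]$simplices, function(s)
      point_simplex_distance(p, s) <= 1e-9, TRUE)
    cov2 <- vapply(sc$frames[[2]]$simplices, function(s)
      point_simplex_distance(p, s) <= 1e-9, TRUE)
    w <- sum(sc$frames[[1]]$weights[cov1]) + sum(sc$frames[[2]]$weights[cov2])
    if (w > 0) return(w)
    if (length(locate_point(out, p)) > 0) 1 else 0   # in-hull gap vs outside
  }, 0)
  mc <- mean(wfun) * box_area
  se <- stats::sd(wfun) * box_area / sqrt(n_mc)
  expect_lt(abs(lhs - mc), 4 * se)
})

test_that("combined frames refine the arrangement of overlapping sources", {
  # random interior points: output weight = sum of covering scaled source
  # weights, or 1 in uncovered hull gaps (exact within 1e-9)
  set.seed(41)
  f1 <- weighted_complex(list(rbind(c(0, 0), c(4, 0), c(2, 3))), 2)
  f2 <- weighted_complex(list(rbind(c(1, -1), c(5, 1), c(2, 2))), 7)
  f3 <- weighted_complex(list(rbind(c(-1, 1), c(3, 1), c(1, 4))), 3)
  sc <- scale_weights(list(f1, f2, f3))
  out <- combine_frames(sc)
  validate_complex(out)
  sources <- list(sc$frames[[1]]$simplices[[1]], sc$frames[[2]]$simplices[[1]],
                  sc$frames[[3]]$simplices[[1]])
  sw <- c(sc$frames[[1]]$weights, sc$frames[[2]]$weights, sc$frames[[3]]$weights)
  V <- unique(do.call(rbind, sources))
  checked <- 0
  for (i in 1:1000) {
    lam <- stats::rexp(nrow(V)); lam <- lam / sum(lam)
    p <- colSums(V * lam)
    dsrc <- vapply(sources, function(s) point_simplex_distance(p, s), 0)
    if (any(dsrc > 1e-9 & dsrc < 1e-6)) next   # near a source edge: ambiguous
    loc <- locate_point(out, p)
    if (length(loc) != 1) next                 # on an output boundary
    expected <- if (any(dsrc <= 1e-9)) sum(sw[dsrc <= 1e-9]) else 1
    expect_equal(out$weights[loc], expected, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gt(checked, 500)
})

test_that("degenerate source sets collapse to lower-dimensional overlays", {
  # all sources one point
  p1 <- weighted_complex(list(rbind(c(1, 1))), 2)
  p2 <- weighted_complex(list(rbind(c(1, 1))), 5)
  out <- combine_frames(list(p1, p2))
  expect_identical(length(out$simplices), 1L)
  expect_identical(out$weights, 7)
  # collinear segments: interval overlay with gap weight 1
  s1 <- weighted_complex(list(rbind(c(0, 0), c(1, 0))), 2)
  s2 <- weighted_complex(list(rbind(c(3, 0), c(4, 0))), 6)
  out2 <- combine_frames(list(s1, s2))
  mids <- vapply(out2$simplices, function(s) mean(s[, 1]), 0)
  expect_identical(out2$weights[order(mids)], c(2, 1, 6))
})

test_that("the A-silhouette pipeline combines ranked neighbours", {
  lex <- tiny_lexicon(5)
  target <- exemplar("new", cbind(c(0.2, 5.2), c(0, 0)))
  asil <- build_asilhouette(target, lex, 3)
  expect_identical(asil$concept, "new")
  expect_identical(attr(asil, "neighbors")$concept, c("w01", "w02", "w03"))
  expect_length(asil$frames, 2)
  for (f in asil$frames) validate_complex(f)
  # k = 1: geometry equals the single neighbour's frame, weights rescaled
  asil1 <- build_asilhouette(target, lex, 1)
  f0 <- lex$expressive$w01$silhouette$frames[[1]]
  expect_equal(complex_area(asil1$frames[[1]]), complex_area(f0), tolerance = 1e-9)
  # deterministic: same lexicon, same output
  asil2 <- build_asilhouette(target, lex, 3)
  expect_identical(asil$frames, asil2$frames)
})
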