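#' Lexicons
#'
#' The expressive vocabulary holds concepts with both a silhouette and an
#' exemplar (words the speaker can produce by direct integration); the
#' receptive-only vocabulary holds exemplars alone.  Novel-word production
#' builds an archi-silhouette (A-silhouette) from the expressive entries
#' perceptually closest to the target.
#'
#' @param expressive named list: concept -> `list(silhouette =, exemplar =)`.
#' @param receptive named list: concept -> [exemplar()].
#' @export
lexicon <- function(expressive, receptive = list()) {
  if (is.null(names(expressive)) && length(expressive))
    stop_dualex("expressive entries must be named by concept",
                "dualex_invalid_argument")
  structure(list(expressive = expressive, receptive = receptive),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d expressive, %d receptive-only concepts>\n",
              length(x$expressive), length(x$receptive)))
  invisible(x)
}

#' Rank expressive neighbours of a target exemplar
#'
#' Orders the expressive vocabulary by perceptual trajectory distance
#' ([trajectory_distance()]) to the target and returns the `k` closest
#' concepts, ascending; ties are broken by concept id for stability.
#'
#' @param target an [exemplar()] (the novel word's perceptual form).
#' @param lex a [lexicon()].
#' @param k number of neighbours (`1 <= k <=` expressive size).
#' @return data frame with columns `concept` and `distance`, `k` rows.
#' @export
rank_neighbors <- function(target, lex, k) {
  k <- check_count(k, "k")
  if (length(lex$expressive) < k)
    stop_dualex(sprintf("expressive vocabulary (%d) smaller than k = %d",
                        length(lex$expressive), k),
                "dualex_insufficient_vocabulary")
  ids <- names(lex$expressive)
  d <- vapply(lex$expressive, function(w)
    trajectory_distance(w$exemplar$trajectory, target$trajectory), 0)
  o <- order(d, ids)
  data.frame(concept = ids[o][seq_len(k)], distance = unname(d[o][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Align silhouettes in time
#'
#' Resamples every silhouette to the common length `T* = max(T_i)` by
#' nearest-frame lookup at uniform parameter values (original frames are
#' reused, never interpolated).  Silhouettes already at `T*` are returned
#' unchanged.
#'
#' @param sils non-empty list of [silhouette()] objects.
#' @export
align_silhouettes <- function(sils) {
  if (!length(sils))
    stop_dualex("no silhouettes to align", "dualex_invalid_argument")
  Ts <- vapply(sils, function(s) length(s$frames), 1L)
  Tstar <- max(Ts)
  lapply(sils, function(s) {
    T_ <- length(s$frames)
    if (T_ == Tstar) return(s)
    idx <- if (Tstar == 1L) 1L else
      floor(1 + (seq_len(Tstar) - 1) * (T_ - 1) / (Tstar - 1) + 0.5)
    silhouette(s$concept, s$frames[idx], iteration = s$iteration)
  })
}

#' Scale weights across silhouette frames to a common maximum
#'
#' The per-time rescaling used when combining silhouettes: every weight is
#' multiplied by `max_i(MAXWEIGHT_i) / MAXWEIGHT_i`, where `MAXWEIGHT_i` is
#' the largest weight within the i-th frame, so that each frame's maximum
#' scaled weight equals the global maximum while relative weights within a
#' frame are preserved.
#'
#' @param frames either a list of [weighted_complex()] frames (one per
#'   silhouette, at a common time) or a list of plain numeric weight
#'   vectors.
#' @return an object of class `scaled_frame_set`: list with `frames` (same
#'   type as the input, weights scaled), `weights` (list of scaled weight
#'   vectors) and `global_max`.
#' @examples
#' scale_weights(list(c(3, 4), c(5, 8), c(2, 1)))$weights
#' # (6, 8), (5, 8), (8, 4)
#' @export
scale_weights <- function(frames) {
  if (!length(frames))
    stop_dualex("no frames to scale", "dualex_invalid_argument")
  plain <- all(vapply(frames, is.numeric, TRUE))
  w <- if (plain) lapply(frames, as.double) else lapply(frames, `[[`, "weights")
  if (any(vapply(w, function(v) any(v <= 0) || !length(v), TRUE)))
    stop_dualex("weights must be positive", "dualex_invalid_argument")
  maxw <- vapply(w, max, 0)
  g <- max(maxw)
  scaled <- lapply(seq_along(w), function(i) w[[i]] * g / maxw[i])
  out_frames <- if (plain) scaled else
    lapply(seq_along(frames), function(i)
      weighted_complex(frames[[i]]$simplices, scaled[[i]], validate = FALSE))
  structure(list(frames = out_frames, weights = scaled, global_max = g),
            class = "scaled_frame_set")
}

#' The weight-scaling worked example
#'
#' Three aligned silhouettes with two regions each, weighted (3,4), (5,8)
#' and (2,1): rescaling to the common maximum 8 yields scaled weights
#' (6,8), (5,8), (8,4).
#'
#' @return list with `input`, `scaled` (lists of weight vectors) and
#'   `global_max`.
#' @export
asil_scaling_example <- function() {
  input <- list(c(3, 4), c(5, 8), c(2, 1))
  s <- scale_weights(input)
  list(input = input, scaled = s$weights, global_max = s$global_max)
}

## ---- frame combination (overlay arrangement, 2D) ---------------------------

#' Combine scaled silhouette frames into one weighted region
#'
#' Triangulates the convex hull of all source regions so that every output
#' simplex lies either inside a fixed set of source regions or outside all
#' of them (the overlay arrangement is respected), then assigns each output
#' simplex the sum of the scaled weights of the source regions covering it,
#' or weight 1 where it covers a gap inside the hull not belonging to any
#' source.
#'
#' Implemented for ambient dimension up to 2 by a vertical-slab
#' (trapezoidal) decomposition refined at every vertex and edge-edge
#' intersection, which guarantees the refinement condition; degenerate
#' source sets (collinear or coincident) collapse to 1D interval overlays or
#' a 0-simplex passthrough.
#'
#' @param scaled a `scaled_frame_set` from [scale_weights()] (geometry
#'   mode), or a plain list of [weighted_complex()] frames whose weights are
#'   already scaled.
#' @return a [weighted_complex()].
#' @export
combine_frames <- function(scaled) {
  frames <- if (inherits(scaled, "scaled_frame_set")) scaled$frames else scaled
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "weighted_complex")))
    stop_dualex("combine_frames needs weighted_complex frames",
                "dualex_invalid_argument")
  dims <- unique(vapply(frames, complex_dim, 1L))
  if (length(dims) != 1L)
    stop_dualex("frames differ in motor dimension", "dualex_invalid_argument")
  sources <- list(); sw <- numeric(0)
  for (f in frames) {
    sources <- c(sources, f$simplices)
    sw <- c(sw, f$weights)
  }
  V <- unique(do.call(rbind, sources))
  ab <- affine_basis(V)
  if (ab$rank == 0L)                        # all sources a single point
    return(weighted_complex(list(V[1L, , drop = FALSE]), sum(sw),
                            validate = FALSE))
  if (ab$rank == 1L) return(.combine_1d(sources, sw, ab))
  if (ab$rank > 2L)
    stop_dualex("combine_frames supports ambient dimension <= 2",
                "dualex_invalid_argument")
  .combine_2d(sources, sw, ab)
}

# 1D overlay: interval arrangement along the common line
.combine_1d <- function(sources, sw, ab) {
  coord <- lapply(sources, function(S) sort(range(span_coords(S, ab))))
  breaks <- sort(unique(round(unlist(coord) / .dualex_tol))) * .dualex_tol
  segs <- list(); wts <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    if (b - a <= .dualex_tol) next
    mid <- (a + b) / 2
    cover <- vapply(coord, function(r) r[1L] - .dualex_tol <= mid &&
                      mid <= r[2L] + .dualex_tol, TRUE)
    w <- if (any(cover)) sum(sw[cover]) else 1
    p1 <- ab$origin + drop(ab$Q) * a
    p2 <- ab$origin + drop(ab$Q) * b
    segs[[length(segs) + 1L]] <- rbind(p1, p2)
    wts <- c(wts, w)
  }
  weighted_complex(segs, wts, validate = FALSE)
}

# 2D overlay via vertical-slab decomposition.  The arrangement tolerance is
# coarser than the geometric containment tolerance: near-concurrent edge
# intersections (events closer than 1e-7) are merged into one event, which
# keeps the decomposition free of sliver slabs and T-junctions.
.combine_2d <- function(sources, sw, ab) {
  tol <- 1e-7
  src2 <- lapply(sources, function(S) span_coords(S, ab))  # in-plane coords
  # constraint segments: all edges of all sources, plus the hull boundary
  seg_a <- list(); seg_b <- list()
  add_seg <- function(p, q) {
    seg_a[[length(seg_a) + 1L]] <<- p; seg_b[[length(seg_b) + 1L]] <<- q
  }
  for (S in src2) {
    n <- nrow(S)
    if (n >= 2L)
      for (i in seq_len(n)) add_seg(S[i, ], S[if (i == n) 1L else i + 1L, ])
  }
  allV <- unique(do.call(rbind, src2))
  hull_idx <- grDevices::chull(allV)
  hullV <- allV[hull_idx, , drop = FALSE]
  nh <- nrow(hullV)
  for (i in seq_len(nh)) add_seg(hullV[i, ], hullV[if (i == nh) 1L else i + 1L, ])
  A <- do.call(rbind, seg_a); B <- do.call(rbind, seg_b)
  keep <- sqrt(rowSums((A - B)^2)) > tol
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  ns <- nrow(A)
  # event x-coordinates: endpoints and pairwise intersections
  xs <- c(A[, 1L], B[, 1L])
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    p <- .seg_intersection(A[i, ], B[i, ], A[j, ], B[j, ], tol)
    if (!is.null(p)) xs <- c(xs, p[1L])
  }
  xs <- sort(xs)
  xs <- xs[c(TRUE, diff(xs) > tol)]
  # per-event vertical cut points (for T-junction-free subdivision)
  ycuts <- lapply(xs, function(x0) {
    ys <- numeric(0)
    for (i in seq_len(ns)) {
      x1 <- A[i, 1L]; x2 <- B[i, 1L]
      if (min(x1, x2) - tol <= x0 && x0 <= max(x1, x2) + tol) {
        if (abs(x2 - x1) <= tol) ys <- c(ys, A[i, 2L], B[i, 2L])
        else ys <- c(ys, A[i, 2L] + (B[i, 2L] - A[i, 2L]) * (x0 - x1) / (x2 - x1))
      }
    }
    ys <- sort(ys)
    ys[c(TRUE, diff(ys) > tol)]
  })
  tris <- list(); n_tri <- 0L
  for (si in seq_len(length(xs) - 1L)) {
    xl <- xs[si]; xr <- xs[si + 1L]
    if (xr - xl <= tol) next
    xm <- (xl + xr) / 2
    act <- which(pmin(A[, 1L], B[, 1L]) <= xl + tol &
                 pmax(A[, 1L], B[, 1L]) >= xr - tol &
                 abs(A[, 1L] - B[, 1L]) > tol)
    if (length(act) < 2L) next
    yl <- A[act, 2L] + (B[act, 2L] - A[act, 2L]) *
      (xl - A[act, 1L]) / (B[act, 1L] - A[act, 1L])
    yr <- A[act, 2L] + (B[act, 2L] - A[act, 2L]) *
      (xr - A[act, 1L]) / (B[act, 1L] - A[act, 1L])
    # snap to the canonical per-event cut values so that every vertex of
    # the decomposition is produced with identical bits wherever it appears
    yl <- vapply(yl, function(v)
      ycuts[[si]][which.min(abs(ycuts[[si]] - v))], 0)
    yr <- vapply(yr, function(v)
      ycuts[[si + 1L]][which.min(abs(ycuts[[si + 1L]] - v))], 0)
    dup <- duplicated(cbind(yl, yr))
    yl <- yl[!dup]; yr <- yr[!dup]
    o <- order((yl + yr) / 2)
    yl <- yl[o]; yr <- yr[o]
    for (bi in seq_len(length(yl) - 1L)) {
      poly <- .trapezoid_polygon(xl, xr, yl[bi], yr[bi], yl[bi + 1L], yr[bi + 1L],
                                 ycuts[[si]], ycuts[[si + 1L]], tol)
      if (is.null(poly)) next
      np <- nrow(poly)
      parea <- abs(sum(poly[, 1L] * poly[c(2:np, 1L), 2L] -
                       poly[c(2:np, 1L), 1L] * poly[, 2L])) / 2
      if (parea < 1e-12) next
      # star-triangulate from the centroid: every boundary edge (including
      # the vertical-edge subdivision points) is preserved exactly, so
      # neighbouring trapezoids meet face-to-face
      cen <- colMeans(poly)
      for (k in seq_len(np)) {
        tri <- rbind(cen, poly[k, ], poly[if (k == np) 1L else k + 1L, ])
        if (.tri_area(tri) > 0) {
          n_tri <- n_tri + 1L
          tris[[n_tri]] <- tri
        }
      }
    }
  }
  if (!n_tri)
    stop_dualex("frame combination produced no area (degenerate input)",
                "dualex_geometry_error")
  # weights: sum of covering scaled source weights, else 1
  wts <- vapply(tris, function(tri) {
    cen <- colMeans(tri)
    cover <- vapply(src2, function(S) .psd(cen, S) <= 1e-7, TRUE)
    if (any(cover)) sum(sw[cover]) else 1
  }, 0)
  # back to ambient coordinates
  tris_amb <- lapply(tris, function(tri)
    sweep(tri %*% t(ab$Q), 2L, ab$origin, "+"))
  weighted_complex(tris_amb, wts, validate = FALSE)
}

.tri_area <- function(tri) {
  abs((tri[2L, 1L] - tri[1L, 1L]) * (tri[3L, 2L] - tri[1L, 2L]) -
      (tri[3L, 1L] - tri[1L, 1L]) * (tri[2L, 2L] - tri[1L, 2L])) / 2
}

# intersection point of segments p1-p2 and p3-p4, or NULL
.seg_intersection <- function(p1, p2, p3, p4, tol) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) <= tol * max(1, sum(abs(d1)), sum(abs(d2)))) return(NULL)
  t1 <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / den
  t2 <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / den
  if (t1 < -tol || t1 > 1 + tol || t2 < -tol || t2 > 1 + tol) return(NULL)
  p1 + t1 * d1
}

# convex polygon (CCW) of a trapezoid with vertical edges subdivided at the
# global cut points; returns NULL if degenerate
.trapezoid_polygon <- function(xl, xr, ybl, ybr, ytl, ytr, cutl, cutr, tol) {
  left_in <- cutl[cutl > ybl + tol & cutl < ytl - tol]
  right_in <- cutr[cutr > ybr + tol & cutr < ytr - tol]
  pts <- rbind(c(xl, ybl), c(xr, ybr))
  if (length(right_in)) pts <- rbind(pts, cbind(xr, sort(right_in)))
  pts <- rbind(pts, c(xr, ytr), c(xl, ytl))
  if (length(left_in)) pts <- rbind(pts, cbind(xl, sort(left_in, decreasing = TRUE)))
  d <- rowSums(abs(pts - pts[c(2:nrow(pts), 1L), , drop = FALSE]))
  pts <- pts[d > tol, , drop = FALSE]
  if (nrow(pts) < 3L) return(NULL)
  pts
}

#' Build an A-silhouette for a novel word
#'
#' The archi-silhouette that guides first production of a word the speaker
#' has only heard: the `k` perceptually closest expressive words are found
#' ([rank_neighbors()]), their silhouettes aligned in time
#' ([align_silhouettes()]), each frame's weights rescaled to a common
#' maximum ([scale_weights()]), and the frames combined region-wise
#' ([combine_frames()]).
#'
#' @inheritParams rank_neighbors
#' @return a [silhouette()] tagged with the target's concept, iteration 0.
#' @export
build_asilhouette <- function(target, lex, k) {
  nb <- rank_neighbors(target, lex, k)
  sils <- lapply(nb$concept, function(id) lex$expressive[[id]]$silhouette)
  sils <- align_silhouettes(sils)
  Tstar <- length(sils[[1L]]$frames)
  frames <- lapply(seq_len(Tstar), function(t)
    combine_frames(scale_weights(lapply(sils, function(s) s$frames[[t]]))))
  out <- silhouette(target$concept, frames, iteration = 0L)
  attr(out, "neighbors") <- nb
  out
}
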