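#' Simplices
#'
#' A k-simplex is the convex hull of k+1 affinely independent points; the
#' model supports 0- to 3-simplices (points, segments, triangles, tetrahedra)
#' embedded in spaces of dimension >= k.  A simplex is stored as a numeric
#' matrix with one vertex per row.
#'
#' @param vertices numeric matrix (rows = vertices) or list of coordinate
#'   vectors.
#' @return an object of class `simplex`.
#' @export
simplex <- function(vertices) {
  v <- as_point_matrix(vertices)
  if (!all(is.finite(v)))
    stop_dualex("simplex vertices must be finite", "dualex_invalid_argument")
  if (nrow(v) > ncol(v) + 1L)
    stop_dualex("a simplex has at most dim+1 vertices", "dualex_invalid_argument")
  if (nrow(v) > 1L && simplex_degenerate(v))
    stop_dualex("simplex vertices are affinely dependent (degenerate)",
                "dualex_geometry_error")
  structure(v, class = c("simplex", "matrix", "array"))
}

# TRUE if the rows of v are affinely dependent within tolerance
simplex_degenerate <- function(v, tol = .dualex_tol) {
  if (nrow(v) == 1L) return(FALSE)
  e <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
  # smallest singular value of edge matrix relative to scale
  sv <- svd(e, nu = 0, nv = 0)$d
  length(sv) < nrow(e) || sv[nrow(e)] <= tol * max(1, sv[1L])
}

# k-volume of a simplex (length / area / volume in its intrinsic dimension)
simplex_volume <- function(v) {
  v <- as_point_matrix(v)
  k <- nrow(v) - 1L
  if (k == 0L) return(0)
  e <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
  g <- e %*% t(e)
  sqrt(max(0, det(g))) / factorial(k)
}

#' Distance from a point to a closed simplex
#'
#' Minimal Euclidean distance from `p` to the closed simplex `s`; zero
#' exactly when `p` lies in the simplex.  Used to spread activation from a
#' silhouette region to nearby junctures.
#'
#' The computation projects `p` onto the simplex's affine hull; if the
#' projection's barycentric coordinates are all non-negative the distance to
#' the projection is returned, otherwise the minimum over the simplex's
#' facets is taken recursively.
#'
#' @param p numeric coordinate vector.
#' @param s a [simplex()] (or vertex matrix).
#' @return a single non-negative number.
#' @examples
#' point_simplex_distance(c(0, 2), rbind(c(0, 0), c(1, 0))) # 2
#' @export
point_simplex_distance <- function(p, s) {
  p <- as.double(p)
  v <- as_point_matrix(s)
  if (length(p) != ncol(v))
    stop_dualex("point and simplex dimensions differ", "dualex_invalid_argument")
  .psd(p, v)
}

.psd <- function(p, v) {
  n <- nrow(v)
  if (n == 1L) return(sqrt(sum((p - v[1L, ])^2)))
  e <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])     # (n-1) x d edge matrix
  g <- e %*% t(e)
  rhs <- e %*% (p - v[1L, ])
  a <- tryCatch(solve(g, rhs), error = function(e2) NULL)
  if (is.null(a)) {                                   # degenerate: fall to facets
    return(min(vapply(seq_len(n), function(i) .psd(p, v[-i, , drop = FALSE]), 0)))
  }
  lambda <- c(1 - sum(a), a)
  if (all(lambda >= -.dualex_tol)) {
    proj <- v[1L, ] + as.vector(t(e) %*% a)
    return(sqrt(max(0, sum((p - proj)^2))))
  }
  min(vapply(seq_len(n), function(i) .psd(p, v[-i, , drop = FALSE]), 0))
}

# closed containment test, tolerance-controlled
point_in_simplex <- function(p, v, tol = .dualex_tol) {
  point_simplex_distance(p, v) <= tol
}

## ---- vectorised 2D distance kernels (hot path for activation) -------------

# distance from each row of P (n x 2) to each segment (A[i,], B[i,]) (m x 2)
dist_points_segments <- function(P, A, B) {
  n <- nrow(P); m <- nrow(A)
  dx <- B[, 1L] - A[, 1L]; dy <- B[, 2L] - A[, 2L]
  len2 <- pmax(dx * dx + dy * dy, .Machine$double.xmin)
  px <- outer(P[, 1L], A[, 1L], "-")      # n x m
  py <- outer(P[, 2L], A[, 2L], "-")
  t_ <- sweep(px, 2L, dx, "*") + sweep(py, 2L, dy, "*")
  t_ <- pmin(pmax(sweep(t_, 2L, len2, "/"), 0), 1)
  ex <- px - sweep(t_, 2L, dx, "*")
  ey <- py - sweep(t_, 2L, dy, "*")
  sqrt(ex * ex + ey * ey)
}

# distance from each row of P (n x 2) to each triangle V1/V2/V3 (m x 2 each)
dist_points_triangles <- function(P, V1, V2, V3) {
  n <- nrow(P); m <- nrow(V1)
  d <- pmin(dist_points_segments(P, V1, V2),
            dist_points_segments(P, V2, V3),
            dist_points_segments(P, V3, V1))
  # zero out points inside a triangle (sign-consistent half-plane test)
  s1 <- .edge_sign(P, V1, V2); s2 <- .edge_sign(P, V2, V3); s3 <- .edge_sign(P, V3, V1)
  inside <- (s1 >= -.dualex_tol & s2 >= -.dualex_tol & s3 >= -.dualex_tol) |
            (s1 <= .dualex_tol & s2 <= .dualex_tol & s3 <= .dualex_tol)
  d[inside] <- 0
  d
}

# signed area-ish orientation of P relative to directed edge A->B, n x m
.edge_sign <- function(P, A, B) {
  dx <- B[, 1L] - A[, 1L]; dy <- B[, 2L] - A[, 2L]
  px <- outer(P[, 1L], A[, 1L], "-")
  py <- outer(P[, 2L], A[, 2L], "-")
  sweep(py, 2L, dx, "*") - sweep(px, 2L, dy, "*")
}

# distances from points P (n x d) to every simplex of a frame; returns
# (#simplices x n) matrix.  Uses the vectorised 2D kernels when possible.
frame_point_distances <- function(simplices, P) {
  P <- as_point_matrix(P)
  k <- nrow(simplices[[1L]]) - 1L
  d <- ncol(P)
  if (d == 2L && k == 2L) {
    V1 <- do.call(rbind, lapply(simplices, function(s) s[1L, ]))
    V2 <- do.call(rbind, lapply(simplices, function(s) s[2L, ]))
    V3 <- do.call(rbind, lapply(simplices, function(s) s[3L, ]))
    return(t(dist_points_triangles(P, V1, V2, V3)))
  }
  if (d == 2L && k == 1L) {
    A <- do.call(rbind, lapply(simplices, function(s) s[1L, ]))
    B <- do.call(rbind, lapply(simplices, function(s) s[2L, ]))
    return(t(dist_points_segments(P, A, B)))
  }
  out <- matrix(0, nrow = length(simplices), ncol = nrow(P))
  for (i in seq_along(simplices))
    for (j in seq_len(nrow(P)))
      out[i, j] <- .psd(P[j, ], as_point_matrix(simplices[[i]]))
  out
}
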