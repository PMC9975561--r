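#' Weighted homogeneous simplicial complexes
#'
#' The region a silhouette highlights at one moment in time: a set of
#' same-dimension simplices with positive weights, meeting face-to-face,
#' whose union is convex.  Weights encode how often motor traces have passed
#' through each subregion.
#'
#' @param simplices non-empty list of [simplex()] objects (or vertex
#'   matrices), all with the same number of vertices.
#' @param weights positive numeric vector, one weight per simplex.
#' @param validate check homogeneity and convexity of the union (default
#'   `TRUE`; construction-internal calls skip it for speed).
#' @return an object of class `weighted_complex`.
#' @export
weighted_complex <- function(simplices, weights = rep(1, length(simplices)),
                             validate = TRUE) {
  if (length(simplices) < 1L)
    stop_dualex("a weighted complex needs at least one simplex",
                "dualex_invalid_argument")
  simplices <- lapply(simplices, as_point_matrix)
  weights <- as.double(weights)
  if (length(weights) != length(simplices) || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop_dualex("weights must be positive, one per simplex",
                "dualex_invalid_argument")
  nv <- unique(vapply(simplices, nrow, 1L))
  nd <- unique(vapply(simplices, ncol, 1L))
  if (length(nv) != 1L || length(nd) != 1L)
    stop_dualex("complex is not homogeneous (mixed simplex dimensions)",
                "dualex_invalid_argument")
  if (nv > nd + 1L)
    stop_dualex("simplices cannot have more vertices than dim + 1",
                "dualex_invalid_argument")
  x <- structure(list(simplices = simplices, weights = weights),
                 class = "weighted_complex")
  if (validate) validate_complex(x)
  x
}

#' @export
print.weighted_complex <- function(x, ...) {
  cat(sprintf("<weighted complex: %d %d-simplices in %dD, total weight %g>\n",
              length(x$simplices), nrow(x$simplices[[1L]]) - 1L,
              ncol(x$simplices[[1L]]), sum(x$weights)))
  invisible(x)
}

complex_dim <- function(x) ncol(x$simplices[[1L]])          # ambient
complex_k <- function(x) nrow(x$simplices[[1L]]) - 1L       # intrinsic

complex_vertices <- function(x) {
  v <- do.call(rbind, x$simplices)
  unique(v)
}

# weight-weighted mean of simplex centroids; the fallback output point
complex_centroid <- function(x) {
  cents <- do.call(rbind, lapply(x$simplices, colMeans))
  colSums(cents * x$weights) / sum(x$weights)
}

## ---- affine span tools -----------------------------------------------------

affine_basis <- function(V, tol = .dualex_tol) {
  origin <- V[1L, ]
  if (nrow(V) == 1L)
    return(list(origin = origin, Q = matrix(0, length(origin), 0L), rank = 0L))
  M <- sweep(V[-1L, , drop = FALSE], 2L, origin)
  s <- svd(t(M))
  keep <- s$d > tol * max(1, s$d[1L])
  list(origin = origin, Q = s$u[, keep, drop = FALSE], rank = sum(keep))
}

span_residual <- function(p, ab) {
  w <- p - ab$origin
  if (ab$rank == 0L) return(sqrt(sum(w^2)))
  r <- w - as.vector(ab$Q %*% (t(ab$Q) %*% w))   # stable: no cancellation
  sqrt(sum(r^2))
}

span_coords <- function(P, ab) {
  P <- as_point_matrix(P)
  sweep(P, 2L, ab$origin) %*% ab$Q
}

## ---- facets ----------------------------------------------------------------

.facet_key <- function(m) {
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  paste(sprintf("%.17g", t(m)), collapse = ",")
}

# boundary facets of a homogeneous complex: facets appearing in exactly one
# simplex.  Returns a list of (facet matrix, opposite vertex).
boundary_facets <- function(x) {
  counts <- new.env(parent = emptyenv())
  entries <- list()
  n <- 0L
  for (i in seq_along(x$simplices)) {
    S <- x$simplices[[i]]
    for (j in seq_len(nrow(S))) {
      f <- S[-j, , drop = FALSE]
      key <- .facet_key(f)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      n <- n + 1L
      entries[[n]] <- list(key = key, facet = f, opposite = S[j, ])
    }
  }
  Filter(function(e) counts[[e$key]] == 1L, entries)
}

# outward unit normal of a boundary facet, expressed in span coordinates of
# the complex (rank k), oriented away from the opposite vertex
facet_outward_normal <- function(entry, ab) {
  Fc <- span_coords(entry$facet, ab)              # k x k
  o <- drop(span_coords(rbind(entry$opposite), ab))
  k <- ncol(Fc)
  if (k == 1L) {
    n <- 1
  } else {
    E <- sweep(Fc[-1L, , drop = FALSE], 2L, Fc[1L, ])   # (k-1) x k
    # unit null vector of E
    s <- svd(t(E), nu = k)
    n <- s$u[, k]
  }
  if (sum(n * (o - Fc[1L, ])) > 0) n <- -n
  list(normal = n, f0 = Fc[1L, ])
}

## ---- point location --------------------------------------------------------

#' Locate a point within a weighted complex
#'
#' Returns the indices of every simplex that contains `p` (closed
#' containment, within tolerance).  A point on a shared boundary belongs to
#' all touching simplices; a point outside the union yields an empty vector.
#'
#' @param x a [weighted_complex()].
#' @param p numeric coordinate vector.
#' @export
locate_point <- function(x, p) {
  p <- as.double(p)
  if (length(p) != complex_dim(x))
    stop_dualex("point and complex dimensions differ", "dualex_invalid_argument")
  if (complex_k(x) == 2L && complex_dim(x) == 2L) {
    st <- attr(x, "stack") %||% .tri_stack(x$simplices)
    return(which(.in_triangles(p, st)))
  }
  d <- frame_point_distances(x$simplices, rbind(p))[, 1L]
  which(d <= .dualex_tol)
}

# stacked vertex/edge arrays for fast repeated queries on 2D triangle frames
.tri_stack <- function(simplices) {
  V1 <- do.call(rbind, lapply(simplices, function(s) s[1L, ]))
  V2 <- do.call(rbind, lapply(simplices, function(s) s[2L, ]))
  V3 <- do.call(rbind, lapply(simplices, function(s) s[3L, ]))
  len <- function(A, B) sqrt((B[, 1L] - A[, 1L])^2 + (B[, 2L] - A[, 2L])^2)
  list(V1 = V1, V2 = V2, V3 = V3,
       l1 = len(V1, V2), l2 = len(V2, V3), l3 = len(V3, V1))
}

# closed containment (within tolerance) of one point in stacked triangles;
# orientation-free: all three signed edge distances share a sign
.in_triangles <- function(p, st) {
  s1 <- ((p[1L] - st$V1[, 1L]) * (st$V2[, 2L] - st$V1[, 2L]) -
         (p[2L] - st$V1[, 2L]) * (st$V2[, 1L] - st$V1[, 1L])) / st$l1
  s2 <- ((p[1L] - st$V2[, 1L]) * (st$V3[, 2L] - st$V2[, 2L]) -
         (p[2L] - st$V2[, 2L]) * (st$V3[, 1L] - st$V2[, 1L])) / st$l2
  s3 <- ((p[1L] - st$V3[, 1L]) * (st$V1[, 2L] - st$V3[, 2L]) -
         (p[2L] - st$V3[, 2L]) * (st$V1[, 1L] - st$V3[, 1L])) / st$l3
  (s1 >= -.dualex_tol & s2 >= -.dualex_tol & s3 >= -.dualex_tol) |
  (s1 <= .dualex_tol & s2 <= .dualex_tol & s3 <= .dualex_tol)
}

## ---- absorption ------------------------------------------------------------

#' Absorb a motor-trace point into a weighted complex
#'
#' The silhouette update rule at a single time step.  If `p` already lies in
#' the complex, every simplex containing it has its weight increased by one
#' and the geometry is untouched (Case 1).  If `p` lies outside, the old
#' simplices and weights are kept and a minimal set of weight-1 simplices is
#' added, fanning from `p` to the boundary facets visible from it, so that
#' the new union is the convex hull of the old vertices together with `p`
#' (Case 2).  If `p` leaves the affine span of a degenerate complex (a point
#' or a flat of lower dimension), the intrinsic dimension grows: the new
#' complex is the cone from `p` over the old simplices, recorded as weight-1
#' simplices.
#'
#' @param x a [weighted_complex()].
#' @param p numeric coordinate vector (finite).
#' @return a `weighted_complex`; attribute `"case"` records which update
#'   rule fired (`1`, `2`, or `"2-cone"`).
#' @export
absorb_point <- function(x, p) {
  p <- as.double(p)
  if (!all(is.finite(p)))
    stop_dualex("absorbed point must be finite", "dualex_invalid_argument")
  if (is.null(attr(x, "stack")) && complex_k(x) == 2L && complex_dim(x) == 2L)
    attr(x, "stack") <- .tri_stack(x$simplices)
  idx <- locate_point(x, p)
  if (length(idx)) {                               # Case 1: reweight
    w <- x$weights
    w[idx] <- w[idx] + 1
    out <- weighted_complex(x$simplices, w, validate = FALSE)
    attr(out, "case") <- 1
    attr(out, "boundary") <- attr(x, "boundary")   # geometry untouched
    attr(out, "stack") <- attr(x, "stack")
    return(out)
  }
  k <- complex_k(x); d <- complex_dim(x)
  if (k < d) {
    V <- complex_vertices(x)
    ab <- affine_basis(V)
    if (span_residual(p, ab) > .dualex_tol) {
      # dimension raise: cone from p over every old simplex
      sims <- lapply(x$simplices, function(S) rbind(S, p))
      out <- weighted_complex(sims, rep(1, length(sims)), validate = FALSE)
      attr(out, "case") <- "2-cone"
      return(out)
    }
  } else ab <- NULL
  # Case 2: fan p to visible boundary facets.  For full-dimensional
  # complexes the outward normals live in ambient space and are cached on
  # the boundary entries; lower-dimensional complexes go through the span
  # machinery.
  pc <- if (is.null(ab)) p else drop(span_coords(rbind(p), ab))
  bf <- attr(x, "boundary") %||% boundary_facets(x)
  new_sims <- list(); visible <- list(); invisible <- list()
  for (i in seq_along(bf)) {
    e <- bf[[i]]
    if (is.null(ab)) {
      if (is.null(e$normal)) {
        e$normal <- .ambient_outward_normal(e)
        e$f0 <- e$facet[1L, ]
        bf[[i]] <- e
      }
      vis <- sum(e$normal * (pc - e$f0)) > .dualex_tol
    } else {
      nrm <- facet_outward_normal(e, ab)
      vis <- sum(nrm$normal * (pc - nrm$f0)) > .dualex_tol
    }
    if (vis) {
      cand <- rbind(e$facet, p)
      if (simplex_degenerate(cand)) vis <- FALSE else
        new_sims[[length(new_sims) + 1L]] <- cand
    }
    if (vis) visible[[length(visible) + 1L]] <- e
    else invisible[[length(invisible) + 1L]] <- e
  }
  if (!length(new_sims))
    stop_dualex("no boundary facet visible from an exterior point (geometry error)",
                "dualex_geometry_error")
  out <- weighted_complex(c(x$simplices, new_sims),
                          c(x$weights, rep(1, length(new_sims))),
                          validate = FALSE)
  attr(out, "case") <- 2
  attr(out, "boundary") <- c(invisible, .new_boundary_entries(new_sims, visible))
  st <- attr(x, "stack")
  if (!is.null(st)) {
    ns <- .tri_stack(new_sims)
    attr(out, "stack") <- list(V1 = rbind(st$V1, ns$V1), V2 = rbind(st$V2, ns$V2),
                               V3 = rbind(st$V3, ns$V3), l1 = c(st$l1, ns$l1),
                               l2 = c(st$l2, ns$l2), l3 = c(st$l3, ns$l3))
  }
  out
}

# outward unit normal in ambient coordinates of a boundary facet of a
# full-dimensional complex (facet has d vertices in dimension d)
.ambient_outward_normal <- function(entry) {
  Fc <- entry$facet
  d <- ncol(Fc)
  n <- if (d == 1L) 1
  else if (d == 2L) {
    e <- Fc[2L, ] - Fc[1L, ]
    c(e[2L], -e[1L])
  } else if (d == 3L) {
    e1 <- Fc[2L, ] - Fc[1L, ]; e2 <- Fc[3L, ] - Fc[1L, ]
    c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
      e1[3L] * e2[1L] - e1[1L] * e2[3L],
      e1[1L] * e2[2L] - e1[2L] * e2[1L])
  } else {
    s <- svd(t(sweep(Fc[-1L, , drop = FALSE], 2L, Fc[1L, ])), nu = d)
    s$u[, d]
  }
  n <- n / sqrt(sum(n^2))
  if (sum(n * (entry$opposite - Fc[1L, ])) > 0) n <- -n
  n
}

# boundary entries contributed by a Case-2 fan: facets of the new simplices
# that are neither a base (a formerly visible facet) nor shared between two
# new simplices
.new_boundary_entries <- function(new_sims, visible) {
  base_keys <- vapply(visible, function(e) .facet_key(e$facet), "")
  counts <- new.env(parent = emptyenv())
  entries <- list(); n <- 0L
  for (S in new_sims) {
    for (j in seq_len(nrow(S))) {
      f <- S[-j, , drop = FALSE]
      key <- .facet_key(f)
      if (key %in% base_keys) next
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      n <- n + 1L
      entries[[n]] <- list(key = key, facet = f, opposite = S[j, ])
    }
  }
  Filter(function(e) counts[[e$key]] == 1L, entries)
}

## ---- validation ------------------------------------------------------------

#' Validate a weighted complex
#'
#' Checks homogeneity (constructor-enforced), positivity of weights,
#' non-degeneracy of simplices, and convexity of the union: every boundary
#' facet's supporting hyperplane must have all complex vertices on its inner
#' side (within tolerance).  Pairwise interior disjointness is not checked
#' here (it is exercised by volume-accounting tests).
#'
#' @param x a [weighted_complex()].
#' @return `x`, invisibly; errors with class `dualex_geometry_error` on
#'   violation.
#' @export
validate_complex <- function(x) {
  k <- complex_k(x)
  if (k > 0L && any(vapply(x$simplices, simplex_degenerate, TRUE)))
    stop_dualex("complex contains a degenerate simplex", "dualex_geometry_error")
  if (k == 0L) {
    if (length(x$simplices) > 1L)
      stop_dualex("a 0-complex with a convex union has a single point",
                  "dualex_geometry_error")
    return(invisible(x))
  }
  V <- complex_vertices(x)
  ab <- affine_basis(V)
  if (ab$rank != k)
    stop_dualex("complex does not span its intrinsic dimension",
                "dualex_geometry_error")
  Vc <- span_coords(V, ab)
  scale <- max(1, max(abs(Vc)))
  for (e in boundary_facets(x)) {
    nrm <- facet_outward_normal(e, ab)
    s <- Vc %*% nrm$normal - sum(nrm$normal * nrm$f0)
    if (max(s) > 1e-7 * scale)
      stop_dualex("union of simplices is not convex", "dualex_geometry_error")
  }
  invisible(x)
}
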