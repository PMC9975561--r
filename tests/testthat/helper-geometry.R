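# Shared fixtures and independent oracles for the geometry tests.

unit_square_complex <- function(weights = c(1, 1)) {
  weighted_complex(list(rbind(c(0, 0), c(1, 0), c(1, 1)),
                        rbind(c(0, 0), c(1, 1), c(0, 1))), weights)
}

tri <- function(...) do.call(rbind, list(...))

# brute-force oracle: distance from p to a simplex by dense barycentric
# sampling (slow, only for tiny tests)
grid_simplex_distance <- function(p, v, n = 120) {
  v <- as.matrix(v)
  k <- nrow(v)
  if (k == 1L) return(sqrt(sum((p - v[1, ])^2)))
  if (k == 2L) {
    tt <- seq(0, 1, length.out = n)
    pts <- outer(1 - tt, v[1, ]) + outer(tt, v[2, ])
  } else {
    g <- expand.grid(a = seq(0, 1, length.out = n), b = seq(0, 1, length.out = n))
    g <- g[g$a + g$b <= 1, ]
    pts <- outer(1 - g$a - g$b, v[1, ]) + outer(g$a, v[2, ]) + outer(g$b, v[3, ])
  }
  min(sqrt(rowSums(sweep(pts, 2, p)^2)))
}

# area helpers (2D) for volume-accounting checks
tri_area <- function(s) {
  abs((s[2, 1] - s[1, 1]) * (s[3, 2] - s[1, 2]) -
      (s[3, 1] - s[1, 1]) * (s[2, 2] - s[1, 2])) / 2
}

complex_area <- function(x) sum(vapply(x$simplices, tri_area, 0))

hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

# grow a random (but seeded) 2D complex by absorbing points
random_grown_complex <- function(n_absorb = 15, lim = c(-3, 4)) {
  wc <- weighted_complex(list(rbind(c(0, 0), c(1, 0), c(0, 1))), 1)
  for (i in seq_len(n_absorb))
    wc <- absorb_point(wc, stats::runif(2, lim[1], lim[2]))
  wc
}

# tiny two-cluster map with identical motor/perceptual layouts
toy_map <- function(centers = rbind(c(0, 0), c(10, 0)), r = 1) {
  clusters <- lapply(seq_len(nrow(centers)), function(i) {
    offs <- rbind(c(r, 0), c(0, r), c(-r, 0), c(0, -r)) / 2
    js <- lapply(1:4, function(j)
      juncture(sprintf("cl%d_j%d", i, j), centers[i, ] + offs[j, ],
               centers[i, ] + offs[j, ]))
    cluster(sprintf("cl%d", i), js)
  })
  pm_map(clusters)
}
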