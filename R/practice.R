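#' One iteration of speech practice
#'
#' Integrates the silhouette and exemplar, optionally perturbs the executed
#' motor trajectory with zero-mean isotropic Gaussian noise (peripheral motor
#' noise), and absorbs the executed trace back into the silhouette.
#' Communicative success is assumed, so every trace is absorbed; the
#' `success` hook is exposed for future listener models.
#'
#' @inheritParams integrate_word
#' @param noise_sd standard deviation of motor noise per coordinate
#'   (default 0: deterministic).  Uses the current RNG state.
#' @param success absorb the trace? (default `TRUE`).
#' @return list with elements `output` (an `output_trajectory`, motor points
#'   as executed, i.e. including noise) and `silhouette` (the updated
#'   silhouette).
#' @export
practice_iteration <- function(sil, e, map, params = activation_params(),
                               noise_sd = 0, success = TRUE, .cache = NULL) {
  check_number(noise_sd, "noise_sd", min = 0)
  out <- integrate_word(sil, e, map, params, .cache = .cache)
  if (noise_sd > 0) {
    m <- unclass(out$motor)
    m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m), ncol(m))
    out$motor <- trajectory(m)
  }
  new_sil <- if (success) absorb_trace(sil, out$motor) else sil
  list(output = out, silhouette = new_sil)
}

#' Run a practice loop
#'
#' Chains [practice_iteration()]: the silhouette at iteration `n` produces
#' the output that is absorbed to give the silhouette used at `n + 1`.
#' With `noise_sd = 0` the loop is fully deterministic.
#'
#' @inheritParams practice_iteration
#' @param iterations number of productions (`>= 1`).
#' @param seed optional integer seed for the motor noise.
#' @return an object of class `practice_history`: list with `outputs` (one
#'   `output_trajectory` per iteration), `silhouette` (final state),
#'   `total_weight` (per-iteration total silhouette weight), `params`,
#'   `noise_sd`, `seed`.
#' @export
run_practice <- function(sil, e, map, params = activation_params(),
                         iterations = 1L, noise_sd = 0, seed = NULL) {
  iterations <- check_count(iterations, "iterations")
  if (!is.null(seed)) set.seed(seed)
  outputs <- vector("list", iterations)
  tw <- numeric(iterations)
  cache <- new.env(parent = emptyenv())
  cache$D <- list()
  for (i in seq_len(iterations)) {
    step <- practice_iteration(sil, e, map, params, noise_sd = noise_sd,
                               .cache = cache)
    outputs[[i]] <- step$output
    sil <- step$silhouette
    tw[i] <- silhouette_total_weight(sil)
  }
  structure(list(outputs = outputs, silhouette = sil, total_weight = tw,
                 params = params, noise_sd = noise_sd, seed = seed),
            class = "practice_history")
}

#' @export
print.practice_history <- function(x, ...) {
  cat(sprintf("<practice history: %d iterations, final total weight %g>\n",
              length(x$outputs), x$total_weight[length(x$total_weight)]))
  invisible(x)
}

#' Accuracy time series of a practice run
#'
#' Production accuracy at each iteration, measured as the perceptual
#' trajectory distance (see [trajectory_distance()]) between the output's
#' perceptual image and the exemplar being targeted.  Smaller is more
#' accurate.
#'
#' @param history a [run_practice()] result.
#' @param e the targeted [exemplar()].
#' @return numeric vector, one distance per iteration.
#' @export
accuracy_series <- function(history, e) {
  if (!length(history$outputs))
    stop_dualex("empty practice history", "dualex_invalid_argument")
  vapply(history$outputs, function(o)
    trajectory_distance(o$perceptual, e$trajectory), 0)
}

## ---- packaged practice worlds ---------------------------------------------

# square region (two triangles) centred at `center` with half-width h
square_frame <- function(center, h, weights = c(1, 1)) {
  x <- center[1L]; y <- center[2L]
  v1 <- c(x - h, y - h); v2 <- c(x + h, y - h)
  v3 <- c(x + h, y + h); v4 <- c(x - h, y + h)
  weighted_complex(list(rbind(v1, v2, v3), rbind(v1, v3, v4)), weights,
                   validate = FALSE)
}

.compass_offsets <- function(r) rbind(c(r, 0), c(0, r), c(-r, 0), c(0, -r))

# clusters with 4 compass junctures (+ optional seeded jitter), identical
# motor and perceptual layouts
.identical_layout_clusters <- function(centers, ids, juncture_radius, jitter_sd) {
  offs <- .compass_offsets(juncture_radius / 2)
  lapply(seq_along(ids), function(i) {
    js <- lapply(seq_len(nrow(offs)), function(j) {
      pos <- centers[i, ] + offs[j, ] +
        (if (jitter_sd > 0) stats::rnorm(2L, sd = jitter_sd) else c(0, 0))
      juncture(sprintf("%s_j%d", ids[i], j), pos, pos)
    })
    cluster(ids[i], js)
  })
}

#' Packaged 2D practice world (consonant/vowel rows, CVC target)
#'
#' The stated world behind the practice-plateau simulations: a 2D space in
#' which motor and perceptual layouts are identical, with a consonantal
#' cluster row at `y = 0` and a vocalic row at `y = 14`; the exemplar traces
#' a CVC path through three cluster centres, dwelling on the vowel nucleus
#' (three of its seven points sit on the vowel cluster, as vowel nuclei
#' dominate syllable duration).  The starting silhouette is an early,
#' inaccurate motor wordform: the same path of square regions translated by
#' `offset` in motor space.  The default offset of one cluster spacing puts
#' the starting path through the *adjacent* (wrong) clusters — a motor plan
#' that diverges from the exemplar trajectory — so practice first reshapes
#' the silhouette rapidly toward the exemplar-activated clusters and then
#' settles.  The seed jitters juncture placement slightly, giving each seed
#' its own realisation of the same world.
#'
#' @param seed integer seed for juncture jitter.
#' @param offset translation of the starting silhouette path relative to
#'   the exemplar's motor path (default `c(-8, 0)`: one cluster spacing).
#' @param jitter_sd standard deviation of juncture jitter (default 0.15).
#' @param half_width half-width of the starting silhouette squares.
#' @return list with `map`, `sil` (starting silhouette), `e` (target
#'   exemplar), `params`.
#' @export
practice_world_2d <- function(seed = 1L, offset = c(-8, 0), jitter_sd = 0.15,
                              half_width = 2.5) {
  set.seed(child_seed(seed, "practice2d"))
  centers <- rbind(c(0, 0), c(8, 0), c(16, 0),   # consonant row
                   c(0, 14), c(8, 14), c(16, 14)) # vowel row
  ids <- c("C1", "C2", "C3", "V1", "V2", "V3")
  map <- pm_map(.identical_layout_clusters(centers, ids, 1, jitter_sd))
  # CVC path C2 -> V2 -> C3 through realised centres, dwelling on the vowel
  pc <- cluster_centers(map, "perceptual")
  path <- .cvc_path(pc[2L, ], pc[5L, ], pc[3L, ])
  e <- exemplar("cvc", path)
  sil_centers <- sweep(path, 2L, offset, "+")
  frames <- lapply(seq_len(nrow(sil_centers)), function(t)
    square_frame(sil_centers[t, ], half_width))
  sil <- silhouette("cvc", frames, iteration = 1L)
  list(map = map, sil = sil, e = e, params = activation_params())
}

# 7-step CVC path: onset consonant, transition, 3-step vowel dwell,
# transition, coda consonant
.cvc_path <- function(c1, v, c2) {
  rbind(c1, (c1 + v) / 2, v, v, v, (v + c2) / 2, c2)
}

# small tetrahedron centred at p
.tetra_frame <- function(p, h) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * h
  weighted_complex(list(sweep(v, 2L, p, "+")), 1, validate = FALSE)
}

#' Packaged 3D practice world
#'
#' Same construction as [practice_world_2d()] in a 3D space: the z axis
#' separates consonant-like clusters (near the x-y plane) from vowel-like
#' clusters (above it), the exemplar traces a vowel-dwelling CVC path, and
#' the starting silhouette is the same path of small tetrahedra translated
#' by `offset`.
#'
#' @inheritParams practice_world_2d
#' @export
practice_world_3d <- function(seed = 1L, offset = c(-8, 0, 0), jitter_sd = 0.15,
                              half_width = 2) {
  set.seed(child_seed(seed, "practice3d"))
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0),
                   c(0, 0, 14), c(8, 0, 14), c(16, 0, 14))
  ids <- c("C1", "C2", "C3", "V1", "V2", "V3")
  offs <- cbind(.compass_offsets(0.5), 0)
  clusters <- lapply(seq_along(ids), function(i) {
    js <- lapply(seq_len(nrow(offs)), function(j) {
      pos <- centers[i, ] + offs[j, ] + stats::rnorm(3L, sd = jitter_sd)
      juncture(sprintf("%s_j%d", ids[i], j), pos, pos)
    })
    cluster(ids[i], js)
  })
  map <- pm_map(clusters)
  pc <- cluster_centers(map, "perceptual")
  path <- .cvc_path(pc[2L, ], pc[5L, ], pc[3L, ])
  e <- exemplar("cvc3d", path)
  sil_centers <- sweep(path, 2L, offset, "+")
  frames <- lapply(seq_len(nrow(sil_centers)), function(t)
    .tetra_frame(sil_centers[t, ], half_width))
  sil <- silhouette("cvc3d", frames, iteration = 1L)
  list(map = map, sil = sil, e = e, params = activation_params())
}
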