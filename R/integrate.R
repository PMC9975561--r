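#' Perceptual-motor integration of a silhouette and an exemplar
#'
#' The production engine.  At each time step the silhouette's frame
#' activates clusters in motor space (time-varying, weight-sensitive) while
#' the exemplar activates clusters in perceptual space (all at once); the
#' two are combined per cluster by the geometric mean, optionally smoothed
#' over a look-back/look-ahead window, and the output point is the
#' activation-weighted average of cluster motor centres.  The perceptual
#' image of the output uses the same activations with perceptual centres.
#'
#' A time step where no cluster is co-activated carries the previous output
#' point forward (at `t = 1`, the frame's weighted centroid and the plain
#' mean of perceptual centres), with a message.  If no cluster is ever
#' co-activated the integration fails with an error naming the first dead
#' time step.
#'
#' @param sil a [silhouette()].
#' @param e an [exemplar()].
#' @param map a [pm_map()].
#' @param params an [activation_params()].
#' @param .cache optional environment memoising geometry-only distance
#'   matrices across repeated integrations of the same word (used by
#'   [run_practice()]); safe to ignore.
#' @return an object of class `output_trajectory` with elements `motor` and
#'   `perceptual` (equal-length [trajectory()]s), `concept`, and the
#'   `activations` grid (T x clusters).
#' @export
integrate_word <- function(sil, e, map, params = activation_params(),
                           .cache = NULL) {
  T_ <- length(sil$frames)
  mgrid <- motor_activation_grid(sil, map, params, cache = .cache)
  pvec <- if (!is.null(.cache) && !is.null(.cache$pvec)) .cache$pvec
          else exemplar_activation_vector(e, map, params)
  if (!is.null(.cache)) .cache$pvec <- pvec
  combined <- sweep(sqrt(mgrid), 2L, sqrt(pvec), "*")
  combined <- smooth_activation_grid(combined, params$lookback, params$lookahead)
  alive <- rowSums(combined) > 0
  if (!any(alive))
    stop_dualex(sprintf(
      "integration failure: no cluster co-activated at any time step (first dead step t=%d)",
      which(!alive)[1L]), "dualex_integration_failure")
  motor <- matrix(NA_real_, T_, map$motor_dim)
  perc <- matrix(NA_real_, T_, map$perceptual_dim)
  pcenters <- cluster_centers(map, "perceptual")
  for (t in seq_len(T_)) {
    if (alive[t]) {
      motor[t, ] <- estimate_position(combined[t, ], map, "motor")
      perc[t, ] <- estimate_position(combined[t, ], map, "perceptual")
    } else if (t == 1L) {
      message("integration: no co-activated cluster at t=1; using frame centroid")
      motor[t, ] <- complex_centroid(sil$frames[[1L]])
      perc[t, ] <- colMeans(pcenters)
    } else {
      message(sprintf("integration: no co-activated cluster at t=%d; carrying forward", t))
      motor[t, ] <- motor[t - 1L, ]
      perc[t, ] <- perc[t - 1L, ]
    }
  }
  output_trajectory(sil$concept, motor, perc, combined)
}

output_trajectory <- function(concept, motor, perceptual, activations = NULL) {
  if (nrow(motor) == 1L) {    # single-step words still form trajectories
    motor <- rbind(motor, motor)
    perceptual <- rbind(perceptual, perceptual)
  }
  structure(list(concept = as.character(concept),
                 motor = trajectory(motor),
                 perceptual = trajectory(perceptual),
                 activations = activations),
            class = "output_trajectory")
}

#' @export
print.output_trajectory <- function(x, ...) {
  cat(sprintf("<output trajectory '%s': %d steps, motor %dD -> perceptual %dD>\n",
              x$concept, nrow(x$motor), ncol(x$motor), ncol(x$perceptual)))
  invisible(x)
}

#' @export
plot.output_trajectory <- function(x, e = NULL, ...) {
  if (ncol(x$perceptual) != 2L)
    stop_dualex("plotting supports 2D outputs only", "dualex_invalid_argument")
  P <- unclass(x$perceptual)
  rng <- P
  if (!is.null(e)) rng <- rbind(rng, unclass(e$trajectory))
  graphics::plot(rng, type = "n", xlab = "perceptual x", ylab = "perceptual y",
                 main = sprintf("output vs exemplar ('%s')", x$concept), ...)
  graphics::lines(P, col = "red"); graphics::points(P, col = "red", pch = 16)
  if (!is.null(e)) {
    E <- unclass(e$trajectory)
    graphics::lines(E, col = "purple", lty = 2)
    graphics::points(E, col = "purple", pch = 1)
  }
  invisible(x)
}

# CSV export of an output trajectory: t, motor coords, perceptual coords
output_trajectory_df <- function(x) {
  m <- unclass(x$motor); p <- unclass(x$perceptual)
  colnames(m) <- paste0("motor_", seq_len(ncol(m)))
  colnames(p) <- paste0("perceptual_", seq_len(ncol(p)))
  data.frame(t = seq_len(nrow(m)), m, p)
}
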