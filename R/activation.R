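#' Activation parameters
#'
#' Cluster activation falls off linearly with distance from its source (a
#' silhouette region in motor space, an exemplar point in perceptual space),
#' from `highest_*` at distance zero, bottoming out at zero at distance
#' `highest_* / dropoff_*`.  The defaults (1 and 0.1, so a reach of 10 model
#' units) are the values used throughout the simulations.  `lookback` /
#' `lookahead` give an optional centred moving-average window applied to the
#' combined activation pattern over time (default off).
#'
#' @param highest_motor,highest_perceptual peak activation (> 0).
#' @param dropoff_motor,dropoff_perceptual activation lost per unit distance
#'   (> 0).
#' @param lookback,lookahead window extent in time steps (>= 0).
#' @return an object of class `activation_params`.
#' @export
activation_params <- function(highest_motor = 1, dropoff_motor = 0.1,
                              highest_perceptual = 1, dropoff_perceptual = 0.1,
                              lookback = 0L, lookahead = 0L) {
  check_number(highest_motor, "highest_motor", min = 1e-12)
  check_number(dropoff_motor, "dropoff_motor", min = 1e-12)
  check_number(highest_perceptual, "highest_perceptual", min = 1e-12)
  check_number(dropoff_perceptual, "dropoff_perceptual", min = 1e-12)
  structure(list(highest_motor = highest_motor, dropoff_motor = dropoff_motor,
                 highest_perceptual = highest_perceptual,
                 dropoff_perceptual = dropoff_perceptual,
                 lookback = check_count(lookback, "lookback", 0L),
                 lookahead = check_count(lookahead, "lookahead", 0L)),
            class = "activation_params")
}

#' Motor activation of a single juncture by a silhouette frame
#'
#' Each subregion contributes `max(0, highest - dropoff * distance)` where
#' the distance is from the juncture's motor point to the closed simplex;
#' the frame's activation is the weight-weighted average of the per-region
#' terms.  With a single region (or uniform weights over regions at equal
#' distance) this reduces to the plain linear drop-off rule.
#'
#' @param frame a [weighted_complex()] (the silhouette's region at time t).
#' @param j a [juncture()].
#' @param params an [activation_params()].
#' @return a number in `[0, highest_motor]`.
#' @export
juncture_motor_activation <- function(frame, j, params = activation_params()) {
  if (length(frame$simplices) < 1L)
    stop_dualex("empty frame", "dualex_invalid_argument")
  d <- frame_point_distances(frame$simplices, rbind(j$motor))[, 1L]
  terms <- pmax(0, params$highest_motor - params$dropoff_motor * d)
  sum(frame$weights * terms) / sum(frame$weights)
}

#' Motor activation of a cluster at time t
#'
#' The mean of [juncture_motor_activation()] over the cluster's junctures:
#' activation spreads evenly within a cluster, so all its junctures share
#' one value.
#'
#' @param sil a [silhouette()].
#' @param t time step in `1..T`.
#' @param cl a [cluster()].
#' @inheritParams juncture_motor_activation
#' @export
cluster_motor_activation <- function(sil, t, cl, params = activation_params()) {
  t <- check_count(t, "t")
  if (t > length(sil$frames))
    stop_dualex("t exceeds the silhouette's length", "dualex_invalid_argument")
  if (length(cl$junctures) < 1L)
    stop_dualex("empty cluster", "dualex_invalid_argument")
  mean(vapply(cl$junctures, function(j)
    juncture_motor_activation(sil$frames[[t]], j, params), 0))
}

#' Perceptual activation of a cluster by an exemplar
#'
#' The exemplar activates perceptual space all at once: the activation of a
#' cluster is the mean over exemplar points and cluster junctures of
#' `max(0, highest - dropoff * distance)` in perceptual space, and does not
#' vary with time.
#'
#' @param e an [exemplar()].
#' @param cl a [cluster()].
#' @inheritParams juncture_motor_activation
#' @export
cluster_exemplar_activation <- function(e, cl, params = activation_params()) {
  if (length(cl$junctures) < 1L)
    stop_dualex("empty cluster", "dualex_invalid_argument")
  P <- unclass(e$trajectory)
  J <- do.call(rbind, lapply(cl$junctures, `[[`, "perceptual"))
  if (ncol(P) != ncol(J))
    stop_dualex("perceptual dimensions differ", "dualex_invalid_argument")
  d2 <- outer(rowSums(P^2), rowSums(J^2), "+") - 2 * P %*% t(J)
  d <- sqrt(pmax(0, d2))
  mean(pmax(0, params$highest_perceptual - params$dropoff_perceptual * d))
}

#' Combine motor and perceptual activation
#'
#' The geometric mean `(motor * perceptual)^(1/2)`.  It acts as an AND gate:
#' a cluster with zero activation in either space contributes nothing, so
#' parts of the exemplar irrelevant to the current time cannot override the
#' silhouette's sequencing.
#'
#' @param motor_a,perc_a non-negative activations.
#' @export
combine_activations <- function(motor_a, perc_a) {
  if (any(motor_a < 0) || any(perc_a < 0))
    stop_dualex("activations must be non-negative", "dualex_invalid_argument")
  sqrt(motor_a * perc_a)
}

#' Activation-weighted position estimate
#'
#' The compromise the motor system reaches among competing clusters: the
#' activation-weighted average of cluster centres.  With motor centres this
#' is the output point ESTMOTOR(t); with perceptual centres it gives the
#' output's perceptual image.
#'
#' @param activations non-negative per-cluster activations.
#' @param map a [pm_map()].
#' @param space `"motor"` or `"perceptual"`.
#' @return a coordinate vector in the convex hull of the cluster centres,
#'   or `NULL` if all activations are zero (callers apply the documented
#'   fallback).
#' @export
estimate_position <- function(activations, map, space = c("motor", "perceptual")) {
  space <- match.arg(space)
  if (length(activations) != length(map$clusters))
    stop_dualex("one activation per cluster required", "dualex_invalid_argument")
  if (any(activations < 0))
    stop_dualex("activations must be non-negative", "dualex_invalid_argument")
  s <- sum(activations)
  if (s == 0) return(NULL)
  centers <- cluster_centers(map, space)
  colSums(centers * activations) / s
}

## ---- vectorised grids (internal) ------------------------------------------

# all junctures' motor points, plus the cluster index of each row
map_juncture_matrix <- function(map, space = c("motor", "perceptual")) {
  space <- match.arg(space)
  rows <- list(); idx <- integer(0)
  for (i in seq_along(map$clusters)) {
    for (j in map$clusters[[i]]$junctures) {
      rows[[length(rows) + 1L]] <- j[[space]]
      idx <- c(idx, i)
    }
  }
  list(points = do.call(rbind, rows), cluster = idx)
}

# T x n_cluster motor activation grid for a silhouette against a map.
# `cache` (an environment) memoises the geometry-only distance matrices per
# frame: Case-1 absorption changes weights but not geometry, so practice
# loops invalidate entries only when a frame actually grows.
motor_activation_grid <- function(sil, map, params = activation_params(),
                                  cache = NULL) {
  jm <- if (!is.null(cache) && !is.null(cache$jm)) cache$jm
        else map_juncture_matrix(map, "motor")
  if (!is.null(cache)) cache$jm <- jm
  ncl <- length(map$clusters)
  grid <- matrix(0, nrow = length(sil$frames), ncol = ncl)
  csum <- t(vapply(seq_len(ncl), function(i) as.double(jm$cluster == i),
                   numeric(length(jm$cluster))))
  csum <- csum / rowSums(csum)
  for (t in seq_along(sil$frames)) {
    f <- sil$frames[[t]]
    D <- NULL
    old <- if (!is.null(cache) && length(cache$D) >= t) cache$D[[t]] else NULL
    if (!is.null(old) && identical(attr(old, "k"), nrow(f$simplices[[1L]]))) {
      if (nrow(old) == length(f$simplices)) {
        D <- old                                  # Case-1 history: geometry unchanged
      } else if (nrow(old) < length(f$simplices)) {
        # Case-2 history: absorption only appends simplices, so old rows stand
        extra <- frame_point_distances(f$simplices[(nrow(old) + 1L):length(f$simplices)],
                                       jm$points)
        D <- rbind(old, extra)
        attr(D, "k") <- attr(old, "k")
      }
    }
    if (is.null(D)) {
      D <- frame_point_distances(f$simplices, jm$points)     # nsimp x njunc
      attr(D, "k") <- nrow(f$simplices[[1L]])
    }
    if (!is.null(cache)) cache$D[[t]] <- D
    terms <- params$highest_motor - params$dropoff_motor * D
    terms[terms < 0] <- 0
    ja <- as.vector(crossprod(terms, f$weights)) / sum(f$weights)
    grid[t, ] <- as.vector(csum %*% ja)
  }
  grid
}

# per-cluster exemplar activation vector
exemplar_activation_vector <- function(e, map, params = activation_params()) {
  vapply(map$clusters, function(cl) cluster_exemplar_activation(e, cl, params), 0)
}

# centred moving average over time of an activation grid
smooth_activation_grid <- function(grid, lookback = 0L, lookahead = 0L) {
  if (lookback == 0L && lookahead == 0L) return(grid)
  T_ <- nrow(grid)
  out <- grid
  for (t in seq_len(T_)) {
    w <- max(1L, t - lookback):min(T_, t + lookahead)
    out[t, ] <- colMeans(grid[w, , drop = FALSE])
  }
  out
}
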