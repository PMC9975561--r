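#' Trajectories through motor or perceptual space
#'
#' A trajectory is an ordered sequence of at least two points of a common
#' dimension, uniformly parameterised over its index range.  Evaluation
#' between samples is by linear interpolation.  Trajectories represent both
#' executed motor paths and perceptual wordforms (exemplars).
#'
#' @param points a numeric matrix (rows are points) or a list of numeric
#'   vectors, all of the same length.
#' @return an object of class `trajectory`: a numeric matrix with one row
#'   per time sample.
#' @examples
#' trajectory(rbind(c(0, 0), c(1, 1), c(2, 0)))
#' @export
trajectory <- function(points) {
  m <- as_point_matrix(points)
  if (nrow(m) < 2L)
    stop_dualex("a trajectory needs at least 2 points", "dualex_invalid_argument")
  if (!all(is.finite(m)))
    stop_dualex("trajectory coordinates must be finite", "dualex_invalid_argument")
  structure(m, class = c("trajectory", "matrix", "array"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d points in %dD>\n", nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Resample a trajectory to a fixed number of points
#'
#' Samples `n` points at uniform parameter values over the original index
#' range, using linear interpolation between adjacent samples.  Endpoints are
#' preserved exactly; resampling at the original length is the identity.
#'
#' @param traj a [trajectory()].
#' @param n number of output points (`n >= 2`).
#' @return a `trajectory` with `n` rows.
#' @export
resample_trajectory <- function(traj, n) {
  traj <- trajectory(traj)
  n <- check_count(n, "n", min = 2L)
  len <- nrow(traj)
  if (n == len) return(traj)
  # parameter values in the original index scale 1..len
  s <- seq(1, len, length.out = n)
  i0 <- pmin(floor(s), len - 1L)
  frac <- s - i0
  out <- unclass(traj)[i0, , drop = FALSE] * (1 - frac) +
    unclass(traj)[i0 + 1L, , drop = FALSE] * frac
  out[1L, ] <- unclass(traj)[1L, ]    # endpoints bit-exact
  out[n, ] <- unclass(traj)[len, ]
  trajectory(out)
}

#' Distance between two trajectories (d_PERC)
#'
#' The perceptual distance used throughout the model: both trajectories are
#' aligned so that their endpoints line up, by resampling each to
#' `max(length(a), length(b))` uniformly spaced points with linear
#' interpolation, and the mean Euclidean distance between index-paired points
#' is returned.  The distance is symmetric, non-negative, and zero exactly
#' when the aligned point sequences coincide.
#'
#' @param a,b trajectories of equal dimension.
#' @return a single non-negative number.
#' @examples
#' a <- trajectory(rbind(c(0, 0), c(0, 2)))
#' b <- trajectory(rbind(c(1, 0), c(1, 2)))
#' trajectory_distance(a, b) # 1
#' @export
trajectory_distance <- function(a, b) {
  a <- trajectory(a); b <- trajectory(b)
  if (ncol(a) != ncol(b))
    stop_dualex("trajectories have different dimensions", "dualex_invalid_argument")
  n <- max(nrow(a), nrow(b))
  ra <- unclass(resample_trajectory(a, n))
  rb <- unclass(resample_trajectory(b, n))
  mean(sqrt(rowSums((ra - rb)^2)))
}
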