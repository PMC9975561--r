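#' Junctures, clusters, and the perceptual-motor map
#'
#' A juncture is a paired motor/perceptual point: a location in motor space
#' where established trajectories meet, linked to the sound produced there.
#' Clusters group nearby junctures into perceptual-motor control units; a
#' cluster's motor centre is the coordinate-wise mean of its junctures' motor
#' points (and symmetrically for the perceptual centre).  The
#' perceptual-motor map is the collection of all clusters in both spaces.
#'
#' @param motor,perceptual numeric coordinate vectors.
#' @param id identifier (coerced to character).
#' @return `juncture()` returns an object of class `juncture`.
#' @name pm_map
NULL

#' @rdname pm_map
#' @export
juncture <- function(id, motor, perceptual) {
  motor <- as.double(motor); perceptual <- as.double(perceptual)
  if (!all(is.finite(motor), is.finite(perceptual)))
    stop_dualex("juncture coordinates must be finite", "dualex_invalid_argument")
  structure(list(id = as.character(id), motor = motor, perceptual = perceptual),
            class = "juncture")
}

#' @rdname pm_map
#' @param junctures a non-empty list of [juncture()] objects.
#' @export
cluster <- function(id, junctures) {
  if (length(junctures) < 1L)
    stop_dualex("a cluster needs at least one juncture", "dualex_invalid_argument")
  md <- vapply(junctures, function(j) length(j$motor), 1L)
  pd <- vapply(junctures, function(j) length(j$perceptual), 1L)
  if (length(unique(md)) != 1L || length(unique(pd)) != 1L)
    stop_dualex("junctures in a cluster must agree in dimension",
                "dualex_invalid_argument")
  structure(list(id = as.character(id), junctures = junctures), class = "cluster")
}

#' @rdname pm_map
#' @export
motor_center <- function(x) UseMethod("motor_center")

#' @export
motor_center.cluster <- function(x) {
  colMeans(do.call(rbind, lapply(x$junctures, `[[`, "motor")))
}

#' @rdname pm_map
#' @export
perceptual_center <- function(x) UseMethod("perceptual_center")

#' @export
perceptual_center.cluster <- function(x) {
  colMeans(do.call(rbind, lapply(x$junctures, `[[`, "perceptual")))
}

#' @rdname pm_map
#' @param clusters a list of [cluster()] objects with unique ids.
#' @export
pm_map <- function(clusters) {
  if (length(clusters) < 1L)
    stop_dualex("a perceptual-motor map needs at least one cluster",
                "dualex_invalid_argument")
  ids <- vapply(clusters, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_dualex("cluster ids must be unique", "dualex_invalid_argument")
  md <- unique(unlist(lapply(clusters, function(cl)
    vapply(cl$junctures, function(j) length(j$motor), 1L))))
  pd <- unique(unlist(lapply(clusters, function(cl)
    vapply(cl$junctures, function(j) length(j$perceptual), 1L))))
  if (length(md) != 1L || length(pd) != 1L)
    stop_dualex("all junctures in a map must agree in dimension",
                "dualex_invalid_argument")
  structure(list(clusters = clusters, motor_dim = md, perceptual_dim = pd),
            class = "pm_map")
}

#' @export
print.pm_map <- function(x, ...) {
  nj <- sum(vapply(x$clusters, function(cl) length(cl$junctures), 1L))
  cat(sprintf("<perceptual-motor map: %d clusters, %d junctures, motor %dD, perceptual %dD>\n",
              length(x$clusters), nj, x$motor_dim, x$perceptual_dim))
  invisible(x)
}

# matrix of cluster motor (or perceptual) centers, one row per cluster
cluster_centers <- function(map, space = c("motor", "perceptual")) {
  space <- match.arg(space)
  f <- if (space == "motor") motor_center else perceptual_center
  do.call(rbind, lapply(map$clusters, f))
}

#' Exemplars: perceptual wordforms
#'
#' An exemplar is a whole-word perceptual representation: a trajectory
#' through perceptual space linked to a concept.  Exemplars come from the
#' ambient language; during production the exemplar activates clusters in
#' perceptual space all at once.
#'
#' @param concept concept identifier (coerced to character).
#' @param traj a [trajectory()] in perceptual space.
#' @export
exemplar <- function(concept, traj) {
  structure(list(concept = as.character(concept), trajectory = trajectory(traj)),
            class = "exemplar")
}

#' @export
print.exemplar <- function(x, ...) {
  cat(sprintf("<exemplar '%s': %d points in %dD perceptual space>\n",
              x$concept, nrow(x$trajectory), ncol(x$trajectory)))
  invisible(x)
}
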