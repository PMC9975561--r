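#' Save and load silhouettes as JSON
#'
#' Round-trip-exact serialisation: coordinates and weights are written as
#' 17-significant-digit decimal strings, which reproduce IEEE doubles
#' bit-exactly on re-parse.
#'
#' @param sil a [silhouette()].
#' @param path file path.
#' @export
save_silhouette <- function(sil, path) {
  obj <- list(
    concept = sil$concept,
    iteration = sil$iteration,
    T = length(sil$frames),
    motor_dim = complex_dim(sil$frames[[1L]]),
    frames = lapply(seq_along(sil$frames), function(t) {
      f <- sil$frames[[t]]
      list(t = t,
           simplices = lapply(f$simplices, function(S)
             lapply(seq_len(nrow(S)), function(i) .num_str(S[i, ]))),
           weights = .num_str(f$weights))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

.num_str <- function(x) vapply(x, function(v) sprintf("%.17g", v), "")

#' @rdname save_silhouette
#' @export
load_silhouette <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop_dualex(sprintf("malformed silhouette file '%s': %s",
                                        path, conditionMessage(e)),
                                "dualex_schema_error"))
  need <- c("concept", "iteration", "T", "motor_dim", "frames")
  if (!all(need %in% names(obj)))
    stop_dualex(sprintf("silhouette file '%s' missing fields: %s", path,
                        paste(setdiff(need, names(obj)), collapse = ", ")),
                "dualex_schema_error")
  frames <- lapply(obj$frames, function(fr) {
    sims <- lapply(fr$simplices, function(S)
      do.call(rbind, lapply(S, function(row) as.double(unlist(row)))))
    weighted_complex(sims, as.double(unlist(fr$weights)), validate = FALSE)
  })
  if (length(frames) != obj$T)
    stop_dualex(sprintf("silhouette file '%s': frame count differs from T", path),
                "dualex_schema_error")
  silhouette(obj$concept, frames, iteration = obj$iteration)
}

#' Save and load perceptual-motor maps as JSON
#'
#' Schema: `{motor_dim, perceptual_dim, clusters: [{id, junctures: [{id,
#' motor: [...], perceptual: [...]}]}]}`, with coordinates as decimal
#' strings for an exact round trip.
#'
#' @param map a [pm_map()].
#' @param path file path.
#' @export
save_map <- function(map, path) {
  obj <- list(
    motor_dim = map$motor_dim,
    perceptual_dim = map$perceptual_dim,
    clusters = lapply(map$clusters, function(cl) list(
      id = cl$id,
      junctures = lapply(cl$junctures, function(j) list(
        id = j$id, motor = .num_str(j$motor), perceptual = .num_str(j$perceptual))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop_dualex(sprintf("malformed map file '%s': %s", path,
                                        conditionMessage(e)),
                                "dualex_schema_error"))
  if (!all(c("motor_dim", "perceptual_dim", "clusters") %in% names(obj)))
    stop_dualex(sprintf("map file '%s' missing fields", path),
                "dualex_schema_error")
  clusters <- lapply(obj$clusters, function(cl)
    cluster(cl$id, lapply(cl$junctures, function(j)
      juncture(j$id, as.double(unlist(j$motor)), as.double(unlist(j$perceptual))))))
  map <- pm_map(clusters)
  if (map$motor_dim != obj$motor_dim || map$perceptual_dim != obj$perceptual_dim)
    stop_dualex(sprintf("map file '%s': declared dimensions disagree with data",
                        path), "dualex_schema_error")
  map
}
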