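#' Silhouettes: motor wordforms
#'
#' A silhouette is a temporally structured motor memory for a concept: a map
#' from discrete time `t = 1..T` to a weighted region of motor space (a
#' [weighted_complex()]).  It grows by absorbing the motor traces of
#' successful productions, which skews its weights toward frequently used
#' paths.
#'
#' @param concept concept identifier.
#' @param frames list of [weighted_complex()] objects, one per time step,
#'   all with the same ambient motor dimension.
#' @param iteration number of traces absorbed so far (`n >= 0`).
#' @return an object of class `silhouette`.
#' @export
silhouette <- function(concept, frames, iteration = 0L) {
  if (length(frames) < 1L)
    stop_dualex("a silhouette needs at least one frame", "dualex_invalid_argument")
  dims <- unique(vapply(frames, complex_dim, 1L))
  if (length(dims) != 1L)
    stop_dualex("all frames must share the motor dimension", "dualex_invalid_argument")
  iteration <- check_count(iteration, "iteration", min = 0L)
  structure(list(concept = as.character(concept), frames = frames,
                 iteration = iteration),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette '%s': T=%d, motor %dD, iteration %d, total weight %g>\n",
              x$concept, length(x$frames), complex_dim(x$frames[[1L]]),
              x$iteration, silhouette_total_weight(x)))
  invisible(x)
}

#' @rdname silhouette
#' @param x a `silhouette`.
#' @export
silhouette_total_weight <- function(x) {
  sum(vapply(x$frames, function(f) sum(f$weights), 0))
}

#' Build a first silhouette from a single motor trace
#'
#' The first successful production of a concept seeds its silhouette: each
#' frame is the degenerate complex consisting of the single trace point with
#' weight one.  Later traces expand the frames through [absorb_trace()].
#'
#' @param concept concept identifier.
#' @param m a motor [trajectory()], one point per time step.
#' @export
silhouette_from_trace <- function(concept, m) {
  m <- trajectory(m)
  frames <- lapply(seq_len(nrow(m)), function(t)
    weighted_complex(list(m[t, , drop = FALSE]), 1, validate = FALSE))
  silhouette(concept, frames, iteration = 1L)
}

#' Absorb a motor trace into a silhouette
#'
#' Applies [absorb_point()] frame-by-frame: at each time step the trace
#' point either reweights the subregion(s) containing it (Case 1) or extends
#' the frame convexly with weight-1 simplices (Case 2).  The silhouette's
#' iteration count increases by one.  Traces whose length differs from the
#' silhouette's are resampled to `T` first.
#'
#' @param sil a [silhouette()].
#' @param m a motor [trajectory()] of matching dimension.
#' @export
absorb_trace <- function(sil, m) {
  m <- trajectory(m)
  T_ <- length(sil$frames)
  if (ncol(m) != complex_dim(sil$frames[[1L]]))
    stop_dualex("trace and silhouette motor dimensions differ",
                "dualex_invalid_argument")
  if (nrow(m) != T_) {
    if (T_ < 2L)
      stop_dualex("cannot resample a trace onto a single-frame silhouette",
                  "dualex_invalid_argument")
    m <- resample_trajectory(m, T_)
  }
  frames <- sil$frames
  cases <- integer(T_)
  for (t in seq_len(T_)) {
    frames[[t]] <- absorb_point(frames[[t]], m[t, ])
    cases[t] <- if (identical(attr(frames[[t]], "case"), 1)) 1L else 2L
  }
  out <- silhouette(sil$concept, frames, iteration = sil$iteration + 1L)
  attr(out, "cases") <- cases
  out
}

#' @export
plot.silhouette <- function(x, t = seq_along(x$frames), ...) {
  if (complex_dim(x$frames[[1L]]) != 2L)
    stop_dualex("plotting supports 2D silhouettes only", "dualex_invalid_argument")
  V <- do.call(rbind, lapply(x$frames[t], complex_vertices))
  graphics::plot(V, type = "n", xlab = "motor x", ylab = "motor y",
                 main = sprintf("silhouette '%s'", x$concept), ...)
  shade <- grDevices::grey(seq(0.85, 0.4, length.out = length(t)))
  for (i in seq_along(t)) {
    f <- x$frames[[t[i]]]
    for (S in f$simplices) {
      if (nrow(S) >= 3L) graphics::polygon(S[, 1L], S[, 2L], border = shade[i])
      else graphics::lines(S[, 1L], S[, 2L], col = shade[i])
    }
  }
  invisible(x)
}
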