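## Internal helpers shared across modules.

# absolute tolerance for geometric containment / degeneracy decisions
.dualex_tol <- 1e-9

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dualex <- function(msg, class) {
  stop(structure(
    class = c(class, "dualex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop_dualex(sprintf("`%s` must be a single finite number >= %s", name, min),
                "dualex_invalid_argument")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_dualex(sprintf("`%s` must be a single integer >= %d", name, min),
                "dualex_invalid_argument")
  invisible(as.integer(x))
}

as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.numeric(x)) return(matrix(as.double(x), nrow = 1L))
  if (is.list(x)) return(do.call(rbind, lapply(x, as.double)))
  stop_dualex("cannot interpret input as coordinates", "dualex_invalid_argument")
}

## Derive a child seed (< 2^31) from a master seed and a stream label.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}
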