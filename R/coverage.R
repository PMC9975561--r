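#' Vocabulary coverage probability
#'
#' The probability that a random expressive vocabulary `V` of size `m`,
#' drawn from a language `L` of size `n`, contains at least `k` of the
#' `k + r` words of `L` perceptually closest to a novel target — i.e. that
#' the `k` best words available for building an A-silhouette are among the
#' `k + r` best in the whole language.  Evaluated as the closed-form sum
#'
#' \deqn{\sum_{i=0}^{r} \frac{(k+r)!}{(k+i)!\,(r-i)!} \cdot
#'       \frac{(n-k-r)!}{(m-k-i)!\,(n-r-m+i)!} \cdot \frac{m!\,(n-m)!}{n!}}
#'
#' with log-gamma arithmetic (no overflow at `n = 2500`).  The sum equals
#' the hypergeometric tail `P(X >= k)` with `X ~ Hypergeom(n, k + r, m)`,
#' which serves as an independent cross-check in the tests, never as the
#' implementation.
#'
#' @param n language size (`L`).
#' @param m expressive vocabulary size (`V`), `k <= m <= n`.
#' @param k number of neighbours used to build an A-silhouette.
#' @param r slack: the `p = k + r` best words are considered close enough.
#' @return a probability in `[0, 1]`.
#' @examples
#' coverage_probability(2500, 500, 3, 4) # ~0.148
#' @export
coverage_probability <- function(n, m, k, r) {
  spec <- coverage_spec(n, m, k, r)
  n <- spec$n; m <- spec$m; k <- spec$k; r <- spec$r
  total <- 0
  for (i in 0:r) {
    if (m - k - i < 0 || n - r - m + i < 0) next
    total <- total + .coverage_term(n, m, k, r, i)
  }
  min(1, max(0, total))
}

# one term of the printed sum,
#   (k+r)! / ((k+i)! (r-i)!) * (n-k-r)! / ((m-k-i)! (n-r-m+i)!) * m!(n-m)!/n!
# For small k + r the factorials are regrouped by the exact identity
#   C(k+r, k+i) C(n-k-r, m-k-i) / C(n, m)
#     = C(m, k+i) C(n-m, r-i) / C(n, k+r),
# whose binomials all have lower index <= k + r and evaluate as short exact
# products in double precision (full relative accuracy, no overflow up to
# n in the thousands).  Large k + r falls back to log-gamma arithmetic.
.coverage_term <- function(n, m, k, r, i) {
  if (k + r <= 40 && choose(n, k + r) < .Machine$double.xmax / 1e16) {
    return(choose(m, k + i) * choose(n - m, r - i) / choose(n, k + r))
  }
  lf <- function(x) lgamma(x + 1)
  exp(lf(k + r) - lf(k + i) - lf(r - i) +
      lf(n - k - r) - lf(m - k - i) - lf(n - r - m + i) +
      lf(m) + lf(n - m) - lf(n))
}

# validated coverage parameter set
coverage_spec <- function(n, m, k, r) {
  n <- check_count(n, "n"); m <- check_count(m, "m")
  k <- check_count(k, "k"); r <- check_count(r, "r", min = 0L)
  if (!(k <= m && m <= n && k + r <= n))
    stop_dualex("need 1 <= k <= m <= n and k + r <= n", "dualex_invalid_argument")
  list(n = n, m = m, k = k, r = r)
}

#' Monte-Carlo estimate of the coverage probability
#'
#' Draws `reps` random `m`-subsets of `1..n` and returns the fraction in
#' which at least `k` of the indices `1..(k+r)` (the "best" words) are
#' included.  A simulation oracle for [coverage_probability()].
#'
#' @inheritParams coverage_probability
#' @param reps number of replicates (`>= 1`).
#' @param seed optional integer seed.
#' @export
coverage_probability_mc <- function(n, m, k, r, reps = 10000L, seed = NULL) {
  spec <- coverage_spec(n, m, k, r)
  reps <- check_count(reps, "reps")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  best <- seq_len(spec$k + spec$r)
  for (i in seq_len(reps)) {
    v <- sample.int(spec$n, spec$m)
    if (sum(v <= spec$k + spec$r) >= spec$k) hits <- hits + 1L
  }
  hits / reps
}

#' Coverage probability table over vocabulary sizes
#'
#' Long-format table of [coverage_probability()] over a grid of expressive
#' vocabulary sizes for several `(k, p = k + r)` settings; the probability
#' is non-decreasing in `m` for fixed `(k, p)`.
#'
#' @param n language size.
#' @param kp list of `c(k, p)` pairs (with `p >= k`).
#' @param m_grid vocabulary sizes to evaluate.
#' @return data frame with columns `k`, `p`, `m`, `probability`.
#' @export
coverage_table <- function(n = 2500L,
                           kp = list(c(1, 5), c(3, 6), c(3, 7)),
                           m_grid = seq(100L, n, by = 100L)) {
  rows <- list()
  for (pair in kp) {
    k <- pair[1L]; p <- pair[2L]
    if (p < k) stop_dualex("p must be >= k", "dualex_invalid_argument")
    for (m in m_grid) {
      if (m < k) next
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, p = p, m = m,
        probability = coverage_probability(n, m, k, p - k))
    }
  }
  do.call(rbind, rows)
}
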