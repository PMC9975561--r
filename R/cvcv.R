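#' Configuration of the synthetic CVCV world
#'
#' The 2D world behind the vocabulary-size experiment: `n_consonant`
#' consonantal and `n_vowel` vocalic clusters laid out in two rows of motor
#' space separated along y, with the perceptual space keeping the
#' consonant/vowel row structure but shuffling cluster x-positions within
#' each row (different topologies for the two spaces).  Words are all CVCV
#' centre-to-centre paths; silhouettes are 7 uniformly weighted square
#' regions (odd steps on the clusters, even steps midway between them).
#'
#' Defaults: 6 + 6 clusters spaced 8 units apart in x, rows 14 units apart.
#' Relative to the activation reach of 10 units (peak 1, drop-off 0.1 per
#' unit) this makes activation selective: a silhouette region on a cluster
#' activates it fully, activates its within-row neighbours only weakly
#' (distance 8, activation 0.2), and leaves the other row silent — the
#' consonant/vowel separation the world is meant to encode.  4 junctures
#' per cluster at compass offsets of half `juncture_radius = 1` (clusters
#' stay well separated), squares of half-width 1, `T = 7`.
#'
#' @param n_consonant,n_vowel clusters per row.
#' @param cluster_spacing x distance between adjacent cluster centres.
#' @param row_separation y distance between the consonant and vowel rows.
#' @param junctures_per_cluster junctures per cluster (compass layout).
#' @param juncture_radius juncture placement radius.
#' @param region_half_width half-width of the square silhouette regions.
#' @param params an [activation_params()].
#' @export
cvcv_config <- function(n_consonant = 6L, n_vowel = 6L,
                        cluster_spacing = 8, row_separation = 14,
                        junctures_per_cluster = 4L, juncture_radius = 1,
                        region_half_width = 1,
                        params = activation_params()) {
  structure(list(
    n_consonant = check_count(n_consonant, "n_consonant"),
    n_vowel = check_count(n_vowel, "n_vowel"),
    cluster_spacing = check_number(cluster_spacing, "cluster_spacing", 1e-9),
    row_separation = check_number(row_separation, "row_separation", 1e-9),
    junctures_per_cluster = check_count(junctures_per_cluster, "junctures_per_cluster"),
    juncture_radius = check_number(juncture_radius, "juncture_radius", 1e-9),
    region_half_width = check_number(region_half_width, "region_half_width", 1e-9),
    T = 7L, params = params), class = "cvcv_config")
}

#' Build the perceptual-motor map of the CVCV world
#'
#' Motor space: consonant-row centres at `y = 0`, vowel-row centres at
#' `y = row_separation`, evenly spaced in x.  Perceptual space: identical
#' row structure, but x-positions permuted within each row by a seeded
#' shuffle (the identity permutation gives identical layouts).  Each
#' juncture's perceptual point carries the same offset from its cluster's
#' perceptual centre as its motor point does from the motor centre.
#'
#' @param cfg a [cvcv_config()].
#' @param seed integer seed for the x-shuffle.
#' @export
build_map <- function(cfg, seed = 1L) {
  set.seed(child_seed(seed, "shuffle"))
  nc <- cfg$n_consonant; nv <- cfg$n_vowel
  cx <- (seq_len(nc) - 1L) * cfg$cluster_spacing
  vx <- (seq_len(nv) - 1L) * cfg$cluster_spacing
  perm_c <- sample.int(nc)
  perm_v <- sample.int(nv)
  offs <- .regular_offsets(cfg$junctures_per_cluster, cfg$juncture_radius / 2)
  mk <- function(id, mcenter, pcenter) {
    js <- lapply(seq_len(nrow(offs)), function(j)
      juncture(sprintf("%s_j%d", id, j), mcenter + offs[j, ], pcenter + offs[j, ]))
    cluster(id, js)
  }
  clusters <- c(
    lapply(seq_len(nc), function(i)
      mk(sprintf("C%d", i), c(cx[i], 0), c(cx[perm_c[i]], 0))),
    lapply(seq_len(nv), function(i)
      mk(sprintf("V%d", i), c(vx[i], cfg$row_separation),
         c(vx[perm_v[i]], cfg$row_separation))))
  map <- pm_map(clusters)
  attr(map, "shuffle") <- list(consonant = perm_c, vowel = perm_v, seed = seed)
  map
}

.regular_offsets <- function(n, r) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(th), r * sin(th))
}

#' Build the full CVCV language
#'
#' Enumerates every (C, V, C, V) cluster tuple — `(n_c * n_v)^2` words, 1296
#' at the defaults — and gives each word a 7-frame silhouette of uniformly
#' weighted squares along its motor centre-to-centre path (odd frames on the
#' clusters, even frames at segment midpoints) and an exemplar that is the
#' perceptual image of that centre path.
#'
#' @param map a map from [build_map()].
#' @param cfg the same [cvcv_config()].
#' @return an object of class `cvcv_language`: list with `map`, `words`
#'   (named list of `list(silhouette =, exemplar =)`), `cfg`.
#' @export
build_language <- function(map, cfg) {
  ids <- vapply(map$clusters, `[[`, "", "id")
  cons <- which(startsWith(ids, "C"))
  vows <- which(startsWith(ids, "V"))
  mc <- cluster_centers(map, "motor")
  pc <- cluster_centers(map, "perceptual")
  h <- cfg$region_half_width
  words <- list()
  for (c1 in cons) for (v1 in vows) for (c2 in cons) for (v2 in vows) {
    wid <- paste(ids[c(c1, v1, c2, v2)], collapse = "-")
    anchors <- c(c1, v1, c2, v2)
    mpath <- .seven_step_path(mc[anchors, , drop = FALSE])
    ppath <- .seven_step_path(pc[anchors, , drop = FALSE])
    frames <- lapply(seq_len(7L), function(t) square_frame(mpath[t, ], h))
    words[[wid]] <- list(
      silhouette = silhouette(wid, frames, iteration = 1L),
      exemplar = exemplar(wid, ppath))
  }
  structure(list(map = map, words = words, cfg = cfg), class = "cvcv_language")
}

# 7-point path: anchors at odd steps, midpoints at even steps
.seven_step_path <- function(anchors) {
  out <- matrix(NA_real_, 7L, ncol(anchors))
  out[c(1L, 3L, 5L, 7L), ] <- anchors
  for (i in c(2L, 4L, 6L))
    out[i, ] <- (out[i - 1L, ] + out[i + 1L, ]) / 2
  out
}

#' @export
print.cvcv_language <- function(x, ...) {
  cat(sprintf("<CVCV language: %d words over %d clusters>\n",
              length(x$words), length(x$map$clusters)))
  invisible(x)
}

#' Sample an expressive vocabulary from the language
#'
#' A seeded uniform sample of words without replacement, never containing
#' `exclude` (the novel word stays receptive-only).  Sampling is nested:
#' enlarging `size` under the same seed keeps all previously sampled words
#' and adds new ones, matching the way the vocabulary-size experiment grows
#' its vocabulary.
#'
#' @param lang a [build_language()] result.
#' @param size expressive vocabulary size (`<= number of words - 1` when
#'   excluding).
#' @param exclude word id to withhold, or `NULL`.
#' @param seed integer seed.
#' @return a [lexicon()]; the excluded word's exemplar (if any) is placed in
#'   the receptive slot.
#' @export
sample_vocabulary <- function(lang, size, exclude = NULL, seed = 1L) {
  ids <- names(lang$words)
  pool <- setdiff(ids, exclude)
  size <- check_count(size, "size")
  if (size > length(pool))
    stop_dualex("vocabulary size exceeds available words",
                "dualex_invalid_argument")
  set.seed(child_seed(seed, "vocab"))
  perm <- sample(pool)
  sel <- perm[seq_len(size)]
  receptive <- if (!is.null(exclude))
    stats::setNames(lapply(exclude, function(w) lang$words[[w]]$exemplar), exclude)
  else list()
  lexicon(lang$words[sel], receptive)
}

#' The vocabulary-size experiment
#'
#' For each of `runs` independent runs: pick a random novel word from the
#' language, grow a nested expressive vocabulary through `sizes`, and at
#' each size build an A-silhouette from the `k` perceptually closest
#' vocabulary words, integrate it with the novel word's exemplar, and record
#' the perceptual distance between output and exemplar (production
#' accuracy; smaller is better).
#'
#' @param lang a [build_language()] result.
#' @param sizes ascending vocabulary sizes (default 5, 10, 20, ...,
#'   640, 1200).
#' @param runs number of independent runs (default 20).
#' @param k neighbours per A-silhouette (default 3).
#' @param seed master seed; run-level seeds are derived from it.
#' @return an object of class `vocab_experiment`: list with `results`
#'   (data frame `run`, `vocab_size`, `novel_word`, `distance`) and
#'   `summary` (`vocab_size`, `mean`, `sd`).
#' @export
run_vocab_experiment <- function(lang, sizes = c(5L, 10L, 20L, 40L, 80L, 160L,
                                                 320L, 640L, 1200L),
                                 runs = 20L, k = 3L, seed = 1L) {
  runs <- check_count(runs, "runs"); k <- check_count(k, "k")
  sizes <- vapply(sizes, check_count, 1L, name = "sizes")
  if (is.unsorted(sizes, strictly = TRUE))
    stop_dualex("sizes must be strictly ascending", "dualex_invalid_argument")
  if (sizes[1L] < k)
    stop_dualex("smallest vocabulary is below k", "dualex_insufficient_vocabulary")
  ids <- names(lang$words)
  rows <- vector("list", runs * length(sizes))
  ri <- 0L
  for (run in seq_len(runs)) {
    set.seed(child_seed(seed, paste0("novel", run)))
    novel <- sample(ids, 1L)
    target <- lang$words[[novel]]$exemplar
    # target-to-word distances, computed once per run
    d_all <- vapply(lang$words, function(w)
      trajectory_distance(w$exemplar$trajectory, target$trajectory), 0)
    pool <- setdiff(ids, novel)
    set.seed(child_seed(seed, paste0("vocab", run)))
    perm <- sample(pool)
    for (size in sizes) {
      sel <- perm[seq_len(size)]
      nb_ids <- sel[order(d_all[sel], sel)][seq_len(k)]
      sils <- align_silhouettes(lapply(nb_ids, function(id)
        lang$words[[id]]$silhouette))
      frames <- lapply(seq_len(length(sils[[1L]]$frames)), function(t)
        combine_frames(scale_weights(lapply(sils, function(s) s$frames[[t]]))))
      asil <- silhouette(novel, frames, iteration = 0L)
      out <- integrate_word(asil, target, lang$map, lang$cfg$params)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(run = run, vocab_size = size, novel_word = novel,
                               distance = trajectory_distance(out$perceptual,
                                                              target$trajectory))
    }
  }
  results <- do.call(rbind, rows)
  agg_m <- tapply(results$distance, results$vocab_size, mean)
  agg_s <- tapply(results$distance, results$vocab_size, stats::sd)
  summary <- data.frame(vocab_size = as.integer(names(agg_m)),
                        mean = as.vector(agg_m), sd = as.vector(agg_s))
  summary <- summary[order(summary$vocab_size), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, k = k, seed = seed),
            class = "vocab_experiment")
}

#' @export
print.vocab_experiment <- function(x, ...) {
  cat(sprintf("<vocabulary-size experiment: %d runs x %d sizes, k=%d>\n",
              max(x$results$run), nrow(x$summary), x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.vocab_experiment <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$vocab_size, s$mean, log = "x", type = "b", pch = 16,
                 xlab = "expressive vocabulary size (log scale)",
                 ylab = "mean output-exemplar distance",
                 ylim = range(c(s$mean - s$sd, s$mean + s$sd)), ...)
  graphics::lines(s$vocab_size, s$mean + s$sd, lty = 3)
  graphics::lines(s$vocab_size, s$mean - s$sd, lty = 3)
  invisible(x)
}
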