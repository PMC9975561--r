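# dualex

Simulation of whole-word speech production under a **dual lexicon**: every
concept is linked to a perceptual wordform (an *exemplar* — a trajectory
through perceptual space, learned from the ambient language) and a motor
wordform (a *silhouette* — a time-indexed sequence of weighted convex
regions of motor space, built up from the speaker's own successful
productions).  The package is for researchers in speech motor learning and
phonological development who want a tested, scriptable implementation of
this model family to probe how practice and vocabulary size shape
production accuracy.

## The model in brief

A silhouette is a map `SIL(t) = (R_1..R_k, v_1..v_k)`, `t = 1..T`, where
each `R_i` is a simplex, the union of the `R_i` is convex, and `v_i > 0`
are weights.  Production integrates a silhouette and an exemplar over a
perceptual-motor map of juncture clusters:

- motor activation of a juncture at time t:
  `Σ_s v_s · max(0, H − D·dist(j, R_s)) / Σ_s v_s` (defaults `H = 1`,
  `D = 0.1`), averaged within clusters;
- perceptual activation: the same drop-off averaged over all exemplar
  points, constant in time;
- combined activation: the geometric mean `(m·e)^(1/2)` (an AND gate);
- output point: `ESTMOTOR(t) = Σ_i a_i(t)·MOTORCENTER_i / Σ_i a_i(t)`.

After a successful production the motor trace is absorbed: points inside a
frame increment the containing simplex weights (+1), points outside extend
the frame convexly with weight-1 simplices.  Novel words are produced from
an *A-silhouette*: the silhouettes of the `k` perceptually closest
expressive words, aligned, rescaled to a common per-frame maximum weight
`v'_{i,j} = v_{i,j} · max_i(MAXWEIGHT_i)/MAXWEIGHT_i`, and combined over a
triangulation of their convex hull with covering-sum weights.  The chance
that a random expressive vocabulary of size `m` contains at least `k` of
the `k + r` best matches in an `n`-word language is the hypergeometric
tail computed by `coverage_probability()`.

## Worked example

```r
library(dualex)

# A-silhouette weight scaling: three silhouettes with region weights
# (3,4), (5,8), (2,1) are rescaled to a shared maximum
scale_weights(list(c(3, 4), c(5, 8), c(2, 1)))$weights
#> [[1]] 6 8    [[2]] 5 8    [[3]] 8 4

# Coverage: a 500-word expressive vocabulary from a 2500-word language
coverage_probability(n = 2500, m = 500, k = 3, r = 4)
#> [1] 0.1477562        # "about 15%"

# Practice: a CVC word in the packaged 2D world, 200 iterations
w <- practice_world_2d(seed = 1)
h <- run_practice(w$sil, w$e, w$map, w$params, iterations = 200)
acc <- accuracy_series(h, w$e)
round(acc[c(1, 10, 50, 200)], 3)
#> [1] 4.075 3.211 3.065 2.974
```

The accuracy series (perceptual distance between output and exemplar)
falls fast over the first iterations and then plateaus — the rapid
early gain and long plateau typical of motor learning.  The
vocabulary-size experiment builds A-silhouettes for novel CVCV words from
growing expressive vocabularies sampled out of a 1296-word synthetic
language:

```r
cfg  <- cvcv_config()
lang <- build_language(build_map(cfg, seed = 1), cfg)
exp  <- run_vocab_experiment(lang, runs = 20, k = 3, seed = 1)
exp$summary
#>   vocab_size  mean   sd
#>            5 7.872 3.27
#>           10 7.131 2.83
#>           20 6.459 2.37
#>           40 6.047 2.30
#>           80 5.655 2.28
#>          160 5.497 2.29
#>          320 4.991 2.17
#>          640 4.867 2.33
#>         1200 4.781 2.07
```

Mean distance to the novel word's exemplar shrinks as the vocabulary
grows — steeply at first, gently later — because larger vocabularies
contain perceptually closer neighbours to lend their silhouettes.

A thin command-line wrapper lives in `exec/dualex`
(`practice`, `asil`, `asil-example`, `coverage`, `coverage-table`,
`make-language`, `vocab-exp`); see `?run_cli`.

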