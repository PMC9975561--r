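---
title: "A dual-lexicon model of whole-word speech production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-lexicon model of whole-word speech production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualex)
```

## The model

`dualex` simulates whole-word speech production under a dual lexicon.  A
concept is linked to two wordforms that live in different spaces:

* an **exemplar** — a perceptual wordform: a trajectory through perceptual
  space, acquired from the ambient language;
* a **silhouette** — a motor wordform: a function from discrete time
  `t = 1..T` to a *weighted region* of motor space, built up endogenously
  from the motor traces of the speaker's own successful productions.

Each silhouette frame is a weighted homogeneous simplicial complex: a set
of same-dimension simplices with positive weights, meeting face-to-face,
whose union is convex.  Weights record how often traces passed through each
subregion, so the silhouette encodes both *where* the word's articulation
may go (the convex region) and *where it usually goes* (the weights).

The two spaces are linked by a **perceptual-motor map**: junctures (paired
motor/perceptual points) grouped into clusters that act as units of speech
motor control.  A cluster's motor centre is the mean of its junctures'
motor points; the perceptual centre is defined symmetrically so output
trajectories can be read in both spaces.

### Production

Producing a word integrates the two forms through cluster activation:

1. **Motor activation** (time-varying).  At time `t` the silhouette frame
   activates junctures with the weighted linear drop-off
   `sum_s v_s * max(0, H - D * dist(juncture, R_s)) / sum_s v_s`, with
   peak `H = 1` and slope `D = 0.1` per model unit (activation reaches 10
   units).  Junctures in a cluster share the cluster's mean activation.
2. **Perceptual activation** (simultaneous).  The exemplar activates
   clusters all at once: the same linear drop-off averaged over all
   exemplar points and cluster junctures, constant over time.
3. **Combination.**  The per-cluster activations are combined by the
   geometric mean — an AND gate: a cluster silent in either space
   contributes nothing, so exemplar material irrelevant to the current
   time cannot override the silhouette's sequencing.
4. **Output.**  The output point at `t` (ESTMOTOR) is the
   activation-weighted average of cluster motor centres; its perceptual
   image uses the same activations with perceptual centres.  The output is
   therefore always a *compromise* among co-activated clusters — even a
   perfect silhouette does not reproduce its exemplar exactly, and the
   perceptual image is discontinuous when the two spaces have different
   topologies.

Accuracy is measured by `trajectory_distance()` (the perceptual distance
`d_PERC`): both trajectories are resampled to the longer length at uniform
parameter values (endpoints preserved), and index-paired Euclidean
distances are averaged.  Linear endpoint alignment is used; no non-linear
time warping.

### Learning by absorption

After a successful production the executed motor trace is absorbed
frame-by-frame:

* **Case 1** — the trace point lies in the frame: every simplex containing
  it (all of them, on a shared boundary) gains weight `+1`; the geometry is
  bit-identical.
* **Case 2** — the point lies outside: the old simplices and weights are
  kept, and weight-1 simplices fan from the point to the boundary facets
  visible from it, so the new union is exactly the convex hull of the old
  vertices plus the point.

A point outside the frame's affine span (absorbing into a degenerate
point- or segment-frame) raises the intrinsic dimension: the new frame is
the cone from the point over the old simplices, recorded as weight-1
simplices.  This is the one place where old weights are not preserved; it
only occurs for frames with essentially no history.  Old simplices are
never retriangulated in Case 2 — retriangulation would make the weights
ambiguous.

### A-silhouettes for novel words

A word the speaker has only heard has an exemplar but no silhouette.  The
`k` expressive words perceptually closest to the target (by `d_PERC`, ties
broken by concept id) lend their silhouettes, which are aligned in time
(nearest-frame lookup to the longest `T`), rescaled, and combined:

* **Scaling.**  At each time, every silhouette's weights are multiplied by
  `max_i(MAXWEIGHT_i) / MAXWEIGHT_i`, so all silhouettes share the same
  maximum while relative weights within each are preserved.  For input
  weights (3,4), (5,8), (2,1) this gives (6,8), (5,8), (8,4) with shared
  maximum 8.
* **Combination.**  The convex hull of all source regions is triangulated
  so that every output simplex lies inside a fixed set of source regions
  or outside all of them; its weight is the sum of the covering scaled
  weights, or 1 for hull gaps covered by no source.

The combination is implemented (for the 2D worlds all packaged experiments
use) by a vertical-slab decomposition: the hull is cut at every vertex and
every pairwise edge intersection, each slab is split into trapezoids
between consecutive non-crossing edges, and trapezoids are fan-triangulated
with all cut points on their vertical sides included, which removes
T-junctions and guarantees a face-to-face complex refining the overlay
arrangement.  Degenerate source sets collapse to 1D interval overlays or a
single weighted point.  Ambient dimensions above 2 are not supported by the
combiner (no constrained-triangulation library is available); all other
machinery (distances, absorption, activation) works in 3D as well.

## Vocabulary coverage

Whether an A-silhouette can be good depends on whether the expressive
vocabulary `V` (size `m`) contains enough of the whole language `L`'s
(size `n`) best perceptual matches.  `coverage_probability(n, m, k, r)`
evaluates the closed-form sum

$$\sum_{i=0}^{r} \frac{(k+r)!}{(k+i)!\,(r-i)!}\cdot
  \frac{(n-k-r)!}{(m-k-i)!\,(n-r-m+i)!}\cdot\frac{m!\,(n-m)!}{n!}$$

with log-gamma arithmetic.  The sum equals the hypergeometric tail
`P(X >= k)`, `X ~ Hypergeom(n, k+r, m)`; the tests verify this equality to
1e-12 on random parameter sets and against Monte-Carlo subset sampling —
`stats::phyper` is used only as a cross-check, never as the
implementation.  At `n = 2500`, `m = 500`, `k = 3`, `r = 4` the sum gives
`r round(coverage_probability(2500, 500, 3, 4), 4)` (about 15%); the
companion value for at least 1 of the 5 best recomputes to
`r round(coverage_probability(2500, 500, 1, 4), 3)`, conventionally
rounded to "about 70%".

## The synthetic worlds

No real speech data enter the package; both experiment worlds are
generated, and their defaults are fixed design choices, not tuning knobs.

### The CVCV language

`cvcv_config()` describes a 2D world with 6 consonantal clusters at
`y = 0` and 6 vocalic clusters at `y = 14`, spaced 8 units apart in x.
Relative to the activation reach of 10 units these distances make
activation *selective*: a region on a cluster activates it fully, its
within-row neighbours weakly (0.2), and the other row not at all —
the consonant/vowel separation the rows are meant to encode.  (With much
tighter spacing every cluster is partially active everywhere, outputs
collapse toward a global centroid, and neither silhouette quality nor
vocabulary size can matter.)  The perceptual space keeps the row structure
but shuffles cluster x-positions within each row by a seeded permutation,
giving the two spaces different topologies; junctures carry the same
offsets in both spaces.

The language is all `6 x 6 x 6 x 6 = 1296` CVCV centre-to-centre paths.
Silhouettes are 7 uniformly weighted squares (half-width 1): odd frames on
the four clusters, even frames at segment midpoints.  The exemplar is the
perceptual image of the 7-point centre path.

`run_vocab_experiment()` grows a nested expressive vocabulary (5, 10, 20,
40, ..., 640, then capped at 1200 — a doubling schedule over the stated
range), builds an A-silhouette for a random novel word from its `k = 3`
closest vocabulary words at each size, and records the perceptual distance
between the integrated output and the novel exemplar.  Because compromise
outputs have an intrinsic error floor (even a word's own silhouette does
not reproduce its exemplar), the meaningful result is the *trend*: mean
distance decreases with vocabulary size, steeply early and gently late.

### The practice world

`practice_world_2d()` is the world behind the practice experiments: two
rows of three clusters (spacing 8, rows 14 apart), identical motor and
perceptual layouts so that silhouette movement toward the exemplar is
directly visible, and a CVC exemplar `C2 -> V2 -> C3` that dwells on the
vowel (three of its seven points on the vowel cluster, as vowel nuclei
dominate syllable duration).  The starting silhouette is the same path of
squares (half-width 2.5) translated by one cluster spacing — an early
motor plan that runs through the *adjacent, wrong* clusters.  The seed
adds a small Gaussian jitter (sd 0.15) to juncture placement, so each seed
is its own realisation of the same world.

The dwell and the divergent start matter, and are worth stating honestly
because they delimit what a green test establishes.  Perceptual activation
is static, so consonant clusters remain partially active at vowel times;
only when the exemplar dwells on the vowel is the vowel cluster's
activation strong enough that practice pulls the vowel-time output upward
rather than letting the consonant row capture it.  And since absorption
reinforces wherever the output currently is, accuracy *improves* only when
the starting silhouette is worse than the attractor of the integration
dynamics — a divergent starting path, as in the published simulations.  A
silhouette that already sits on the right path drifts slightly *away*
(toward the compromise attractor) under continued practice.  The packaged
world therefore demonstrates the documented regime — rapid early gains
followed by a long plateau — not a claim that practice helps from every
starting point.

With noise off the loop is deterministic; `noise_sd` adds zero-mean
isotropic Gaussian noise to the executed motor points before absorption
(the optional silhouette deviation mechanism), and is reproducible under a
seed.

## Numerical choices

* Containment and degeneracy use an absolute tolerance of `1e-9` (world
  coordinates are O(10)); boundary points increment *all* touching
  simplices.
* Span membership is decided with a cancellation-free orthogonal residual;
  convexity validation checks that every boundary facet's supporting
  hyperplane keeps all vertices inside (tolerance `1e-7` relative).
* All-zero combined activation at a time step (possible under the AND
  gate) carries the previous output point forward, or at `t = 1` uses the
  frame's weight-weighted centroid, with a message; a word with no
  co-activated cluster at *any* step raises an integration failure naming
  the first dead step.
* Look-back/look-ahead windows are an optional centred moving average of
  the combined activation grid, default off — the packaged simulations
  specify no window.
* Weights are stored as doubles (A-silhouette scaling is fractional);
  pure practice updates keep them integral.  JSON serialisation writes
  coordinates and weights as 17-significant-digit decimal strings, which
  round-trips IEEE doubles exactly.
* Silhouette alignment uses nearest-frame lookup (half-way points round
  up); how silhouettes come to be aligned is unspecified in the underlying
  model, and resampling frames avoids interpolating geometry.
* Hull-gap pieces in `combine_frames()` get weight 1 *per simplex* (the
  rule is stated per region); per-connected-gap weighting would be the
  alternative reading.
* Performance: repeated integrations memoise geometry-only distance
  matrices (Case 1 changes no geometry; Case 2 only appends simplices, so
  cached rows remain valid), and Case-2 updates maintain boundary facets
  incrementally.  These are pure optimisations; tests compare them against
  full recomputation.

## Limitations

* Clusters and junctures are given inputs; their creation from babbling
  and early matching is outside the model.
* Exemplars never change: there is no perceptual learning and no listener
  feedback (communicative success is assumed; the hook exists).
* The spaces are abstract 2D/3D stand-ins for high-dimensional
  articulatory/acoustic spaces; nothing here touches real speech signals.
* `combine_frames()` is 2D; 3D A-silhouettes would need a constrained
  tetrahedralisation.
* The coverage analysis treats the vocabulary as a uniform random subset
  of the language — no frequency or phonotactic structure.
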