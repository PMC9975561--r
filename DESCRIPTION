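Package: dualex
Title: Dual-Lexicon Simulator of Whole-Word Speech Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-word speech production under a dual lexicon of
    motor wordforms ("silhouettes": time-indexed weighted simplicial complexes
    in motor space) and perceptual wordforms ("exemplars": trajectories in
    perceptual space), linked through a perceptual-motor map of juncture
    clusters.  Implements distance-based cluster activation, geometric-mean
    perceptual-motor integration with a weighted-centroid output trajectory,
    practice-driven silhouette learning (reweighting and convex extension),
    archi-silhouette construction for novel words from perceptually nearest
    neighbours, a closed-form hypergeometric vocabulary-coverage probability,
    and a synthetic CVCV-language experiment relating expressive vocabulary
    size to novel-word production accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
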