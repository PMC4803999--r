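Package: nichemorph
Title: Ecological Niche Divergence, Morphological Covariation and
    Phylogenetic Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline linking ecological-niche divergence to
    morphological divergence across a clade: presence/background
    maximum-entropy suitability models on gridded climate layers,
    niche-overlap statistics (Schoener's D, Warren's I, Hellinger distance)
    with background randomization tests classifying species pairs as
    divergent, conserved or non-significant, two-block partial least
    squares of climate versus morphology with the Rv coefficient and
    row-permutation significance, maximum-likelihood fitting of
    continuous-trait evolutionary models (white noise, Brownian motion,
    Pagel's lambda, Ornstein-Uhlenbeck, early burst, delta, kappa) with
    AICc selection, and Mantel correlation of niche and morphological
    distance matrices.  A synthetic-data module generates correlated
    environmental rasters, Gaussian-niche virtual species, pure-birth
    trees, simulated traits and planted climate/morphology couplings so
    every stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
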