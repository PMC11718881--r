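Package: herdnet
Title: Social Structure Analysis of Equid Groups from Scan-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the social structure of small groups of
    equids (and similar group-living mammals) observed by instantaneous
    scan sampling and all-occurrence interaction sampling. Builds
    association-index and interaction-rate networks with the gambit of
    the group, tests non-randomness by day-restricted data-stream
    permutations, detects subgroups by modularity optimisation, computes
    David's scores and Landau's linearity for dominance, a behavioural
    synchronization index with its randomization null, electivity and
    spread-of-participation indices for enclosure use, and pedigree
    kinship coefficients. Includes a synthetic scan-data generator with
    planted social structure for validation, and packaged worked-example
    matrices from a published bachelor group of nine Przewalski's horse
    stallions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
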