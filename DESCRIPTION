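Package: mhealthscape
Title: Tag-Based Clustering and Privacy-Risk Archetyping of Mobile Health App Stores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for landscape analyses of mobile health
    (mHealth) app stores. Tags app descriptions against a surface-string to
    tag-label corpus, filters weakly tagged apps, builds the undirected
    weighted graph whose vertices are apps and whose edge weights count shared
    tags, clusters it by Louvain modularity optimization (implemented in
    package code with an exhaustive small-graph oracle), quantifies
    inter-rater agreement of five information-security and privacy cluster
    characteristics with the Janson-Olsson iota coefficient, and consolidates
    identically assessed clusters into app archetypes. Includes a seeded
    synthetic app-store corpus generator with planted archetype structure and
    realistic rating metadata so the whole pipeline is testable without store
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    tibble,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
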