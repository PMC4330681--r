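Package: nichedist
Title: Trait, Phylogenetic and Ecological-Niche Distances for Species Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compares species' ecological niche positions (Ellenberg-type
    indicator values) with their functional trait values and phylogenetic
    relatedness using pairwise distance matrices.  Implements absolute
    (|tA - tB|) and hierarchical, signed (tA - tB) trait distances, Mantel
    permutation tests adapted to anti-symmetric matrices (including exact
    enumeration for small species sets), neighbor-joining tree estimation
    with bootstrap supports and patristic distances, phylogenetic-eigenvector
    (PVR-style) variance analysis of trait values, calculators for leaf and
    root functional traits from raw measurement records, and a synthetic-data
    generator (Yule trees, Brownian or white traits, planted trait-indicator
    couplings, invertible measurement records) so that every stage of the
    analysis can be verified by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
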