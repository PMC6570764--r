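Package: ecomotifs
Title: Grade-of-Membership Motif Analysis for Communities and Bioregions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mixed-membership ("Grade of Membership") decomposition of
    ecological matrices into motifs: a Bernoulli model for site-by-species
    presence-absence data (bioregionalization) and a multinomial model for
    community abundance counts, assemblage dispersion fields and
    phylogenetic clade counts. Models are fitted by EM with conjugate
    priors, restarts are ranked by an approximate log Bayes factor, and
    observed fits are compared against community null models (frequency,
    richness, independent swap, trial swap). Includes time-slice collapsing
    of ultrametric phylogenies to lineage-level counts, dispersion-field
    construction from gridded species ranges, Block Structure plot
    ordering, pie-map GeoJSON export, and synthetic-data generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
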