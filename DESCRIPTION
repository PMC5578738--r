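Package: plexscreen
Title: Multiplexed Bead-Array Interactome Screening and Equilibrium Affinity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular receptor-ligand interactome
    screens run on multiplexed bead arrays (Luminex xMAP / Bio-Plex class
    instruments). Assembles median-fluorescence-intensity plate reads into a
    bait-prey interaction matrix with replicate averaging and a minimum
    bead-count filter, scores every cell by bootstrap-of-the-median row and
    column Z-scores, combines the two assay orientations of each protein pair
    by the geometric mean of their averaged Z-scores, calls interactions at a
    strict threshold with an explicit curator-override mechanism, quantizes
    scores into low/mid/high categories at empirical percentile cutoffs, and
    merges called pairs with a prior interaction network into an annotated
    bipartite graph with new/confirmed/prior-only edge provenance. Includes
    equilibrium surface-plasmon-resonance analysis (Langmuir isotherm fitting
    of titration series to estimate dissociation constants with standard
    errors) and a synthetic-data generator that emulates the statistical
    structure of the assay (sparse planted interactions with signal monotone
    in affinity, per-protein expression factors, expression failures,
    log-normal background and multiplicative noise) so that every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    pheatmap,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    xml2
VignetteBuilder: knitr
Config/testthat/edition: 3
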