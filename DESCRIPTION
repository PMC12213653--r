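Package: geneterrain
Title: Temporal GeneTerrain Maps of Time-Course Gene Expression on Protein
    Interaction Network Layouts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Projects gene expression values onto a fixed two-dimensional
    layout of a protein-protein interaction network and renders them as
    continuous Gaussian density "terrains", one per time point. The layout
    is computed once by Kamada-Kawai energy minimization and frozen across
    all time points and conditions, so that pixelwise differences between
    terrains reflect expression changes only. Includes Z-score
    normalization, top-variance and Pearson co-expression gene filtering,
    interval delta terrains with up/down gene-set extraction (GMT export),
    linear temporal interpolation for smooth animations, an adaptive
    Gaussian smoothing variant, a divergent blue-green-red renderer, and a
    seeded synthetic network/time-course generator for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
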