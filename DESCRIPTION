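Package: iostates
Title: Input-Output Signal-Processing States from Single Cell-Scale qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of mesoscale single-neuron RT-qPCR profiles:
    limit-of-detection censored expression, quartile binning and Z scoring,
    hierarchical discovery of neuronal states and gene modules with
    parsimonious dendrogram cuts, condition-induced state-shift statistics,
    receptor-based input-output signal-processing maps with differential
    edge classification, q-value-thresholded gene co-expression networks
    with edge set algebra and hub ranking, minimum-spanning-tree phenotype
    landscapes with terminal/transitional branch calls, PCA group
    ellipsoids, NanoString-style microRNA detection with template matching
    and candidate prioritisation, and a truth-labelled synthetic data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
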