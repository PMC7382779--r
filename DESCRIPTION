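Package: kinodelta
Title: Downstream Analysis of Multiplexed Kinase/Phosphatase Deletion
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end downstream analysis for multiplexed (TMT)
    proteomic and phosphoproteomic profiling of single-gene deletion
    strain panels: isotopic impurity correction, peptide filtering and
    protein rollup, loading equalization, bridge-channel log2 ratios with
    trimmed-mean centering, protein normalization of phosphosites,
    trimmed-SD regulation-event calling with protein/phospho attribution,
    deletion-strain correlation networks, molecule covariance networks
    with permutation false-positive estimation, and hypergeometric
    gene-set enrichment. Includes a synthetic-data generator with planted
    ground truth that emulates the bridge-channel plex design, so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
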