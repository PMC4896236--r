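Package: ptmscope
Title: Physicochemical Interface Descriptors for Classifying
    Post-Translational Modification Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how phosphorylation patterns affect multimeric
    protein interfaces using nine physicochemical descriptors computed
    from conformational ensembles: total, hydrophobic and buried
    solvent-accessible surface area, inter-chain hydrogen bonds,
    inter-chain Lennard-Jones energy, inter-chain gap volume and gap
    index, and two free-energy-landscape stability markers (occupancy of
    the deepest basin and the number of basins) derived from essential
    dynamics. Descriptors are combined with binary modification
    indicators and classified by pairwise normalization, principal
    component analysis, k-means clustering and site-descriptor Pearson
    correlation. Includes synthetic generators (toy dimers, harmonic and
    multi-basin ensembles, planted feature studies) so every stage is
    testable without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
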