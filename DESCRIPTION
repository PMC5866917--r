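Package: mutdomino
Title: Detection and Characterization of Somatic Mutation Hotspots in Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies single protein residues that accumulate somatic
    missense mutations at a significantly higher rate than their surrounding
    sequence (mutation "hotspots"), using a dual sliding-window share
    criterion with an adjusted Poisson test. Maps genomic variants onto
    protein coordinates from transcript models, filters hotspot candidates
    against common population variants and precomputed deleteriousness
    predictions, classifies genes by tumor-suppressor-like mutation
    signatures, transfers structure-derived interaction-interface residues
    onto protein coordinates by local alignment and tests interfaces for
    mutation clustering with a binomial-logistic model, clusters tumor types
    by hotspot mutation frequencies with bootstrap support, and generates
    fully synthetic cohorts so every stage can be exercised without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    ape,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
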