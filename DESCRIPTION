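Package: rmscape
Title: Detection and Comparative Genomics of Restriction-Modification Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects complete restriction-modification (R-M) systems and
    solitary components in annotated prokaryotic genomes from gene-neighborhood
    co-localization rules, associates them with mobile genetic elements,
    competence machinery and CRISPR spacers, places them on positional-orthology
    core- and pan-genomes, measures integration-region sizes between consecutive
    core genes, and screens selection pressure with pairwise dN/dS estimators
    (Nei-Gojobori counting and the Yang-Nielsen approximate method). Includes a
    deterministic synthetic-genome simulator that plants every feature class
    with machine-readable ground truth, so the whole pipeline can be exercised
    end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
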