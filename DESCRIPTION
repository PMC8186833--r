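Package: coexminer
Title: Mutual-Rank Co-Expression Mining and Screening of Candidate Pathway Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transcriptome mining toolkit for discovering candidate regulators
    of specialized-metabolite pathways from bulk RNA-Seq expression atlases.
    Builds gene co-expression rankings and mutual-rank weighted k-nearest-neighbor
    (KNN) networks from TPM matrices, prioritizes candidate regulators by
    intersecting bait-gene neighborhoods with an annotated regulator set,
    assembles combinatorial overexpression screening groups, and evaluates
    qPCR screens with reference-gene normalized relative quantities, fold
    changes and a pass/fail advancement gate. Includes a synthetic expression
    atlas and qPCR data generator with planted co-expression modules and
    regulators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
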