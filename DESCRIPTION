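Package: carciprofiler
Title: Data-Driven Consensus QSAR Profiling of Chemical Carcinogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands a small, well-labeled probe set of human carcinogens and
    noncarcinogens into large bioassay-derived training sets, builds
    combinatorial consensus QSAR (quantitative structure-activity
    relationship) models per bioassay, and scores new compounds by a mixed
    experimental-and-predicted carcinogenicity probability with a
    confidence-based applicability domain. Includes structure curation
    (salt stripping, neutralization, deduplication), sparse ternary
    bioassay profiles, Fisher's exact assay selection with balanced-accuracy
    screening, MACCS/ECFP/FCFP binary fingerprints, a five-algorithm by
    three-fingerprint model grid with five-fold cross-validation and
    consensus averaging, virtual-screening reports, and a seedable
    synthetic-data generator with planted assay-endpoint associations for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
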