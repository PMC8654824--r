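Package: barcodeval
Title: Evaluation of DNA Barcode Loci for Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well one or more DNA barcode loci
    discriminate species in a reference library of aligned sequences.
    Implements Kimura 2-parameter and uncorrected p-distances with
    pairwise deletion, per-species barcoding-gap analysis (scatter and
    histogram views), leave-one-out Best Match and Best Close Match
    identification with the 95% intraspecific-distance threshold,
    neighbour-joining tree construction with per-species monophyly
    scoring, multi-locus concatenation, and a species-structured
    sequence simulator so the whole pipeline can be exercised on data
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
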