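Package: cosmis
Title: Contact Set Missense Tolerance Scores from Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the depletion of missense variation in the 3D
    spatial neighborhood (contact set) of every amino acid site of a
    protein, relative to a sequence-context-aware neutral expectation.
    Builds a trinucleotide mutability model, partitions per-codon
    mutability by coding consequence, predicts expected variant counts by
    regressing observed synonymous counts on synonymous mutability, and
    compares observed unique missense counts in each contact set against
    a multinomial permutation null to produce per-site Z scores (COSMIS)
    and empirical p values. Includes structure selection and confidence
    filters, oligomeric interface detection, odds-ratio enrichment across
    score percentile bins, and a synthetic toy-protein generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
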