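Package: nlsmine
Title: Nuclear Localization Signal Prediction by Sequential Pattern
    Mining and Linear Motif Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts nuclear localization signals (NLSs) in protein
    sequences. Enriched gapped sequential patterns (ordered lists of short
    amino-acid words) are mined from a positive NLS peptide corpus against
    a negative peptide corpus with an Apriori-style frequent word-set
    miner, query proteins are scanned for qualified pattern matches and
    for a bipartite-NLS consensus, candidate segments are scored by
    combining pattern enrichment with a disorder-based linear motif
    probability, and predictions can be masked by inverse relative local
    conservation (IRLC) computed from PSI-BLAST position-specific scoring
    matrices. Includes overlap-hit evaluation metrics (precision, recall,
    F1, amino-acid performance coefficient) and a seeded synthetic-data
    generator for self-contained benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
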