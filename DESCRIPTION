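Package: tapfams
Title: Rule-Based Classification and Comparative Evolution of
    Transcription-Associated Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies proteins into transcription-associated protein (TAP)
    families from profile-HMM domain searches: parses HMMER3 per-domain
    tables, applies per-profile gathering-threshold and model-coverage
    filters, and assigns each protein to at most one family by evaluating
    required ("should") and forbidden ("should not") domain rules, resolving
    competing families by independent domain E-value. Downstream, it builds
    families-by-species count matrices, runs normality-gated group
    comparisons and principal component analysis, and reconstructs ancestral
    family sizes on a rooted species tree by asymmetric Wagner parsimony,
    classifying per-branch gains, losses, expansions and contractions. A
    seed-alignment augmentation planner and a synthetic fixture generator
    with recorded ground truth round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
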