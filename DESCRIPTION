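Package: medlinkr
Title: Medication Named-Entity and Relation Extraction from Discharge Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts drug names and seven associated attributes (strength,
    dosage, frequency, duration, route, form, reason) from free-text
    discharge summaries and links each attribute to the drug it modifies.
    Provides a BiLSTM-CRF sequence labeller over BIOES tags with four
    token-representation stacks (random or pretrained word embeddings,
    character embeddings, semantic-feature embeddings), a deterministic
    sentence-segmentation rule linker and a context-aware LSTM relation
    classifier, majority-vote ensembling, lenient/strict micro and macro
    evaluation, BRAT-style standoff corpus input/output, and a synthetic
    prescription-corpus generator for training and benchmarking without
    access to restricted clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
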