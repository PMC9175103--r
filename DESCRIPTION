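Package: sirvanlp
Title: Rule-Based Clinical Text Mining for Shoulder Injury Related to
    Vaccine Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies potential cases of shoulder injury related to
    vaccine administration (SIRVA) from electronic health record data.
    Implements structured-data cohort selection over vaccination,
    encounter, diagnosis and membership tables; lexicon-driven indexing
    of free-text clinical notes (section detection, sentence
    segmentation, tokenization, concept matching, NegEx-style
    negation/uncertainty/hypothetical scoping); distance-constrained
    ordered and nested relation search within and across sentences;
    anatomic, temporal and causal finding extraction; and patient-level
    classification into definite, probable and possible SIRVA cases with
    a per-criterion audit trail. Ships a template-grammar synthetic EHR
    generator with token-level ground truth so the full pipeline is
    testable end to end, plus exact binomial evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
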