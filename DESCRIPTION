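Package: trialmatchr
Title: Explainable Rule-Based Matching of Oncology Patients to Phase 1 Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based natural language processing pipeline that screens
    unstructured oncology patient notes against phase 1 clinical trial
    protocols. Four eligibility criteria are extracted and compared: cancer
    type (with metastatic status, resolved against a Neoplasm-branch concept
    thesaurus), ECOG performance status (explicit scores or implicit
    functional-status phrases), measurable disease under RECIST 1.1 site and
    size rules, and genetic mutation mentions (with therapy-context
    filtering). Each patient-protocol pair receives a matching score (the
    fraction of protocol-required criteria the patient meets), a threshold
    decision, and a full evidence ledger so every verdict can be audited by a
    human reviewer. Includes a pluggable entity-tagger contract with a
    built-in lexicon tagger, abbreviation expansion, sentence-scope negation,
    an evaluation harness (confusion matrix, precision, sensitivity,
    specificity, accuracy), and a seeded synthetic corpus generator with
    controllable error-mode confounders for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
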