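Package: clinfacts
Title: Clinical NLP Concept Extraction, i2b2 Fact Encoding, and Federated Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for network-scale clinical natural language processing
    pipelines: ruleset-driven dictionary extraction of clinical concepts from
    free-text notes with ConText-style certainty, experiencer, and temporality
    attributes; bit-exact encoding of mentions into the i2b2 observation_fact
    entity-attribute-value model with the "NLP|" prefix conventions; generation
    of i2b2 metadata (ontology) tables for note types and project-specific
    clinical concepts; a gold/silver-standard evaluation harness with ICD
    wildcard cohort selection, precision/recall/F1 reporting across sites, and
    a four-class error taxonomy; and a synthetic clinical-note generator with
    planted ground-truth annotations for PHI-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
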