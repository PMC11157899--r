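Package: modmtl
Title: Multi-Task Classification of Clinical Entity Modifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint prediction of clinical entity modifiers (negation,
    uncertainty, severity, course, subject, conditionality, generic status,
    document-time relation, illicit-use status) with one classification head
    per modifier over a shared sequence-pair encoder. Includes BRAT standoff
    and JSON-lines corpus I/O, character-window feature extraction around
    gold entity mentions, averaged cross-entropy and focal losses, AdamW
    fine-tuning with early stopping, transfer learning across schemas whose
    modifier sets only partially overlap, prevalence-weighted accuracy and
    F1 evaluation, and a seeded synthetic clinical-note generator so the
    whole system trains and evaluates at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
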