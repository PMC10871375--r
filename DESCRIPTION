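Package: CohortCube
Title: Federated Aggregate Count Matrices from Bulk FHIR Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale federated learning over electronic health records.
    Reads bulk-FHIR NDJSON exports, de-identifies resources with a keyed
    codebook, extracts symptom mentions from clinical note text with
    dictionary matching and rule-based negation detection, evaluates
    computable phenotypes (case definition, study variables, study period),
    computes the power-set aggregate count matrix with small-cell
    suppression, merges site matrices into a network matrix, and derives
    epidemiological measures (prevalence, odds ratio, relative risk,
    conditional probability, chi-square, monthly trend series) from
    aggregate counts alone. A seeded synthetic multi-site bulk-FHIR
    generator with known ground truth replaces the EHR so that every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    data.table,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
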