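Package: phenoval
Title: Validation of Diagnostic-Code Phenotyping Algorithms in Electronic
    Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to validate diagnostic-code phenotyping algorithms
    against chart review in hospital electronic medical records: strict
    readers for patient/diagnosis/procedure tables, registry cleaning with
    an exclusion audit, ICD-10 code-set matching (exact codes, category
    prefixes and category ranges), same-day deduplication of code
    registrations, diagnosis-imaging temporal linkage arms, seeded
    chart-review sampling, positive predictive values with exact binomial
    confidence intervals, and a synthetic EMR generator with latent
    ground-truth labels for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
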