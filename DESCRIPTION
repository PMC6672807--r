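Package: ecrfpop
Title: Terminology-Driven Clinical Information Extraction and eCRF Prepopulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic clinical natural language processing pipeline that
    recognises coded medical concepts (SNOMED-CT / RadLex style) in narrative
    admission records and imaging reports, classifies assertions (present or
    absent), extracts i2b2-style relations, associates numeric values with
    observables, and uses the result to prepopulate electronic case report
    forms (eCRFs) with full text provenance. Ships the accompanying evaluation
    framework (double-entry adjudication, accuracy and elapsed-time statistics
    on the log scale with geometric-mean ratios, commission-error analysis)
    and a seeded synthetic clinical-case generator plus participant-behaviour
    simulator so the whole workflow is testable without access to real
    electronic medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
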