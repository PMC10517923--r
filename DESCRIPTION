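Package: microfhir
Title: Microbiology Laboratory Results as FHIR R4 with Terminology-Driven
    Validation and MRGN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Typed representation of clinical microbiology results (culture
    detection, colony counts, antimicrobial susceptibility, microscopy,
    molecular detection, serology/immunology, multidrug-resistance
    characterization), lossless serialization to FHIR R4 JSON Observation and
    DiagnosticReport resources, a snapshot-based terminology engine for
    extensional and intensional (ECL-subset and LOINC-part) value sets, a
    profile validator with a stable rule catalog, the KRINKO MRGN classifier
    for multidrug-resistant Gram-negative organisms, and a seeded synthetic
    laboratory-information-system data generator so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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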