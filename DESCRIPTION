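Package: alzmood
Title: Ontology-Based Mood-State Inference for Alzheimer's Patients from
    Pose Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and serializes an OWL ontology of Alzheimer's patient
    observation (patients, scenes, activity patterns, mood states),
    ingests tabular pose-observation streams as ontology individuals,
    classifies ordered pose pairs and pose windows into mood labels
    (wandering, nervous, depressed, disoriented, bored, none) using a
    pair-code table and restricted Damerau-Levenshtein template matching,
    infers patient-level mood states by forward-chaining run-length rules,
    simulates cohorts and pose streams with known ground truth, and
    summarizes cohorts with mood percentages and principal component
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
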