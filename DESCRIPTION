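Package: codonscreen
Title: Codon-Specific Genomic Biomarker Survival Screening for Chemotherapy Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Driver-event classification from somatic mutation and copy-number
    calls, hierarchical candidate-biomarker enumeration with redundancy
    collapse, and an exact permutation log-rank discovery screen with
    Benjamini-Hochberg false-discovery-rate control, for time-to-event
    biomarker discovery in treated cancer cohorts. Also provides the
    codon-specific validation toolkit (Kaplan-Meier estimates, stratified and
    adjusted Cox proportional-hazards models, treatment-by-biomarker
    interaction tests, Grambsch-Therneau proportional-hazards diagnostics,
    baseline-table hypothesis tests) and a synthetic-cohort generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    ggplot2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
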