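Package: facialEMG
Title: Time-Domain Feature Analysis of Bilateral Facial Surface EMG for
    Palsy Severity Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing bilateral facial surface electromyography
    (sEMG) acquired under a fixed MOVE/REST trial protocol, aimed at grading
    facial palsy severity on the House-Brackmann (HB) scale and at selecting
    features for EMG biofeedback. The package conditions six-channel bipolar
    recordings with zero-phase Butterworth band-pass and mains band-stop
    filters, segments them by the protocol clock, extracts twenty time-domain
    features per interval and facial side, computes a bilateral asymmetry
    index, and ranks features by Fisher score, Spearman correlation against
    ordinal HB groups, and paired MOVE-versus-REST contrasts. A synthetic
    cohort generator produces severity-graded bilateral EMG so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'io.R'
    'preprocessing.R'
    'features.R'
    'asymmetry.R'
    'grading.R'
    'pipeline.R'
    'cohort-reference.R'
    'utils.R'
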