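Package: romnav
Title: Routine Outcome Monitoring with Nearest-Neighbour Expected
    Recovery Curves and Dynamic Failure Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for session-by-session routine outcome monitoring in
    psychotherapy. Scores the HSCL-11 symptom checklist and the ASC, ASQ
    and OQ-30 battery instruments with reversal, missing-data and cut-off
    rules; predicts each patient's expected recovery curve from nearest
    neighbours in an archival reference pool and derives a dynamic failure
    boundary (upper limit of the 90 percent interval) over sessions 6-30;
    classifies patients as on-track or not-on-track with a reliable-change
    return rule; drives domain-level clinical-support-tool alerts; and
    compares the two groups with multilevel logistic model building,
    Pearson chi-square tests and pooled t-tests. A synthetic-cohort
    generator with a three-level (sessions in patients in therapists)
    log-time trajectory model makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
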