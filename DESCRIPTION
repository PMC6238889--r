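Package: glywalk
Title: Diurnal Glucose Curve Simulation and Walking Behavior-Change Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the acute effect of walking on the diurnal
    blood-glucose curve of adults with type 2 diabetes, and for analysing the
    within-subjects study design built around that simulation. Provides
    HbA1c-personalised 24-hour counterfactual glucose curves on a 15-minute
    grid, a walking-effect simulator with configurable start time and duration,
    area-under-the-curve (AUC) measurement of drawn glucose trajectories as a
    quantitative outcome-expectancy measure, a calibrated synthetic cohort
    generator, and the paired statistical pipeline (paired t tests,
    difference-of-differences, missing-data sensitivity analysis, and
    outlier-subset analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
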