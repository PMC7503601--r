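Package: wearadhere
Title: Wearable-Based Physical Activity Adherence Scoring and Baseline Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning minute-level wrist-worn activity and heart-rate
    streams into walking and exercise adherence scores for older adults
    following a prescribed physical-activity program. Implements closed-form
    exercise physiology (age-predicted maximal heart rate for sedentary
    adults, Karvonen heart-rate-reserve target zones, six-minute-walk-test
    based VO2max estimation), walking-bout counting rules with a minimum-bout
    exclusion, program- and volume-adherence definitions scored per calendar
    week, a synthetic cohort and stream generator with known ground truth, a
    shadow-feature random-forest selection and k-means (k = 2) profiling
    chain for baseline predictors of adherence, and the accompanying
    normality-gated statistical toolkit (paired tests, repeated-measures and
    mixed ANOVA with sphericity corrections, Friedman test, Pearson
    correlation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
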