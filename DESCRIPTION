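Package: wearlab
Title: Digital Phenotyping of Daily Depressive Symptoms from Wearable
    Living-Lab Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving daily sleep, heart-rate-variability and
    physical-activity biomarkers from minute-level wearable sensor streams
    in older adults, generating individualized traffic-light health
    feedback with emergency alerting, and testing whether within-person
    deviations in the biomarkers predict same-day and next-day depressive
    symptom reports via random-intercept multilevel logistic models.
    Includes a synthetic cohort generator that emulates a six-week
    living-lab study (circadian heart rate, fragmented nightly sleep,
    daytime activity bouts, chatbot symptom surveys, day-level
    missingness) so the full pipeline is testable without participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
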