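Package: cardioscore
Title: Modified HFA-ICOS Cardiovascular Risk Stratification for Cancer
    Patients, with a Competing-Risks Validation Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a harmonized, treatment-agnostic variant of the
    HFA-ICOS (Heart Failure Association / International Cardio-Oncology
    Society) baseline cardiovascular-toxicity risk proforma and the full
    statistical machinery needed to validate it against long-term
    cardiovascular outcomes: composite first-event construction under
    competing non-cardiovascular death, Kaplan-Meier and Nelson-Aalen
    estimators, Aalen-Johansen cumulative incidence functions, Harrell's
    concordance index, Cox and Fine-Gray regression fitted from scratch by
    Newton-Raphson, chained-equation multiple imputation, and a calibrated
    synthetic cohort generator so the entire pipeline is exercisable
    without access to registry-linked patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    yaml
Config/testthat/edition: 3
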