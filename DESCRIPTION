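Package: bioagemh
Title: Blood-Chemistry Biological Aging and Incident Depression/Anxiety Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Klemera-Doubal biological age (KDM-BA) estimator
    and the PhenoAge blood-chemistry clock, derives chronological-age-
    residualized age accelerations, scores PHQ-4/PHQ-9/GAD-7 questionnaires,
    ICD-9/10 hospital-record case definitions and childhood-adversity items,
    and fits the cross-sectional, time-to-event, dose-response, sensitivity
    and joint polygenic-risk association models used to study biological
    aging as a risk factor for prevalent and incident depression and anxiety.
    A synthetic cohort generator with known injected effect sizes makes every
    stage testable by parameter recovery without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
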