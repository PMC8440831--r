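Package: spinemc
Title: Reliability and Uncertainty Analysis of Subject-Specific Spino-Pelvic
    Kinematic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-driven kinematic analysis of subject-specific
    spino-pelvic rigid-body models (18 bodies, 17 spherical intervertebral
    joints, 28 virtual markers) and for quantifying how reliable the
    resulting spine kinematics are. Implements inverse kinematics of seated
    trunk-flexion trials, extraction of sagittal spino-pelvic parameters
    (lumbar lordosis, thoracic kyphosis, sagittal vertical axis, pelvic
    tilt, T1/T9 spino-pelvic inclination) and their ranges of motion,
    test-retest and inter-operator reliability statistics (ICC(2,1) with
    confidence interval, standard error of measurement, smallest detectable
    difference), and a Monte-Carlo probabilistic simulation that propagates
    operator-dependent model perturbations, sampled from kernel-density
    estimates of pooled operator deviations, into intervertebral joint-angle
    confidence bands and sensitivity factors. A synthetic-data module
    generates plausible adult-spinal-deformity geometry, flexion motions,
    operator variants and test-retest sessions so the whole pipeline is
    testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
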