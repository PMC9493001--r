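Package: stnbeta
Title: Subthalamic Beta-Band LFP Biomarkers of STN-DBS Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links resting-state local field potentials (LFPs) recorded from
    the four contacts of a subthalamic deep-brain-stimulation (DBS) lead to
    stimulation-induced motor improvement in Parkinson's disease. Provides a
    seeded synthetic-cohort generator (1/f background, narrowband low- and
    high-beta oscillations with depth-dependent amplitude, mains line, and
    outcomes drawn from a published two-predictor linear model), signal
    preprocessing (common-average reference, robust artifact screening,
    LOWESS detrending), Welch spectral estimation with relative band-power
    normalization, UPDRS-III hemibody subscores and stimulation-efficacy
    outcomes, DBS lead contact geometry, and the rank-based and
    ordinary-least-squares association statistics used to relate maximum
    high-beta power and contact distance to bradykinesia-rigidity improvement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
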