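Package: retromsm
Title: Progressive Multistate Markov Models for Retrospective Tobacco and
    ENDS Transition Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs a two-timepoint retrospective cohort of adolescent
    cigarette and electronic nicotine delivery system (ENDS) ever-use states
    from single-wave survey recall (grade at first use), fits a progressive
    four-state continuous-time Markov model to the resulting panel
    transitions by maximum likelihood, and reports transition-intensity
    ratios, matrix-exponential transition probabilities and current-use
    prevalence by transition group, with delta-method and simulation-based
    confidence intervals. Includes a synthetic survey-data generator with
    known ground-truth intensities for validation, and exact-count fixtures
    for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, MASS
Suggests: testthat (>= 3.0.0), Matrix, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
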