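Package: cuecat
Title: Audio-Visual Cue Integration in Categorical Phoneme Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-alternative forced-choice
    audio-visual phoneme labeling experiments under a Bayesian
    cue-integration framework. Builds cue-conflict experimental designs
    on 10-step /ba/-/da/ continua with graded visual blur, simulates
    parameterized 2AFC observers with stimulus-independent lapses, fits
    lapse-corrected cumulative-Gaussian psychometric functions by maximum
    likelihood (unimodal curves and a constrained bimodal
    linear-combination surface yielding cue weights), predicts normative
    weights from sensory variance, infers single-cue variance during cue
    combination from the bimodal variance identity, flags inconsistent
    observers, and fits a Gaussian-category linear-discriminant model
    with environmental (production) variance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
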