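Package: sondar
Title: Continuous Visual Stimulus Tracking Analysis for Oculomotor Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of eye movements recorded during continuous visual
    stimulus tracking (SONDA-style smooth and saccadic pursuit), aimed at
    quantifying oculomotor deficits such as those seen in spinocerebellar
    ataxia type 3. Provides stimulus trajectory generation, a synthetic
    binocular gaze simulator with a configurable oculomotor profile, gaze
    pre-processing (down-sampling, artifact masking, discard rules), a
    time-shifted cosine-similarity tracking-performance statistic, binocular
    synchronization measures, saccade detection and main-sequence analysis,
    and covariate-adjusted group statistics with FDR control and a bootstrap
    mixed-effects main-sequence model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
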