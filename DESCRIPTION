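Package: tmsgonogo
Title: TMS-EEG Analysis of Motor Inhibition During Go/NoGo Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of concurrent transcranial magnetic
    stimulation (TMS) and electroencephalography (EEG) recorded during a
    visual Go/NoGo motor inhibition task. Provides a synthetic session
    generator with known ground truth (TMS-evoked potentials, task
    event-related potentials, band-specific phase coupling between motor
    regions, and linked behavioural outcomes), a preprocessing chain
    (pulse-artifact excision with cubic interpolation, zero-phase
    band-pass and notch filtering, downsampling, demeaning, trial
    rejection, independent component cleaning), complex Morlet
    time-frequency decomposition and phase-locking value connectivity
    between source-space regions of interest, a toy distributed forward
    model with a minimum-norm inverse, TMS-evoked potential isolation by
    task-response subtraction with peak extraction, and the inferential
    machinery used in this literature: cluster-based sensor permutation
    tests, consecutive-timepoint permutation tests, repeated-measures
    ANOVA with Greenhouse-Geisser correction and Sidak post-hocs,
    normality-gated paired tests and correlations, and stepwise forward
    regression linking connectivity to evoked-potential amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'evoked.R'
    'ica.R'
    'inverse.R'
    'montage.R'
    'pipeline.R'
    'preprocess.R'
    'spectral.R'
    'stats.R'
    'synthgen.R'
    'tmsgonogo-package.R'
    'utils.R'
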