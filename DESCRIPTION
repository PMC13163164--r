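Package: clasphase
Title: Phase-Dependent Analysis of Auditory Stimulation During NREM Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the timing of auditory tones delivered
    during non-rapid eye movement (NREM) sleep shapes the evoked cortical
    response, using both brain and heart rhythms as timing references.
    Implements slow-oscillation and sleep-spindle detection on EEG,
    R-peak detection and low/high-frequency decomposition of instantaneous
    heart rate on ECG, Hilbert instantaneous phase with a quadrature
    correction, continuous circular phase binning with Gaussian Monte Carlo
    surrogate baselines, a Pairwise Response Index, spindle-likelihood
    resampling nulls, and multidimensional upstate/downstate phase-locking
    comparisons of event-related potentials and slow-wave activity. A
    synthetic polysomnography cohort generator with known phase-dependent
    tone-evoked responses provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
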