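Package: seqfinger
Title: Decoding Sequential Finger Movements from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for EEG recorded during sequential finger
    keystroke tasks (left/right index-finger pairs: LL, RR, LR, RL).
    Provides a paradigm-faithful synthetic EEG generator (movement-related
    cortical potentials with contralateral dominance, alpha/beta
    event-related desynchronization, 1/f background, 50 Hz line noise,
    ocular artifacts), preprocessing (zero-phase Butterworth filtering,
    notch, resampling, common average reference, behavioural trial
    rejection, ICA-based ocular artifact removal), MRCP waveform and
    STFT-based ERSP characterisation, a spatial-filter feature bank
    combining discriminative canonical pattern matching (DCPM),
    task-related component analysis (TRCA) and filter-bank common spatial
    patterns (FBCSP), and mutual-information feature selection with linear
    SVM classification, including cross-validated offline decoding and a
    simulated online session.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
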