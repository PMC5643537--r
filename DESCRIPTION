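Package: microsyn
Title: EEG Microstates and Muscle Synergies During Reaching and Grasping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the temporal dynamics of EEG
    microstates to muscle-synergy activation during reaching-and-grasping
    movements. Provides polarity-invariant topographic k-means clustering
    with cross-validation model-order selection, back-fitting and temporal
    smoothing of microstate sequences, L2-norm non-negative matrix
    factorization of EMG envelopes with variance-accounted-for order
    selection, window-wise occurrence histograms with permutation tests,
    time-frequency beta-band event detection, per-subject canonical
    correlation between microstate and synergy occurrences, and a
    permutation-calibrated four-class linear discriminant grasp decoder.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline can be exercised end to end, plus EDF/BDF and delimited
    I/O utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
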