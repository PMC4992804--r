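Package: p300tsc
Title: Time-Shift Correlation P300 Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training and evaluation of a P300 event-related
    potential brain-computer interface built on time-shift Pearson
    correlation features and a small feedforward neural network.
    Includes a labeled synthetic EEG session generator for the four-choice
    oddball paradigm, stimulus-locked epoch extraction on a 250 Hz grid,
    per-subject P300 template construction, the 31-point time-shift
    correlation feature vector, a 31-15-1 backpropagation classifier,
    fast-recognition (epoch accumulation) and accuracy-recognition
    (voting) decision modes, and session-level metrics such as the
    Wolpaw information transfer rate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
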