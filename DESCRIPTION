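Package: afusion
Title: Atrial Fibrillation Detection from Short Single-Lead ECG by Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects atrial fibrillation in short, noisy single-lead ECG
    recordings. Recordings are unified to 30-second segments, 24 formula-defined
    artificial features (waveform, interval, spectral-moment and permutation
    ratio entropy) are combined with 38 abstract features from a 13-layer 1-D
    convolutional neural network, and the fused 62-dimensional vectors are
    classified into normal, AF, other-rhythm and noisy classes with a random
    forest. Includes a synthetic ECG generator with fiducial ground truth,
    Pan-Tompkins QRS detection, wavelet P-wave delineation, and the
    CinC-2017-style F1 scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
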