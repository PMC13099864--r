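Package: batnav
Title: Biomimetic Sonar Target Search with a Spectrogram Correlation and
    Transformation Receiver
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates an echolocating bat searching a 2D arena for a
    two-glint target with a specific glint-delay spacing. Implements a
    spectrogram correlation and transformation (SCAT) receiver front end
    (Gaussian bandpass filterbank, multi-threshold detection events with
    amplitude-latency trading, dechirping, pooled delay estimation,
    spectral-null extraction and inversion to glint delay), binaural
    azimuth estimation, a beam-aim/flight-heading pursuit controller, and
    an epoch-by-epoch agent-based search loop with scene presets, random
    scene generation, per-epoch logging and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
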