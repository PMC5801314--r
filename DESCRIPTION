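Package: mmndecay
Title: Auditory Memory-Trace Decay Scores from Mismatch Negativity Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the decay of the pre-attentive auditory memory
    trace with the mismatch negativity (MMN). Generates the multi-deviant
    Optimum-1 (short inter-stimulus interval) and Memory-Trace (3 s
    inter-stimulus interval) auditory paradigms, including harmonic tone
    synthesis and audio/event-table export; simulates cohorts of older adults
    at risk of dementia with latent MMN amplitude and retention parameters,
    trial-level multichannel epochs, and a coupled neuropsychological battery;
    processes epochs into fronto-central difference waves (band-pass filtering,
    baseline correction, peak-to-peak artifact rejection, averaging,
    resampling); extracts MMN amplitude and latency with a two-stage
    group-peak/windowed-mean procedure and forms the short-minus-long ISI
    difference score (delta MMN); builds PCA-based episodic-memory and
    attention/executive composite scores; and links delta MMN to cognition via
    hierarchical regression with delta R-squared, nested F tests, standardized
    coefficients and collinearity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
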