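Package: recruitpipe
Title: Auditory-Nerve Response Recruitment Analysis from Round-Window
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying response recruitment in
    auditory-nerve measurements.  Provides overlapped-waveform (ANOW)
    second-harmonic extraction with cochlear-microphonic cancellation and
    weighted least-squares sinusoid estimation, compound action potential
    (CAP) averaging and automated N1/P1 peak picking, double-evoked and
    distortion-product otoacoustic emission component extraction with
    standard-error noise floors, linear-phase FIR band-limiting with
    group-delay correction, quartile-fence artifact detection, weighted
    smoothing-spline fits to response-growth functions with a median-slope
    recruitment metric, and the downstream slope-versus-threshold
    regression statistics.  A seeded synthetic round-window
    electrophysiology generator emulates the cochlear microphonic,
    phase-locked neural components, background noise, transient artifacts,
    and cohort-level compressive versus linearized growth, so the full
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
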