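Package: epwave
Title: Marking and Morphometry of Evoked-Potential Waveforms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for auditory evoked-potential tracings:
    manual and automatic marking of peaks, troughs and zero-crossings;
    latency, amplitude, interpeak, area (definite integral of the absolute
    signal and the classical two-triangle approximation) and slope
    measures; single-sided FFT amplitude spectra with spectral peak
    marking; delimited-text input/output for waveform tables and marker
    sidecars across locale dialects; and a descriptive agreement harness
    (mean absolute deviation, mean absolute percentage error, Pearson
    correlation, intraclass correlation) with a deterministic end-to-end
    desk validation against analytic sinusoid fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
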