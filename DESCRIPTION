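Package: pulsewave
Title: Scripted Arterial Pressure Waveforms for Hemodynamic Monitor Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes a continuous arterial blood-pressure waveform from a
    once-per-second stream of scripted vital signs (heart rate, systolic and
    diastolic pressure), by resampling a normalized single-beat pulse template
    to the commanded heart rate and rescaling its amplitude to the commanded
    pressures. The waveform is mapped to the analog convention of a
    pulse-contour monitor input (0-500 mmHg over 0-5 V, 12-bit DAC codes) and
    can be streamed through a bounded ring-buffer pipeline that emulates a
    patient-simulator-to-monitor interface. A generic pulse-contour analyzer
    (beat detection, per-beat SBP/DBP/PP/MAP, windowed HR and pulse pressure
    variation) closes the loop so commanded vitals can be verified against
    what a monitor would recover, entirely in software.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
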