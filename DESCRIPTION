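Package: pamscape
Title: Passive Acoustic Soundscape Metrics and Beaked Whale Click Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for long-term passive acoustic monitoring of underwater
    soundscapes: synthesis of calibrated synthetic acoustic scenes with
    ground truth (Cuvier's beaked whale FM echolocation pulses, delphinid
    clicks, ultrasonic antifouling pulse combs, echosounder pings,
    low-frequency vessel noise), Teager-Kaiser energy click detection with
    rule-based FM-pulse classification over 75-s segments, long-term
    spectral averages with rule-based logging of anthropogenic sound
    sources, soundscape metrics (Welch power spectral density, per-minute
    medians, one-third-octave band levels, narrowband proxy bands), and
    nonparametric comparison of hourly beaked whale acoustic presence
    across noise conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
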