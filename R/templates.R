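#' Source templates for synthetic acoustic scenes
#'
#' Parametric descriptions of the sound sources that make up a synthetic
#' monitoring scene. Each constructor returns a `source_template` whose
#' defaults emulate the corresponding real-world source as recorded at the
#' receiver; `level` is always a received level (dB re 1 uPa), never a
#' source level, because a bottom-mounted recorder only ever measures the
#' former and no propagation model is applied.
#'
#' * `template_cuvier()` — Cuvier's beaked whale echolocation click: a
#'   polycyclic upswept FM pulse, peak frequency ~40 kHz, duration above
#'   355 us, with the species' characteristic secondary spectral peaks
#'   near 17 and 23 kHz, emitted in trains with a uniform inter-pulse
#'   interval of 0.4-0.5 s.
#' * `template_delphinid()` — a short, weakly modulated delphinid-like
#'   click used as a confuser; its default features (low peak and center
#'   frequency, duration under 355 us, negligible sweep) place it inside
#'   the FM-pulse deletion region of the click classifier.
#' * `template_echosounder()` — narrowband navigational echosounder ping;
#'   the 28-kHz class peaks at 28.8 kHz with energy confined to roughly
#'   27-31 kHz, the 50-kHz class keeps its energy within 49-51 kHz.
#' * `template_ua_comb()` — ultrasonic antifouling pulse suite: a comb of
#'   tonal components whose lowest member sits near 19 kHz; the "anchored"
#'   preset extends to ~42 kHz, "transiting" to ~88 kHz, "close_range" to
#'   ~166 kHz (usable only at sampling rates above 332 kHz).
#' * `template_vessel()` — broadband vessel engine noise with energy
#'   concentrated below 300 Hz.
#'
#' @param level received level in dB re 1 uPa. For pulses this is the RMS
#'   level over the pulse; for the comb it is the per-component RMS level
#'   while the device transmits; for vessel noise the band RMS level.
#' @param duration nominal pulse duration in seconds, defined as the
#'   -10 dB envelope width (the convention in which click durations are
#'   reported); the rendered waveform support is somewhat longer.
#' @param peak_freq spectral peak frequency, Hz.
#' @param sweep_rate FM sweep rate in Hz/s (3e7 = 30 kHz/ms).
#' @param secondary_peaks,secondary_rel_db frequencies (Hz) and relative
#'   amplitudes (dB re main pulse) of the low-frequency spectral peaks.
#' @param ipi inter-pulse interval range in seconds, `c(min, max)`; pulse
#'   times in a train are drawn uniformly from this range.
#' @return object of class `source_template`.
#' @export
template_cuvier <- function(level = 120, duration = 450e-6,
                            peak_freq = 40000, sweep_rate = 3e7,
                            secondary_peaks = c(17000, 23000),
                            secondary_rel_db = c(-14, -11),
                            ipi = c(0.4, 0.5)) {
  stopifnot(length(secondary_peaks) == length(secondary_rel_db))
  .template("cuvier_fm", level = level, duration = duration,
            peak_freq = peak_freq, sweep_rate = sweep_rate,
            secondary_peaks = secondary_peaks,
            secondary_rel_db = secondary_rel_db, ipi = ipi)
}

#' @rdname template_cuvier
#' @export
template_delphinid <- function(level = 115, duration = 120e-6,
                               peak_freq = 22000, sweep_rate = 0,
                               ipi = c(0.05, 0.2)) {
  .template("delphinid", level = level, duration = duration,
            peak_freq = peak_freq, sweep_rate = sweep_rate,
            secondary_peaks = numeric(0), secondary_rel_db = numeric(0),
            ipi = ipi)
}

#' @rdname template_cuvier
#' @param class echosounder class: `"28"` (peak 28.8 kHz, band 27-31 kHz)
#'   or `"50"` (peak 50 kHz, band 49-51 kHz).
#' @param ping_interval seconds between pings in a ping train.
#' @export
template_echosounder <- function(class = c("28", "50"), level = 115,
                                 ping_interval = 1) {
  class <- match.arg(class)
  if (class == "28") {
    .template("echosounder_28", level = level, peak_freq = 28800,
              band = c(27000, 31000), sigma_f = 600,
              ipi = c(ping_interval, ping_interval))
  } else {
    .template("echosounder_50", level = level, peak_freq = 50000,
              band = c(49000, 51000), sigma_f = 300,
              ipi = c(ping_interval, ping_interval))
  }
}

#' @rdname template_cuvier
#' @param preset upper extent of the comb: `"anchored"` (~42 kHz),
#'   `"transiting"` (~88 kHz) or `"close_range"` (~166 kHz).
#' @param freqs explicit comb component frequencies (Hz); overrides
#'   `preset`.
#' @param pulse_duration,pulse_interval on-time and repetition period of
#'   each multi-frequency pulse, seconds. Setting
#'   `pulse_duration >= pulse_interval` makes the comb continuous. The
#'   repetition schedule is a free parameter of the emulation (duty cycle
#'   of real units is not documented); the default is a 50-ms pulse every
#'   200 ms.
#' @export
template_ua_comb <- function(preset = c("anchored", "transiting", "close_range"),
                             freqs = NULL, level = 100,
                             pulse_duration = 0.05, pulse_interval = 0.2) {
  preset <- match.arg(preset)
  if (is.null(freqs)) {
    base <- c(19400, 21900, 24300, 26500, 28700, 31200, 34000, 37500, 41500)
    freqs <- switch(preset,
      anchored    = base,
      transiting  = c(base, 47000, 54000, 62000, 71000, 80000, 87500),
      close_range = c(base, 47000, 54000, 62000, 71000, 80000, 87500,
                      100000, 120000, 142000, 165500))
  }
  if (length(freqs) == 0L) stop("comb must contain at least one component")
  if (min(freqs) < 1000) stop("lowest comb component must be >= 1 kHz")
  .template("ua_comb", level = level, freqs = sort(freqs),
            pulse_duration = pulse_duration, pulse_interval = pulse_interval)
}

#' @rdname template_cuvier
#' @param band frequency band (Hz) holding the bulk of the vessel noise
#'   energy.
#' @export
template_vessel <- function(level = 110, band = c(20, 300)) {
  .template("vessel_lowfreq", level = level, band = band)
}

.template <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "source_template")
}

#' @export
print.source_template <- function(x, ...) {
  cat(sprintf("<source_template: %s> level %.1f dB re 1 uPa\n", x$kind, x$level))
  extra <- x[setdiff(names(x), c("kind", "level"))]
  for (nm in names(extra)) {
    cat(sprintf("  %s: %s\n", nm, paste(signif(unlist(extra[[nm]]), 4), collapse = " ")))
  }
  invisible(x)
}
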