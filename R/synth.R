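# Waveform synthesis for single emissions and full scenes.
#
# All snippet generators return pressure in uPa at the requested sampling
# rate and are deterministic: randomness (event timing jitter, ambient
# noise) enters only at the scene level, where it is controlled by the
# scene seed.

# rendered support of an FM pulse relative to its nominal -10 dB duration
.fm_support_factor <- 1.30

# Tukey (tapered cosine) window; alpha = fraction of the window inside
# the cosine ramps
.tukey <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

.rms <- function(x) sqrt(mean(x^2))

#' Synthesize an upswept FM echolocation pulse
#'
#' Renders a beaked-whale-type polycyclic FM pulse: a linear upsweep
#' centred on the template's peak frequency under a Tukey envelope, plus
#' additive lower-frequency components that produce the template's
#' secondary spectral peaks. Delphinid-type confuser clicks use the same
#' model with no (or negligible) sweep and no secondary components.
#'
#' @param template a `source_template` of kind `cuvier_fm` or `delphinid`
#'   (see [template_cuvier()]).
#' @param sample_rate sampling rate, Hz; must exceed twice the highest
#'   instantaneous frequency of the pulse.
#' @return numeric waveform snippet (uPa), RMS-scaled to `template$level`.
#' @export
make_fm_pulse <- function(template, sample_rate) {
  stopifnot(inherits(template, "source_template"))
  if (!template$kind %in% c("cuvier_fm", "delphinid"))
    stop("template kind must be cuvier_fm or delphinid")
  dur <- template$duration
  if (!is.numeric(dur) || dur <= 0) stop("pulse duration must be positive")
  # template$duration is the nominal -10 dB envelope duration (the
  # convention in which click durations are reported); the rendered
  # support is longer so that the measured -10 dB width lands on the
  # nominal value under the center-weighted envelope below
  support <- dur * .fm_support_factor
  f_top <- template$peak_freq + template$sweep_rate * support / 2
  if (f_top >= sample_rate / 2)
    stop(sprintf("pulse sweeps to %.1f kHz, above Nyquist (%.1f kHz)",
                 f_top / 1e3, sample_rate / 2e3))
  n <- max(8L, round(support * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- template$peak_freq - template$sweep_rate * support / 2
  x <- cos(2 * pi * (f0 * t + template$sweep_rate / 2 * t^2))
  if (length(template$secondary_peaks)) {
    amp <- 10^(template$secondary_rel_db / 20)
    for (i in seq_along(template$secondary_peaks)) {
      x <- x + amp[i] * cos(2 * pi * template$secondary_peaks[i] * t)
    }
  }
  # Tukey taper with center emphasis: the deep spectral dome pins the
  # measured spectral peak to the sweep center (instead of a
  # chirp-spectrum ripple) while the raised edges keep the -10 dB
  # envelope width at the nominal duration
  env <- .tukey(n, 0.12) * (0.25 + 0.75 * sin(pi * (seq_len(n) - 1) / (n - 1))^2)
  x <- x * env
  x / .rms(x) * 10^(template$level / 20)
}

#' Synthesize a narrowband echosounder ping
#'
#' A Gaussian-windowed tone burst at the template's peak frequency; the
#' envelope width is set by the template's spectral width `sigma_f` so
#' that at least 95% of the snippet energy falls inside the template's
#' stated band.
#'
#' @param template a `source_template` of kind `echosounder_28` or
#'   `echosounder_50` (see [template_echosounder()]).
#' @param sample_rate sampling rate, Hz.
#' @return numeric waveform snippet (uPa), RMS-scaled to `template$level`.
#' @export
make_ping <- function(template, sample_rate) {
  stopifnot(inherits(template, "source_template"))
  if (!template$kind %in% c("echosounder_28", "echosounder_50"))
    stop("template kind must be echosounder_28 or echosounder_50")
  if (template$band[1] >= sample_rate / 2)
    stop("ping band lies above Nyquist")
  if (template$peak_freq + 3 * template$sigma_f >= sample_rate / 2)
    stop("ping spectrum extends above Nyquist")
  sigma_t <- 1 / (2 * pi * template$sigma_f)
  dur <- 8 * sigma_t
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- exp(-0.5 * ((t - dur / 2) / sigma_t)^2)
  x <- env * cos(2 * pi * template$peak_freq * (t - dur / 2))
  x / .rms(x) * 10^(template$level / 20)
}

#' Synthesize an ultrasonic antifouling pulse comb
#'
#' A repeating multi-frequency pulse train: each pulse is the sum of tonal
#' components at the comb frequencies under a Tukey envelope, repeated
#' every `pulse_interval` seconds. Carrier phases are tied to absolute
#' time, so a comb with `pulse_duration >= pulse_interval` degenerates to
#' a phase-continuous set of steady tones.
#'
#' @param template a `source_template` of kind `ua_comb`
#'   (see [template_ua_comb()]).
#' @param sample_rate sampling rate, Hz.
#' @param duration length of the rendered train, seconds.
#' @return numeric waveform (uPa); each component has RMS level
#'   `template$level` while the pulse is on.
#' @export
make_ua_comb <- function(template, sample_rate, duration) {
  stopifnot(inherits(template, "source_template"))
  if (template$kind != "ua_comb") stop("template kind must be ua_comb")
  .render_comb(template, sample_rate, t_on = 0, t_off = duration,
               from = 0, to = duration)
}

# render the comb for scene window [from, to), with the device on over
# [t_on, t_off); all times in seconds on the scene clock
.render_comb <- function(template, sample_rate, t_on, t_off, from, to) {
  if (length(template$freqs) == 0L) stop("comb must contain at least one component")
  if (max(template$freqs) >= sample_rate / 2)
    stop(sprintf("comb component %.1f kHz is above Nyquist (%.1f kHz)",
                 max(template$freqs) / 1e3, sample_rate / 2e3))
  n <- round((to - from) * sample_rate)
  out <- numeric(n)
  if (n == 0L || t_off <= from || t_on >= to) return(out)
  amp <- sqrt(2) * 10^(template$level / 20)
  pd <- template$pulse_duration
  pri <- template$pulse_interval
  continuous <- pd >= pri
  if (continuous) {
    spans <- data.frame(ps = max(t_on, from), pe = min(t_off, to))
    taper <- FALSE
  } else {
    k0 <- max(0, floor((from - t_on - pd) / pri))
    k1 <- max(0, ceiling((to - t_on) / pri))
    ps <- t_on + (k0:k1) * pri
    keep <- ps < min(t_off, to) & (ps + pd) > from & ps + pd <= t_off
    spans <- data.frame(ps = ps[keep], pe = ps[keep] + pd)
    taper <- TRUE
  }
  for (i in seq_len(nrow(spans))) {
    s <- max(spans$ps[i], from); e <- min(spans$pe[i], to)
    i0 <- round((s - from) * sample_rate)
    i1 <- round((e - from) * sample_rate)
    if (i1 <= i0) next
    idx <- (i0 + 1L):min(i1, n)
    t_abs <- from + (idx - 1L) / sample_rate
    seg <- numeric(length(idx))
    for (f in template$freqs) seg <- seg + cos(2 * pi * f * t_abs)
    if (taper) seg <- seg * .tukey_at((t_abs - spans$ps[i]) / pd, 0.1)
    out[idx] <- out[idx] + amp * seg
  }
  out
}

# continuous Tukey taper evaluated at fractional position u in [0, 1]
.tukey_at <- function(u, alpha = 0.1) {
  w <- rep(1, length(u))
  w[u < 0 | u > 1] <- 0
  lo <- u >= 0 & u < alpha / 2
  hi <- u <= 1 & u > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / alpha - 1)))
  w
}

# band-limited vessel engine noise for window [from, to); seeded per event
# and per 75-s chunk so rendering is window-independent at chunk granularity
.render_vessel <- function(template, sample_rate, event_seed, chunk_index,
                           n) {
  set.seed((event_seed + 7919L * chunk_index) %% .Machine$integer.max)
  x <- stats::rnorm(n)
  ny <- sample_rate / 2
  hi <- min(template$band[2] / ny, 0.99)
  bf <- signal::butter(4, hi, type = "low")
  x <- signal::filter(bf, x)
  if (template$band[1] > 0 && template$band[1] / ny > 1e-4) {
    bf2 <- signal::butter(2, max(template$band[1] / ny, 1e-4), type = "high")
    x <- signal::filter(bf2, x)
  }
  x <- as.numeric(x)
  x / .rms(x) * 10^(template$level / 20)
}
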