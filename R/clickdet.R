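#' Click detector and FM-pulse classifier configuration
#'
#' Thresholds and detector settings for echolocation click detection and
#' beaked whale FM-pulse classification. Classification of a 75-s segment
#' follows a two-stage rule set: candidate transients are found with a
#' Teager-Kaiser energy detector, per-click features are measured, clicks
#' whose features all fall in the "non-FM-pulse" region (peak frequency
#' below 32 kHz, center frequency below 25 kHz, duration under 355 us,
#' sweep rate under 23 kHz/ms) are deleted, and a segment with more than
#' `min_detections` initial detections is labelled as containing beaked
#' whale FM pulses when strictly more than `retained_fraction_min` of its
#' initial detections survive deletion.
#'
#' All comparisons are strict: a click exactly at a deletion threshold is
#' not deleted, a segment with exactly `min_detections` detections is
#' insufficient, and a retained fraction exactly at the threshold is
#' negative.
#'
#' @param segment_len classification segment length, s.
#' @param min_detections minimum initial detections per segment
#'   (exclusive: a segment needs strictly more to be classified).
#' @param peak_freq_min,center_freq_min,duration_min,sweep_rate_min
#'   deletion thresholds: Hz, Hz, s, Hz/s. A candidate is deleted when its
#'   features fall below these (all of them under `"conjunctive"` logic,
#'   any of them under `"disjunctive"`).
#' @param retained_fraction_min retained-fraction threshold (exclusive)
#'   for a positive segment.
#' @param deletion_logic `"conjunctive"` (default) or `"disjunctive"`;
#'   the published rule set reads as conjunctive, but per-criterion
#'   deletion is common in this class of pipeline, so both are available.
#' @param highpass_hz detector pre-filter cutoff, Hz (4th-order
#'   Butterworth high-pass; the detector targets ultrasonic clicks and
#'   this removes vessel-band energy).
#' @param tk_mad_mult detection threshold in robust units: threshold =
#'   median + `tk_mad_mult` * MAD of the smoothed Teager-Kaiser energy.
#' @param smooth_s moving-average smoothing applied to the energy series
#'   before thresholding, s.
#' @param lockout_s minimum spacing between successive detections, s.
#' @param snippet_s analysis window extracted around each detection, s.
#' @param snr_gate_db required elevation of a candidate's smoothed
#'   squared envelope over the local background (median within
#'   `bg_win_s`), dB. Echolocation clicks are isolated transients over a
#'   quiet background; quasi-continuous sources (such as antifouling
#'   pulse combs) produce envelope maxima riding on a high background
#'   and are rejected by this gate.
#' @param bg_win_s half-width of the local-background window, s.
#' @param max_duration_s candidates whose measured -10 dB envelope
#'   duration exceeds this are discarded at the detection stage: they
#'   are not echolocation clicks (e.g. millisecond-scale echosounder
#'   pings or the onsets of 50-ms antifouling pulses). Standard click
#'   detectors bound click length the same way.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(segment_len = 75, min_detections = 7,
                              peak_freq_min = 32000, center_freq_min = 25000,
                              duration_min = 355e-6, sweep_rate_min = 23e6,
                              retained_fraction_min = 0.13,
                              deletion_logic = c("conjunctive", "disjunctive"),
                              highpass_hz = 10000, tk_mad_mult = 12,
                              smooth_s = 2e-4, lockout_s = 5e-3,
                              snippet_s = 2e-3, snr_gate_db = 18,
                              bg_win_s = 0.05, max_duration_s = 1.5e-3) {
  deletion_logic <- match.arg(deletion_logic)
  stopifnot(segment_len > 0, peak_freq_min > 0, center_freq_min > 0,
            duration_min > 0, sweep_rate_min > 0,
            retained_fraction_min > 0, retained_fraction_min < 1)
  structure(list(segment_len = segment_len, min_detections = min_detections,
                 peak_freq_min = peak_freq_min,
                 center_freq_min = center_freq_min,
                 duration_min = duration_min, sweep_rate_min = sweep_rate_min,
                 retained_fraction_min = retained_fraction_min,
                 deletion_logic = deletion_logic, highpass_hz = highpass_hz,
                 tk_mad_mult = tk_mad_mult, smooth_s = smooth_s,
                 lockout_s = lockout_s, snippet_s = snippet_s,
                 snr_gate_db = snr_gate_db, bg_win_s = bg_win_s,
                 max_duration_s = max_duration_s),
            class = "classifier_config")
}

#' Teager-Kaiser energy operator
#'
#' Nonlinear energy operator `psi[x](n) = x(n)^2 - x(n-1) x(n+1)`,
#' sensitive to both amplitude and frequency of a transient; on a pure
#' sinusoid of amplitude A and digital frequency Omega it is the constant
#' `A^2 sin^2(Omega)`. Endpoints, where the operator is undefined, are
#' zero.
#'
#' @param x numeric waveform, length at least 3.
#' @return numeric vector, same length as `x`.
#' @export
tk_energy <- function(x) {
  n <- length(x)
  if (n < 3L) stop("tk_energy needs at least 3 samples")
  x0 <- x[2:(n - 1)]
  c(0, x0 * x0 - x[1:(n - 2)] * x[3:n], 0)
}

#' Detect echolocation click candidates
#'
#' High-passes the recording, computes smoothed Teager-Kaiser energy,
#' thresholds it at median + k * MAD, and takes the energy maximum of each
#' above-threshold excursion as a candidate time (subject to a lockout).
#' Each candidate carries the features measured by [extract_features()]
#' on a short snippet centred on it.
#'
#' @param rec a [calibrated_recording] (or numeric samples via `samples`
#'   + `sample_rate` internally).
#' @param config a [classifier_config()].
#' @param time_offset seconds added to candidate times (used when
#'   processing a long recording in chunks).
#' @return data.frame of class candidates: `time` (s), `peak_freq`,
#'   `center_freq` (Hz), `duration` (s), `sweep_rate` (Hz/s), `tk_score`.
#' @export
detect_candidates <- function(rec, config = classifier_config(),
                              time_offset = 0) {
  stopifnot(inherits(rec, "calibrated_recording"))
  fs <- rec$sample_rate
  if (fs / 2 <= config$highpass_hz * 1.5)
    stop("sample rate too low for the ultrasonic analysis band")
  bf <- signal::butter(4, config$highpass_hz / (fs / 2), type = "high")
  xf <- .zero_phase(bf$b, bf$a, rec$samples)
  psi <- tk_energy(xf)
  w <- max(3L, round(config$smooth_s * fs))
  sm <- .moving_avg(psi, w)
  rs <- .robust_stats(sm)
  med <- rs[["median"]]
  thr <- med + config$tk_mad_mult * rs[["mad"]]
  above <- sm > thr
  cand_idx <- integer(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    peaks <- vapply(runs, function(j) {
      seg <- starts[j]:ends[j]
      seg[which.max(sm[seg])]
    }, integer(1))
    # lockout: greedy by energy
    o <- order(sm[peaks], decreasing = TRUE)
    kept <- integer(0)
    lock <- round(config$lockout_s * fs)
    for (p in peaks[o]) {
      if (!length(kept) || all(abs(kept - p) >= lock)) kept <- c(kept, p)
    }
    # transient gate on the squared envelope (frequency-flat, unlike the
    # TK energy): the peak must stand well above the local background
    sq <- .moving_avg(xf * xf, w)
    gate <- 10^(config$snr_gate_db / 10)
    hw <- round(config$bg_win_s * fs)
    n_sm <- length(sq)
    kept <- kept[vapply(kept, function(i) {
      bg <- stats::median(sq[max(1L, i - hw):min(n_sm, i + hw)])
      sq[i] >= gate * max(bg, .Machine$double.xmin)
    }, logical(1))]
    cand_idx <- sort(kept)
  }
  half <- round(config$snippet_s * fs / 2)
  n <- length(xf)
  rows <- lapply(cand_idx, function(i) {
    i0 <- max(1L, i - half); i1 <- min(n, i + half)
    feats <- extract_features(xf[i0:i1], fs,
                              band = c(config$highpass_hz, fs / 2))
    data.frame(time = time_offset + (i - 1) / fs,
               peak_freq = feats[["peak_freq"]],
               center_freq = feats[["center_freq"]],
               duration = feats[["duration"]],
               sweep_rate = feats[["sweep_rate"]],
               tk_score = (sm[i] - med) / (thr - med))
  })
  if (!length(rows)) {
    return(data.frame(time = numeric(0), peak_freq = numeric(0),
                      center_freq = numeric(0), duration = numeric(0),
                      sweep_rate = numeric(0), tk_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  # duration veto: ms-scale transients are not echolocation clicks
  out[out$duration <= config$max_duration_s, , drop = FALSE]
}

#' Measure spectral and temporal click features
#'
#' Feature conventions: peak frequency is the interpolated maximum of the
#' zero-padded magnitude spectrum within the analysis band; center
#' frequency is the spectral centroid over the band; duration is the
#' width of the Hilbert envelope at -10 dB below its peak; sweep rate is
#' the slope of a least-squares line through the spectrogram ridge of the
#' high-energy frames.
#'
#' @param snippet numeric waveform window holding one click.
#' @param sample_rate sampling rate, Hz.
#' @param band analysis band `c(lo, hi)` in Hz.
#' @return named numeric vector: `peak_freq` (Hz), `center_freq` (Hz),
#'   `duration` (s), `sweep_rate` (Hz/s).
#' @export
extract_features <- function(snippet, sample_rate, band = c(10000, sample_rate / 2)) {
  if (all(snippet == 0)) stop("all-zero snippet")
  x <- snippet - mean(snippet)
  n <- length(x)
  nfft <- max(8192L, 2^ceiling(log2(n)) * 4L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  m <- Mod(X[seq_len(nfft %/% 2 + 1L)])
  f <- (seq_len(nfft %/% 2 + 1L) - 1) * sample_rate / nfft
  inb <- which(f >= band[1] & f <= band[2])
  # smooth the power spectrum (~1.5 kHz) before peak picking: FM-pulse
  # spectra carry strong chirp ripples that would otherwise capture argmax
  df <- sample_rate / nfft
  wb <- max(3L, round(1500 / df))
  if (wb %% 2L == 0L) wb <- wb + 1L
  ps <- as.numeric(stats::filter(m^2, rep(1 / wb, wb), sides = 2))
  ps[is.na(ps)] <- 0
  ipk <- inb[which.max(ps[inb])]
  peak_freq <- f[ipk] + .parab_offset(ps, ipk) * sample_rate / nfft
  p <- m[inb]^2
  center_freq <- sum(f[inb] * p) / sum(p)
  # envelope duration at -10 dB
  # ~40 us smoothing suppresses beat ripple between polycyclic pulse
  # components; the snippet is zero-padded so the smoother stays valid
  # across the pulse edges even when the snippet is the bare pulse
  w <- max(3L, round(4e-5 * sample_rate))
  env <- Mod(.analytic(c(numeric(w), x, numeric(w))))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  above <- which(env >= max(env) * 10^(-10 / 20))
  duration <- (max(above) - min(above) + 1) / sample_rate
  sweep_rate <- .ridge_sweep(x, sample_rate, band)
  c(peak_freq = peak_freq, center_freq = center_freq,
    duration = duration, sweep_rate = sweep_rate)
}

#' Locate local maxima of a waveform's magnitude spectrum
#'
#' Computes the zero-padded power spectrum, smooths it over
#' `smooth_hz`, and returns the local maxima within `band` whose level
#' is within `min_rel_db` of the strongest in-band component. Used to
#' read characteristic spectral peaks (e.g. the 17 and 23 kHz secondary
#' peaks of a Cuvier's beaked whale FM pulse) off a click snippet.
#'
#' @param x numeric waveform.
#' @param sample_rate sampling rate, Hz.
#' @param band frequency band `c(lo, hi)` to search, Hz.
#' @param smooth_hz spectral smoothing bandwidth, Hz.
#' @param min_rel_db maxima more than this many dB below the strongest
#'   in-band maximum are dropped.
#' @return data.frame with `freq_hz` and `level_db` (dB relative to the
#'   strongest in-band maximum), ordered by frequency.
#' @export
spectral_peaks <- function(x, sample_rate, band = c(1000, sample_rate / 2),
                           smooth_hz = 1000, min_rel_db = 20) {
  if (all(x == 0)) stop("all-zero waveform")
  x <- x - mean(x)
  n <- length(x)
  nfft <- max(65536L, 2^ceiling(log2(n)) * 4L)
  m2 <- Mod(stats::fft(c(x, numeric(nfft - n)))[seq_len(nfft %/% 2 + 1L)])^2
  f <- (seq_len(nfft %/% 2 + 1L) - 1) * sample_rate / nfft
  df <- sample_rate / nfft
  wb <- max(3L, round(smooth_hz / df))
  ps <- .moving_avg(m2, wb)
  inb <- f >= band[1] & f <= band[2]
  v <- ps[inb]; fv <- f[inb]
  loc <- which(diff(sign(diff(v))) == -2) + 1L
  if (!length(loc)) return(data.frame(freq_hz = numeric(0), level_db = numeric(0)))
  lev <- 10 * log10(v[loc] / max(v[loc]))
  keep <- lev >= -min_rel_db
  peaks <- data.frame(freq_hz = fv[loc][keep] +
                        vapply(loc[keep], function(i) .parab_offset(v, i) * df,
                               numeric(1)),
                      level_db = lev[keep])
  peaks[order(peaks$freq_hz), , drop = FALSE]
}

# analytic signal via FFT (Hilbert transform)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# sweep rate (Hz/s): LS slope of the spectrogram ridge over frames whose
# RMS is within 12 dB of the loudest frame
.ridge_sweep <- function(x, sample_rate, band) {
  win <- max(8L, round(1.6e-4 * sample_rate))
  hop <- max(1L, win %/% 4L)
  n <- length(x)
  if (n < win + 2L * hop) return(0)
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- .tukey(win, 0.5)
  nfft <- max(1024L, 2^ceiling(log2(win)) * 8L)
  f <- (seq_len(nfft %/% 2 + 1L) - 1) * sample_rate / nfft
  inb <- which(f >= band[1] & f <= band[2])
  ridge_t <- ridge_f <- amp <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1L)] * w
    m <- Mod(stats::fft(c(seg, numeric(nfft - win)))[seq_len(nfft %/% 2 + 1L)])
    j <- inb[which.max(m[inb])]
    ridge_f[i] <- f[j] + .parab_offset(m, j) * sample_rate / nfft
    ridge_t[i] <- (starts[i] - 1 + (win - 1) / 2) / sample_rate
    amp[i] <- max(m[inb])
  }
  keep <- amp >= max(amp) * 10^(-12 / 20)
  if (sum(keep) < 3L) return(0)
  unname(stats::coef(stats::lm(ridge_f[keep] ~ ridge_t[keep]))[2])
}

# TRUE where a candidate's features fall in the deletion region
.deleted <- function(cand, config) {
  below <- cbind(cand$peak_freq < config$peak_freq_min,
                 cand$center_freq < config$center_freq_min,
                 cand$duration < config$duration_min,
                 cand$sweep_rate < config$sweep_rate_min)
  if (config$deletion_logic == "conjunctive") {
    rowSums(below) == 4L
  } else {
    rowSums(below) > 0L
  }
}

#' Apply the FM-pulse deletion criteria
#'
#' Removes candidates whose features identify them as non-beaked-whale
#' clicks. Under conjunctive logic a candidate is deleted only when all
#' four features fall below their thresholds (peak frequency < 32 kHz,
#' center frequency < 25 kHz, duration < 355 us, sweep rate < 23 kHz/ms
#' at defaults); under disjunctive logic, when any one does. All
#' comparisons are strict, so a feature exactly at its threshold never
#' contributes to deletion. Input order is preserved.
#'
#' @param candidates candidate table from [detect_candidates()].
#' @param config a [classifier_config()].
#' @return the retained candidates (same columns, original order).
#' @export
apply_deletion_criteria <- function(candidates, config = classifier_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates[!.deleted(candidates, config), , drop = FALSE]
}

#' Classify fixed segments for beaked whale FM-pulse presence
#'
#' Cuts the candidate timeline into consecutive segments of
#' `config$segment_len` seconds anchored at time 0 (the trailing partial
#' segment is processed under the same rules) and labels each:
#' `insufficient` when the segment has no more than `min_detections`
#' initial detections, otherwise `beaked_whale` when strictly more than
#' `retained_fraction_min` of the initial detections survive the deletion
#' criteria, else `not_beaked_whale`.
#'
#' @param candidates candidate table from [detect_candidates()].
#' @param total_duration recording length, s (sets the number of
#'   segments).
#' @param config a [classifier_config()].
#' @return data.frame of segment decisions: `start`, `end`, `n_detected`,
#'   `n_retained`, `fraction_retained`, `label`.
#' @export
classify_segments <- function(candidates, total_duration,
                              config = classifier_config()) {
  n_seg <- max(1L, ceiling(total_duration / config$segment_len))
  starts <- (seq_len(n_seg) - 1) * config$segment_len
  ends <- pmin(starts + config$segment_len, total_duration)
  kept <- if (nrow(candidates)) !.deleted(candidates, config) else logical(0)
  out <- lapply(seq_len(n_seg), function(i) {
    inseg <- candidates$time >= starts[i] & candidates$time < ends[i]
    nd <- sum(inseg)
    nr <- sum(inseg & kept)
    fr <- if (nd > 0) nr / nd else NA_real_
    label <- if (nd <= config$min_detections) "insufficient"
      else if (fr > config$retained_fraction_min) "beaked_whale"
      else "not_beaked_whale"
    data.frame(start = starts[i], end = ends[i], n_detected = nd,
               n_retained = nr, fraction_retained = fr, label = label)
  })
  do.call(rbind, out)
}

#' Log beaked whale acoustic presence from segment decisions
#'
#' Merges adjacent positive segments into encounters and returns them as
#' an encounter log (half-open intervals on the recording clock plus
#' UTC).
#'
#' @param decisions segment table from [classify_segments()];
#'   non-overlapping and time-ordered.
#' @param t0 UTC start of the recording.
#' @return data.frame encounter log: `signal_class` (`"beaked_whale"`),
#'   `start_s`, `end_s`, `start_utc`, `end_utc`.
#' @export
log_bw_presence <- function(decisions,
                            t0 = as.POSIXct("2019-01-01 00:00:00", tz = "UTC")) {
  if (nrow(decisions) > 1L) {
    o <- order(decisions$start)
    decisions <- decisions[o, ]
    if (any(decisions$start[-1] < decisions$end[-nrow(decisions)]))
      stop("segments overlap")
  }
  pos <- decisions[decisions$label == "beaked_whale", , drop = FALSE]
  if (nrow(pos) == 0L) {
    return(data.frame(signal_class = character(0), start_s = numeric(0),
                      end_s = numeric(0),
                      start_utc = as.POSIXct(character(0), tz = "UTC"),
                      end_utc = as.POSIXct(character(0), tz = "UTC")))
  }
  m <- merge_intervals(pos$start, pos$end, gap = 1e-9)
  data.frame(signal_class = "beaked_whale", start_s = m$start, end_s = m$end,
             start_utc = t0 + m$start, end_utc = t0 + m$end)
}

#' Summarise an encounter log at minute, hour, and week resolution
#'
#' Cumulative acoustic presence from an encounter log: UTC-aligned
#' half-open 1-min bins touched by an encounter, minutes per hour, and
#' hours per ISO week.
#'
#' @param log encounter log with `start_utc`/`end_utc` (e.g. from
#'   [log_bw_presence()] or [detect_anthro()]); multiple classes are
#'   summarised together.
#' @return list of data.frames: `minutes` (`minute_utc`), `hourly`
#'   (`hour_utc`, `minutes`), `weekly` (`week`, `hours`).
#' @export
presence_summary <- function(log) {
  if (is.null(log) || nrow(log) == 0L) {
    return(list(minutes = data.frame(minute_utc = as.POSIXct(character(0), tz = "UTC")),
                hourly = data.frame(hour_utc = as.POSIXct(character(0), tz = "UTC"),
                                    minutes = integer(0)),
                weekly = data.frame(week = character(0), hours = integer(0))))
  }
  iv <- merge_intervals(as.numeric(log$start_utc), as.numeric(log$end_utc))
  mins <- sort(unique(unlist(lapply(seq_len(nrow(iv)), function(i)
    seq(floor(iv$start[i] / 60), ceiling(iv$end[i] / 60) - 1)))))
  minute_utc <- as.POSIXct(mins * 60, origin = "1970-01-01", tz = "UTC")
  hours <- mins %/% 60
  ht <- table(hours)
  hour_utc <- as.POSIXct(as.numeric(names(ht)) * 3600,
                         origin = "1970-01-01", tz = "UTC")
  wk <- format(hour_utc, "%G-W%V")
  wt <- tapply(rep(1L, length(hour_utc)), wk, sum)
  list(minutes = data.frame(minute_utc = minute_utc),
       hourly = data.frame(hour_utc = hour_utc,
                           minutes = as.integer(ht), row.names = NULL),
       weekly = data.frame(week = names(wt), hours = as.integer(wt),
                           row.names = NULL))
}
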