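#' Soundscape metrics configuration
#'
#' Settings for the per-second Welch PSD and the per-minute metrics
#' derived from it. The defaults follow the long-term monitoring
#' convention: FFT length equal to one second of samples with a Hann
#' window of the same length and 0% overlap (one periodogram per
#' second, 1-Hz bins at a 200-kHz rate), per-minute medians taken in
#' linear power over at least 30 usable seconds, 39 one-third-octave
#' bands with nominal centers from 12.5 Hz to 80 kHz, a 200-Hz coarse
#' PSD, and three 200-Hz proxy bands targeting specific anthropogenic
#' sources (19.3-19.5 kHz for UA devices; 29.1-29.3 kHz for 28-kHz
#' echosounders, chosen to avoid the UA pulse at 28.4-29.0 kHz;
#' 49.9-50.1 kHz for 50-kHz echosounders).
#'
#' @param sample_rate recording sample rate, Hz.
#' @param fft_len FFT and Hann window length in samples (default: one
#'   second).
#' @param minute_min_coverage minimum usable seconds for a minute to
#'   report metrics.
#' @param proxy_bins named list of `c(lo, hi)` Hz proxy bands.
#' @param psd_coarse_bin coarse PSD bin width, Hz.
#' @param floor_db clamp floor for dB conversion, dB re 1 uPa^2/Hz
#'   (mirrors the instrument self-noise floor bounding reported minima).
#' @param exclude data.frame of `start`/`end` second intervals to omit
#'   (e.g. disk-write noise periods); seconds whose frame overlaps an
#'   excluded interval are dropped before any per-minute statistic.
#' @return object of class `soundscape_config`.
#' @export
soundscape_config <- function(sample_rate = 200000, fft_len = sample_rate,
                              minute_min_coverage = 30,
                              proxy_bins = list(ua = c(19300, 19500),
                                                echosounder_28 = c(29100, 29300),
                                                echosounder_50 = c(49900, 50100)),
                              psd_coarse_bin = 200, floor_db = 40,
                              exclude = NULL) {
  stopifnot(fft_len > 0, minute_min_coverage > 0)
  for (b in proxy_bins) stopifnot(length(b) == 2L, b[2] > b[1])
  structure(list(sample_rate = sample_rate, fft_len = as.integer(fft_len),
                 minute_min_coverage = minute_min_coverage,
                 proxy_bins = proxy_bins, psd_coarse_bin = psd_coarse_bin,
                 floor_db = floor_db, exclude = exclude),
            class = "soundscape_config")
}

#' Per-second Welch power spectral density frames
#'
#' Splits the recording into non-overlapping windows of `fft_len`
#' samples (one second at the default rate), applies a Hann window of
#' the full window length (so each frame is a single modified
#' periodogram: Welch's method with window = FFT length and 0% overlap),
#' and returns one-sided mean-square pressure density frames corrected
#' by the recording's transfer function.
#'
#' @param rec a [calibrated_recording].
#' @param config a [soundscape_config()].
#' @param time_offset seconds added to frame times (chunked processing).
#' @return object of class `psd_frames`: list with `freq` (Hz), `power`
#'   (freq x seconds matrix, linear uPa^2/Hz), `time` (frame start, s),
#'   `excluded` (logical per frame), `t0`.
#' @export
welch_psd <- function(rec, config = soundscape_config(rec$sample_rate),
                      time_offset = 0) {
  stopifnot(inherits(rec, "calibrated_recording"))
  fs <- rec$sample_rate
  nfft <- config$fft_len
  n_frames <- length(rec$samples) %/% nfft
  if (n_frames < 1) {
    return(structure(list(freq = numeric(0),
                          power = matrix(numeric(0), 0, 0),
                          time = numeric(0), excluded = logical(0),
                          t0 = rec$t0, frame_s = nfft / fs),
                     class = "psd_frames"))
  }
  w <- .hann(nfft)
  xm <- matrix(rec$samples[seq_len(n_frames * nfft)], nrow = nfft) * w
  X <- stats::mvfft(xm)
  nk <- nfft %/% 2 + 1L
  p <- Mod(X[seq_len(nk), , drop = FALSE])^2 / (fs * sum(w^2))
  p[2:(nk - 1L), ] <- 2 * p[2:(nk - 1L), ]
  freq <- (seq_len(nk) - 1L) * fs / nfft
  gain <- .tf_gain(rec, freq)
  p <- p / 10^(gain / 10)
  tt <- time_offset + (seq_len(n_frames) - 1L) * nfft / fs
  excl <- rep(FALSE, n_frames)
  if (!is.null(config$exclude) && nrow(config$exclude)) {
    for (i in seq_len(nrow(config$exclude))) {
      excl <- excl | .overlaps(tt, tt + nfft / fs,
                               config$exclude$start[i], config$exclude$end[i])
    }
  }
  structure(list(freq = freq, power = p, time = tt, excluded = excl,
                 t0 = rec$t0, frame_s = nfft / fs),
            class = "psd_frames")
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' @export
print.psd_frames <- function(x, ...) {
  cat(sprintf("<psd_frames> %d frames x %d bins (%d excluded)\n",
              length(x$time), length(x$freq), sum(x$excluded)))
  invisible(x)
}

# group frame indices by UTC minute; returns list(minute_utc, idx)
.minute_groups <- function(frames) {
  abs_min <- floor((as.numeric(frames$t0) + frames$time) / 60)
  split(seq_along(frames$time), abs_min)
}

# per-minute median (linear) of a frames-by-anything value matrix;
# returns list(minute_utc, value matrix, coverage)
.per_minute <- function(frames, values, min_cov) {
  groups <- .minute_groups(frames)
  minute_utc <- as.POSIXct(as.numeric(names(groups)) * 60,
                           origin = "1970-01-01", tz = "UTC")
  cov <- vapply(groups, function(ix) sum(!frames$excluded[ix]) * frames$frame_s,
                numeric(1))
  med <- vapply(groups, function(ix) {
    use <- ix[!frames$excluded[ix]]
    if (length(use) * frames$frame_s < min_cov)
      return(rep(NA_real_, nrow(values)))
    apply(values[, use, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(values)))
  med <- matrix(med, nrow = nrow(values))
  list(minute_utc = minute_utc, value = med, coverage_s = unname(cov))
}

#' Per-minute median PSD
#'
#' Median of the per-second mean-square pressure density over the usable
#' seconds of each UTC minute, computed in linear power and then
#' converted to dB (clamped at the configured floor). Minutes with fewer
#' than `minute_min_coverage` usable seconds are reported as missing.
#'
#' @param frames a [welch_psd()] result.
#' @param config a [soundscape_config()].
#' @return object of class `minute_metrics`: `minute_utc`, `freq`,
#'   `psd_db` (freq x minutes), `coverage_s`.
#' @export
minute_median <- function(frames, config = soundscape_config()) {
  pm <- .per_minute(frames, frames$power, config$minute_min_coverage)
  psd_db <- db_from_power(pm$value, floor_db = config$floor_db)
  psd_db[is.na(pm$value)] <- NA_real_
  structure(list(minute_utc = pm$minute_utc, freq = frames$freq,
                 psd_db = psd_db, coverage_s = pm$coverage_s),
            class = "minute_metrics")
}

#' @export
print.minute_metrics <- function(x, ...) {
  cat(sprintf("<minute_metrics> %d minutes x %d bins; coverage %s s\n",
              length(x$minute_utc), nrow(x$psd_db),
              paste(range(x$coverage_s), collapse = "-")))
  invisible(x)
}

#' Plot per-minute PSD as a long-term spectrogram
#'
#' @param x a `minute_metrics` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.minute_metrics <- function(x, ...) {
  graphics::image(as.numeric(x$minute_utc), x$freq / 1000, t(x$psd_db),
                  xlab = "Time", ylab = "Frequency (kHz)",
                  main = "Long-term spectrogram (per-minute median PSD)", ...)
  invisible(x)
}

#' One-third-octave band table
#'
#' The 39 standard proportional bands used for long-term soundscape
#' levels: exact base-10 centers `10^(n/10)` for band numbers 11 to 49
#' (nominal 12.5 Hz to 80 kHz), with band edges at
#' `center * 10^(+/- 1/20)`.
#'
#' @return data.frame: `band` (index), `nominal_hz`, `center_hz`,
#'   `lo_hz`, `hi_hz`, `bw_hz`.
#' @export
tol_bands <- function() {
  n <- 11:49
  center <- 10^(n / 10)
  nominal <- c(12.5, 16, 20, 25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200,
               250, 315, 400, 500, 630, 800, 1000, 1250, 1600, 2000, 2500,
               3150, 4000, 5000, 6300, 8000, 10000, 12500, 16000, 20000,
               25000, 31500, 40000, 50000, 63000, 80000)
  lo <- center * 10^(-1 / 20)
  hi <- center * 10^(1 / 20)
  data.frame(band = n, nominal_hz = nominal, center_hz = center,
             lo_hz = lo, hi_hz = hi, bw_hz = hi - lo)
}

#' Per-minute one-third-octave band levels
#'
#' Integrates each per-second 1-Hz PSD frame over the 39 one-third-octave
#' bands (band power = sum of linear density over `[lo, hi)` edges), then
#' takes the per-minute median over usable seconds and converts to dB re
#' 1 uPa^2. Bands whose upper edge exceeds the available PSD bandwidth
#' are reported as missing.
#'
#' @param frames a [welch_psd()] result (1-Hz bins).
#' @param config a [soundscape_config()].
#' @return object of class `tol_metrics`: `minute_utc`, `bands` (see
#'   [tol_bands()]), `tol_db` (39 x minutes), `coverage_s`.
#' @export
tol_levels <- function(frames, config = soundscape_config()) {
  bands <- tol_bands()
  df <- frames$freq[2] - frames$freq[1]
  bp <- matrix(NA_real_, nrow(bands), ncol(frames$power))
  fmax <- max(frames$freq)
  for (i in seq_len(nrow(bands))) {
    if (bands$hi_hz[i] > fmax + df / 2) next  # insufficient bandwidth
    sel <- frames$freq >= bands$lo_hz[i] & frames$freq < bands$hi_hz[i]
    bp[i, ] <- colSums(frames$power[sel, , drop = FALSE]) * df
  }
  pm <- .per_minute(frames, bp, config$minute_min_coverage)
  tol_db <- db_from_power(pm$value)
  tol_db[is.na(pm$value)] <- NA_real_
  structure(list(minute_utc = pm$minute_utc, bands = bands, tol_db = tol_db,
                 coverage_s = pm$coverage_s),
            class = "tol_metrics")
}

#' Band level of the nominal 125-Hz third octave as a spectral density
#'
#' The vessel-noise indicator: the nominal-125-Hz one-third-octave band
#' level converted to dB re 1 uPa^2/Hz by subtracting `10*log10(bw)`
#' (bandwidth of the band), making it comparable to PSD levels.
#'
#' @param tol a `tol_metrics` object (or a numeric vector of 39 band
#'   levels in dB re 1 uPa^2).
#' @return numeric vector of per-minute densities, dB re 1 uPa^2/Hz.
#' @export
tol125_density <- function(tol) {
  bands <- tol_bands()
  i <- which(bands$nominal_hz == 125)
  lev <- if (inherits(tol, "tol_metrics")) tol$tol_db[i, ] else tol[i]
  lev - 10 * log10(bands$bw_hz[i])
}

#' Per-minute coarse-bin PSD and anthropogenic proxy-band levels
#'
#' Averages the 1-Hz PSD into coarse bins (200 Hz by default) as linear
#' density, then reports the per-minute median for each configured proxy
#' band (UA: 19.3-19.5 kHz; 28-kHz echosounder: 29.1-29.3 kHz; 50-kHz
#' echosounder: 49.9-50.1 kHz), in dB re 1 uPa^2/Hz. The same 30-s
#' coverage rule as [minute_median()] applies.
#'
#' @param frames a [welch_psd()] result.
#' @param config a [soundscape_config()].
#' @return data.frame: `minute_utc`, `coverage_s`, one dB column per
#'   proxy band (named `proxy_<name>_db`).
#' @export
proxy_bin_levels <- function(frames, config = soundscape_config()) {
  vals <- vapply(config$proxy_bins, function(b) {
    sel <- frames$freq >= b[1] & frames$freq < b[2]
    colMeans(frames$power[sel, , drop = FALSE])
  }, numeric(ncol(frames$power)))
  vals <- t(matrix(vals, ncol = length(config$proxy_bins)))
  pm <- .per_minute(frames, vals, config$minute_min_coverage)
  out <- data.frame(minute_utc = pm$minute_utc, coverage_s = pm$coverage_s)
  db <- db_from_power(pm$value, floor_db = config$floor_db)
  db[is.na(pm$value)] <- NA_real_
  for (i in seq_along(config$proxy_bins)) {
    out[[paste0("proxy_", names(config$proxy_bins)[i], "_db")]] <- db[i, ]
  }
  rownames(out) <- NULL
  out
}

#' Coarse-bin per-minute PSD over the full band
#'
#' @param frames a [welch_psd()] result.
#' @param config a [soundscape_config()]; `psd_coarse_bin` sets the bin
#'   width.
#' @return list: `freq` (coarse bin centers, Hz), `psd_db`
#'   (bins x minutes), `minute_utc`, `coverage_s`.
#' @export
coarse_psd <- function(frames, config = soundscape_config()) {
  bw <- config$psd_coarse_bin
  df <- frames$freq[2] - frames$freq[1]
  per <- round(bw / df)
  grp <- frames$freq %/% bw
  cnt <- table(grp)
  keep_grp <- as.numeric(names(cnt))[cnt == per]  # only complete bins
  sel <- grp %in% keep_grp
  p <- rowsum(frames$power[sel, , drop = FALSE], grp[sel]) / per
  pm <- .per_minute(frames, p, config$minute_min_coverage)
  db <- db_from_power(pm$value, floor_db = config$floor_db)
  db[is.na(pm$value)] <- NA_real_
  list(freq = sort(keep_grp) * bw + bw / 2, psd_db = db,
       minute_utc = pm$minute_utc, coverage_s = pm$coverage_s)
}

#' Disk-write exclusion intervals for a recording cycle
#'
#' The recorder's periodic disk activity contaminates 15 s of every
#' 75-s cycle; these intervals are omitted from soundscape metrics.
#'
#' @param duration recording length, s.
#' @param cycle_s,noise_s cycle length and contaminated span, s.
#' @return data.frame `start`/`end` (s), suitable for the `exclude`
#'   slot of [soundscape_config()].
#' @export
disk_write_intervals <- function(duration, cycle_s = 75, noise_s = 15) {
  k <- 0:max(0, ceiling(duration / cycle_s) - 1)
  data.frame(start = k * cycle_s, end = pmin(k * cycle_s + noise_s, duration))
}
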