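#' Compute a long-term spectral average (LTSA)
#'
#' Time-compressed spectrogram used to screen long recordings: successive
#' non-overlapping FFT frames of length `sample_rate / f_res` are averaged
#' (in linear power) over `t_avg`-second bins, corrected by the
#' recording's transfer function, and returned in dB re 1 uPa^2/Hz. The
#' default (5-s time average, 100-Hz frequency resolution) is the
#' full-band screening configuration; for the low-frequency vessel band
#' use [compute_mid_ltsa()], which decimates first.
#'
#' @param rec a [calibrated_recording].
#' @param t_avg time-bin length, s.
#' @param f_res frequency resolution, Hz; `sample_rate / f_res` must be a
#'   whole number of samples.
#' @param time_offset seconds added to the time axis (for chunked
#'   processing).
#' @param frame_stride average every `frame_stride`-th FFT frame instead
#'   of all of them (default 1 = every frame). A stride of 4 quarters the
#'   FFT cost of screening multi-hour recordings at the price of a
#'   noisier (but unbiased) bin average.
#' @return object of class `ltsa`: list with `time` (bin start, s),
#'   `freq` (Hz), `level` (freq x time matrix, dB re 1 uPa^2/Hz), and the
#'   averaging parameters.
#' @export
compute_ltsa <- function(rec, t_avg = 5, f_res = 100, time_offset = 0,
                         frame_stride = 1) {
  stopifnot(inherits(rec, "calibrated_recording"))
  fs <- rec$sample_rate
  nfft <- fs / f_res
  if (abs(nfft - round(nfft)) > 1e-9) {
    cand <- fs / c(floor(fs / f_res), ceiling(fs / f_res))
    stop(sprintf(
      "f_res = %g Hz incompatible with sample rate %g Hz; nearest valid: %s",
      f_res, fs, paste(signif(unique(cand), 6), collapse = ", ")))
  }
  nfft <- as.integer(round(nfft))
  per_bin <- round(t_avg * fs / nfft)
  if (per_bin < 1) stop("t_avg shorter than one FFT frame")
  n_frames <- length(rec$samples) %/% nfft
  n_bins <- n_frames %/% per_bin
  if (n_bins < 1) stop("recording shorter than one LTSA time bin")
  stride <- max(1L, as.integer(frame_stride))
  frame_ix <- seq(1L, n_bins * per_bin, by = stride)
  if (stride == 1L) {
    xm <- matrix(rec$samples[seq_len(n_bins * per_bin * nfft)], nrow = nfft)
  } else {
    off <- rep((frame_ix - 1L) * nfft, each = nfft)
    xm <- matrix(rec$samples[off + seq_len(nfft)], nrow = nfft)
  }
  X <- stats::mvfft(xm)
  nk <- nfft %/% 2 + 1L
  # one-sided periodogram density, rectangular window
  p <- Mod(X[seq_len(nk), , drop = FALSE])^2 / (fs * nfft)
  p[2:(nk - 1L), ] <- 2 * p[2:(nk - 1L), ]
  # average frames into time bins
  grp <- (frame_ix - 1L) %/% per_bin + 1L
  lev <- t(rowsum(t(p), grp, reorder = FALSE) /
             as.vector(table(grp)))
  freq <- (seq_len(nk) - 1L) * f_res
  gain <- .tf_gain(rec, freq)
  lev_db <- 10 * log10(pmax(lev, .Machine$double.xmin)) - gain
  structure(list(time = time_offset + (seq_len(n_bins) - 1L) * t_avg,
                 freq = freq, level = lev_db, t_avg = t_avg, f_res = f_res,
                 t0 = rec$t0),
            class = "ltsa")
}

#' @export
print.ltsa <- function(x, ...) {
  cat(sprintf("<ltsa> %d time bins x %d frequency bins (%g s avg, %g Hz res)\n",
              length(x$time), length(x$freq), x$t_avg, x$f_res))
  invisible(x)
}

#' Plot an LTSA panel
#'
#' Renders the level matrix as an image (time vs frequency), the format
#' in which hour-long panels are screened for anthropogenic signals.
#'
#' @param x an `ltsa`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ltsa <- function(x, ...) {
  graphics::image(x$time, x$freq / 1000, t(x$level),
                  xlab = "Time (s)", ylab = "Frequency (kHz)",
                  main = "Long-term spectral average", ...)
  invisible(x)
}

#' @rdname compute_ltsa
#' @param factor decimation factor applied before the mid-frequency LTSA
#'   (default 20, e.g. 200 kHz to 10 kHz).
#' @param method decimation method: `"fir"` (anti-aliased polyphase FIR,
#'   the default) or `"boxcar"` (block mean; far cheaper for multi-hour
#'   streaming, with a flat passband well below the output Nyquist —
#'   adequate for the sub-300-Hz vessel band).
#' @export
compute_mid_ltsa <- function(rec, factor = 20, t_avg = 5, f_res = 10,
                             time_offset = 0, method = c("fir", "boxcar")) {
  stopifnot(inherits(rec, "calibrated_recording"))
  method <- match.arg(method)
  y <- if (method == "fir") .decimate_fir(rec$samples, factor)
       else .decimate_boxcar(rec$samples, factor)
  rec2 <- calibrated_recording(as.numeric(y),
                               sample_rate = rec$sample_rate / factor,
                               t0 = rec$t0, full_scale_db = rec$full_scale_db,
                               tf = rec$tf)
  compute_ltsa(rec2, t_avg = t_avg, f_res = f_res, time_offset = time_offset)
}

# per-time-bin robust floor: median level across frequencies above f_min
.bin_floor <- function(ltsa, f_min = 19000) {
  sel <- ltsa$freq >= f_min
  apply(ltsa$level[sel, , drop = FALSE], 2L, stats::median)
}

# merge flagged LTSA time bins into encounter intervals
.flags_to_intervals <- function(flags, time, t_avg, gap_s, signal_class) {
  if (!any(flags)) {
    return(data.frame(signal_class = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  iv <- merge_intervals(time[flags], time[flags] + t_avg, gap = gap_s)
  data.frame(signal_class = signal_class, start_s = iv$start, end_s = iv$end)
}

# narrowband local maxima of one LTSA spectrum column above a floor.
# A qualifying line must also be spectrally narrow: its level must drop
# by >= narrow_db within +/- check_hz. That separates the continuous
# tonal lines of an antifouling comb (one frequency bin wide) from the
# kHz-wide spectral humps and tonal components of echolocation click
# trains, whose short duration spreads them over many bins.
.comb_peaks <- function(lev, freq, floor_db, margin_db, f_min, min_spacing,
                        narrow_db = 4, check_hz = 500) {
  sel <- which(freq >= f_min)
  v <- lev[sel]
  loc <- which(diff(sign(diff(v))) == -2) + 1L
  loc <- loc[v[loc] >= floor_db + margin_db]
  if (!length(loc)) return(numeric(0))
  df <- freq[2] - freq[1]
  side <- max(1L, round(check_hz / df))
  narrow <- vapply(loc, function(i) {
    s <- max(v[max(1L, i - side)], v[min(length(v), i + side)])
    v[i] - s >= narrow_db
  }, logical(1))
  loc <- loc[narrow]
  if (!length(loc)) return(numeric(0))
  f <- freq[sel][loc]
  keep <- c(TRUE, diff(f) >= min_spacing)
  f[keep]
}

#' Log ultrasonic antifouling (UA) encounters from an LTSA
#'
#' Rule-based stand-in for the manual analyst screen: a time bin is
#' flagged when at least `min_peaks` narrowband spectral maxima at least
#' `margin_db` above the bin's local floor occur above `f_min`, forming a
#' comb; flagged bins closer than `gap_s` are merged into encounters.
#' Validated against synthetic ground truth only; it does not claim to
#' replicate analyst judgment.
#'
#' @param ltsa full-band `ltsa` from [compute_ltsa()].
#' @param min_peaks minimum number of comb lines.
#' @param margin_db required elevation above the local floor, dB.
#' @param f_min lowest comb frequency considered, Hz (the UA suite starts
#'   near 19 kHz).
#' @param min_spacing_hz minimum spacing between counted comb lines, Hz.
#' @param gap_s merge tolerance between flagged bins, s.
#' @param min_duration_s encounters shorter than this are dropped;
#'   antifouling systems transmit continuously, so very short comb-like
#'   events (e.g. an echolocation click train crossing a bin) do not
#'   qualify.
#' @return data.frame encounter intervals: `signal_class` (`"ua"`),
#'   `start_s`, `end_s`.
#' @export
detect_ua <- function(ltsa, min_peaks = 3, margin_db = 6, f_min = 19000,
                      min_spacing_hz = 500, gap_s = 10, min_duration_s = 15) {
  stopifnot(inherits(ltsa, "ltsa"))
  floor_db <- .bin_floor(ltsa, f_min)
  flags <- vapply(seq_along(ltsa$time), function(j) {
    pk <- .comb_peaks(ltsa$level[, j], ltsa$freq, floor_db[j], margin_db,
                      f_min, min_spacing_hz)
    length(pk) >= min_peaks
  }, logical(1))
  iv <- .flags_to_intervals(flags, ltsa$time, ltsa$t_avg, gap_s, "ua")
  iv[iv$end_s - iv$start_s >= min_duration_s, , drop = FALSE]
}

#' Log echosounder encounters from an LTSA
#'
#' Flags time bins with persistent narrowband energy confined to the
#' 28-kHz-class band (27-31 kHz) or the 50-kHz-class band (49-51 kHz),
#' at least `margin_db` above the bin's out-of-band floor and without an
#' accompanying comb above 19 kHz (which would indicate a UA device
#' instead).
#'
#' @inheritParams detect_ua
#' @param bands named list of class bands, Hz.
#' @return data.frame encounter intervals per band class
#'   (`signal_class` = `"echosounder_28"` / `"echosounder_50"`).
#' @export
detect_echosounder <- function(ltsa, bands = list(echosounder_28 = c(27000, 31000),
                                                  echosounder_50 = c(49000, 51000)),
                               margin_db = 6, min_peaks = 3, f_min = 19000,
                               min_spacing_hz = 500, gap_s = 10) {
  stopifnot(inherits(ltsa, "ltsa"))
  floor_db <- .bin_floor(ltsa, f_min)
  out <- lapply(names(bands), function(cls) {
    b <- bands[[cls]]
    inb <- ltsa$freq >= b[1] & ltsa$freq <= b[2]
    flags <- vapply(seq_along(ltsa$time), function(j) {
      peak_in_band <- max(ltsa$level[inb, j])
      if (peak_in_band < floor_db[j] + margin_db) return(FALSE)
      # a comb above f_min outside this band means UA, not an echosounder
      pk <- .comb_peaks(ltsa$level[, j], ltsa$freq, floor_db[j], margin_db,
                        f_min, min_spacing_hz)
      pk_out <- pk[pk < b[1] | pk > b[2]]
      length(pk_out) < min_peaks
    }, logical(1))
    .flags_to_intervals(flags, ltsa$time, ltsa$t_avg, gap_s, cls)
  })
  do.call(rbind, out)
}

#' Log vessel-noise encounters from a mid-frequency LTSA
#'
#' Flags time bins whose mean level below `f_max` exceeds a rolling
#' per-frequency baseline by `margin_db`; vessel engine noise concentrates
#' below 300 Hz. The baseline is the rolling median over `baseline_s`
#' seconds (the whole scene when shorter).
#'
#' @param mid_ltsa mid-frequency `ltsa` from [compute_mid_ltsa()].
#' @param margin_db required elevation over the baseline, dB.
#' @param f_max upper edge of the vessel band, Hz.
#' @param baseline_s rolling-baseline window, s.
#' @param gap_s merge tolerance between flagged bins, s.
#' @return data.frame encounter intervals (`signal_class` = `"vessel"`).
#' @export
detect_vessel <- function(mid_ltsa, margin_db = 6, f_max = 300,
                          baseline_s = 600, gap_s = 10) {
  stopifnot(inherits(mid_ltsa, "ltsa"))
  sel <- mid_ltsa$freq > 0 & mid_ltsa$freq <= f_max
  if (!any(sel)) stop("mid-frequency LTSA does not cover the vessel band")
  band_db <- apply(mid_ltsa$level[sel, , drop = FALSE], 2L, function(col)
    db_from_power(mean(power_from_db(col))))
  half <- max(1L, round(baseline_s / mid_ltsa$t_avg / 2))
  n <- length(band_db)
  base <- vapply(seq_len(n), function(j) {
    w <- max(1L, j - half):min(n, j + half)
    stats::median(band_db[w])
  }, numeric(1))
  flags <- band_db > base + margin_db
  .flags_to_intervals(flags, mid_ltsa$time, mid_ltsa$t_avg, gap_s, "vessel")
}

#' Detect and log all anthropogenic signal classes in a recording
#'
#' Convenience wrapper: computes the full-band and mid-frequency LTSAs
#' and runs the UA, echosounder, and vessel detectors, returning one
#' combined encounter log with UTC stamps.
#'
#' @param rec a [calibrated_recording].
#' @param t_avg,f_res full-band LTSA parameters (see [compute_ltsa()]).
#' @param mid_factor,mid_f_res mid-frequency LTSA parameters.
#' @param ... passed on to the individual detectors.
#' @return data.frame encounter log: `signal_class`, `start_s`, `end_s`,
#'   `start_utc`, `end_utc`.
#' @export
detect_anthro <- function(rec, t_avg = 5, f_res = 100, mid_factor = 20,
                          mid_f_res = 10, ...) {
  ltsa <- compute_ltsa(rec, t_avg = t_avg, f_res = f_res)
  mid <- compute_mid_ltsa(rec, factor = mid_factor, t_avg = t_avg,
                          f_res = mid_f_res)
  log <- rbind(detect_ua(ltsa, ...),
               detect_echosounder(ltsa),
               detect_vessel(mid))
  log$start_utc <- rec$t0 + log$start_s
  log$end_utc <- rec$t0 + log$end_s
  log[order(log$start_s), , drop = FALSE]
}
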