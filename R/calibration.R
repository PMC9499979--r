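#' Calibrated single-channel recording
#'
#' The universal audio container of the package: pressure samples in
#' micropascals, a sampling rate, a UTC start time, the peak pressure mapped
#' to 16-bit full scale when the recording is written to WAV, and a
#' frequency-dependent transfer function (system response) applied to
#' spectral quantities during analysis.
#'
#' The calibration model mirrors an autonomous seafloor recorder with a
#' hydrophone of flat sensitivity: the digitizer's full-scale count
#' corresponds to a known peak pressure (`full_scale_db`, dB re 1 uPa), and
#' residual frequency dependence of the measurement chain is captured by a
#' transfer function `tf` (data.frame: `freq_hz`, `gain_db`) whose gain is
#' subtracted from measured spectral levels. The default transfer function
#' is flat at 0 dB.
#'
#' @param samples numeric vector, instantaneous pressure in uPa.
#' @param sample_rate sampling rate in Hz (default 200 kHz, the native rate
#'   of high-frequency acoustic recording packages).
#' @param t0 recording start, POSIXct UTC (or a string parseable as such).
#' @param full_scale_db peak pressure at 16-bit full scale, dB re 1 uPa.
#'   The default (140 dB) places a 40 dB re 1 uPa^2/Hz instrument noise
#'   floor roughly 50 dB above the quantization noise density.
#' @param tf transfer function, data.frame with columns `freq_hz`,
#'   `gain_db`; linearly interpolated onto analysis frequencies (constant
#'   extrapolation at the ends).
#' @return object of class `calibrated_recording`.
#' @export
calibrated_recording <- function(samples, sample_rate = 200000,
                                 t0 = as.POSIXct("2019-01-01 00:00:00", tz = "UTC"),
                                 full_scale_db = 140,
                                 tf = NULL) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  sample_rate <- as.double(sample_rate)  # integer rates overflow in f-axis math
  if (is.character(t0)) t0 <- as.POSIXct(t0, tz = "UTC")
  if (is.null(tf)) tf <- data.frame(freq_hz = c(0, sample_rate / 2), gain_db = c(0, 0))
  stopifnot(all(c("freq_hz", "gain_db") %in% names(tf)))
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate, t0 = t0,
         full_scale_db = full_scale_db, tf = tf),
    class = "calibrated_recording"
  )
}

#' @export
print.calibrated_recording <- function(x, ...) {
  cat("<calibrated_recording>\n")
  cat(sprintf("  %d samples @ %g Hz (%.2f s), start %s UTC\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              format(x$t0, "%Y-%m-%d %H:%M:%S")))
  cat(sprintf("  full scale %.1f dB re 1 uPa; transfer function: %d points\n",
              x$full_scale_db, nrow(x$tf)))
  invisible(x)
}

#' @export
length.calibrated_recording <- function(x) length(x$samples)

# transfer-function gain (dB) interpolated at frequencies f (Hz)
.tf_gain <- function(rec, f) {
  tf <- rec$tf
  if (nrow(tf) == 1L) return(rep(tf$gain_db, length(f)))
  stats::approx(tf$freq_hz, tf$gain_db, xout = f, rule = 2)$y
}

#' Write and read mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for the single format this package produces:
#' mono, 16-bit signed PCM. Pressure samples are scaled so that
#' `full_scale_db` (dB re 1 uPa peak) maps to the 16-bit full-scale count;
#' samples beyond full scale are clipped with a warning. `read_wav` inverts
#' the mapping, so a write/read round trip reproduces pressures to within
#' one quantization step.
#'
#' @param rec a [calibrated_recording].
#' @param path file path.
#' @return `write_wav` returns `path` invisibly; `read_wav` returns a
#'   [calibrated_recording].
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "calibrated_recording"))
  fs_pa <- 10^(rec$full_scale_db / 20)
  x <- rec$samples / fs_pa
  if (any(abs(x) > 1)) {
    warning("samples exceed full scale; clipping")
    x <- pmax(-1, pmin(1, x))
  }
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  fs <- as.integer(round(rec$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @param t0,full_scale_db,tf calibration metadata to attach to the samples
#'   read back (WAV carries none); see [calibrated_recording()].
#' @export
read_wav <- function(path, t0 = as.POSIXct("2019-01-01 00:00:00", tz = "UTC"),
                     full_scale_db = 140, tf = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        channels     = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate  = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate    = readBin(con, integer(), size = 4, endian = "little"),
        block_align  = readBin(con, integer(), size = 2, endian = "little"),
        bits         = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk")
      if (fmt$audio_format != 1L || fmt$channels != 1L || fmt$bits != 16L)
        stop("only mono 16-bit PCM WAV is supported")
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      fs_pa <- 10^(full_scale_db / 20)
      return(calibrated_recording(pcm / 32767 * fs_pa,
                                  sample_rate = fmt$sample_rate, t0 = t0,
                                  full_scale_db = full_scale_db, tf = tf))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
  }
}

#' Read a transfer-function table
#'
#' Plain CSV with header columns `freq_hz` and `gain_db`.
#'
#' @param path CSV file path.
#' @return data.frame suitable for the `tf` slot of [calibrated_recording()].
#' @export
read_transfer_function <- function(path) {
  tf <- utils::read.csv(path)
  stopifnot(all(c("freq_hz", "gain_db") %in% names(tf)))
  tf[order(tf$freq_hz), c("freq_hz", "gain_db")]
}
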