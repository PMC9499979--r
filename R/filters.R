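# Internal filtering helpers. Coefficients come from signal's designs;
# the sample loop runs in compiled code so multi-hour recordings stay
# cheap.

# single-pass IIR filter (direct form II transposed)
.iir <- function(b, a, x) {
  .iir_filter_cpp(as.numeric(b) / a[1], as.numeric(a) / a[1], as.numeric(x))
}

# zero-phase forward-backward filtering
.zero_phase <- function(b, a, x) {
  y <- .iir(b, a, x)
  rev(.iir(b, a, rev(y)))
}

# centered moving average via cumulative sums; returns same length,
# edge values replicated from the first/last full window
.moving_avg <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n < w) return(x)
  cs <- cumsum(c(0, x))
  core <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
  lead <- w %/% 2L
  c(rep(core[1], lead), core, rep(core[length(core)], n - length(core) - lead))
}

# block mean + subsample: crude anti-aliased decimation whose passband
# (well below the output Nyquist) is essentially flat; used by the
# streaming pipeline for the low-frequency vessel band
.decimate_boxcar <- function(x, q) {
  n <- (length(x) %/% q) * q
  colMeans(matrix(x[seq_len(n)], nrow = q))
}

# FIR (polyphase) decimation, processed in fixed blocks with margins so
# the FFT-based filter never sees more than a few million samples at
# once; block results are exact except within one filter length of the
# very ends of each margin, which the margins absorb
.decimate_fir <- function(x, q, block = 4e6) {
  n <- length(x)
  if (n <= block) return(as.numeric(signal::decimate(x, q, ftype = "fir")))
  block <- (block %/% q) * q
  margin <- 64L * q
  starts <- seq(1, n, by = block)
  out <- lapply(starts, function(s) {
    a <- max(1, s - margin)
    b <- min(n, s + block - 1 + margin)
    y <- as.numeric(signal::decimate(x[a:b], q, ftype = "fir"))
    lead <- (s - a) / q              # margin is a multiple of q
    len <- ceiling(min(block, n - s + 1) / q)
    y[(lead + 1):(lead + len)]
  })
  unlist(out)
}

# median and MAD on a strided subsample (statistically equivalent on
# millions of samples, much cheaper than full sorts)
.robust_stats <- function(x, max_n = 2e6) {
  stride <- max(1L, length(x) %/% max_n)
  xs <- x[seq(1L, length(x), by = stride)]
  c(median = stats::median(xs), mad = stats::mad(xs))
}
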