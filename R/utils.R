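#' Decibel conversions
#'
#' Convert between linear power quantities and decibels. All soundscape
#' quantities in this package are referenced to 1 uPa^2 (band levels) or
#' 1 uPa^2/Hz (spectral densities); the conversion itself is
#' reference-agnostic.
#'
#' @param p linear power (e.g. mean-square pressure, uPa^2).
#' @param db level in decibels.
#' @param floor_db optional clamp: linear values whose dB level falls below
#'   this are reported at `floor_db` (used to mirror an instrument self-noise
#'   floor; zero power maps to the floor instead of -Inf).
#' @return numeric vector.
#' @export
db_from_power <- function(p, floor_db = NULL) {
  db <- 10 * log10(pmax(p, .Machine$double.xmin))
  if (!is.null(floor_db)) db <- pmax(db, floor_db)
  db
}

#' @rdname db_from_power
#' @export
power_from_db <- function(db) 10^(db / 10)

# half-open interval [start, end) overlap with [lo, hi)
.overlaps <- function(start, end, lo, hi) start < hi & end > lo

#' Merge overlapping or near-adjacent intervals
#'
#' Used by the anthropogenic-signal detectors to turn flagged time bins into
#' encounter intervals, and by presence logging to merge adjacent positive
#' segments. Intervals are half-open `[start, end)`.
#'
#' @param start,end numeric vectors of interval bounds (seconds).
#' @param gap gaps of at most `gap` seconds between consecutive intervals are
#'   bridged (0 merges only touching/overlapping intervals).
#' @return data.frame with columns `start`, `end`, time-sorted and disjoint.
#' @export
merge_intervals <- function(start, end, gap = 0) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  if (any(end <= start)) stop("intervals must satisfy end > start")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  for (i in seq_along(start)[-1]) {
    k <- length(out_s)
    if (start[i] <= out_e[k] + gap) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# total time covered by a set of (possibly overlapping) intervals clipped
# to [lo, hi)
.covered_time <- function(start, end, lo, hi) {
  if (length(start) == 0L) return(0)
  m <- merge_intervals(pmax(start, lo), pmin(end, hi))
  keep <- m$end > m$start
  sum(m$end[keep] - m$start[keep])
}

# quadratic (parabolic) interpolation of a spectral peak; returns fractional
# bin offset in [-0.5, 0.5] around index i of magnitude vector m
.parab_offset <- function(m, i) {
  if (i <= 1L || i >= length(m)) return(0)
  a <- m[i - 1L]; b <- m[i]; c <- m[i + 1L]
  den <- a - 2 * b + c
  if (den == 0) return(0)
  max(-0.5, min(0.5, 0.5 * (a - c) / den))
}
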