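#' Specify a synthetic acoustic scene
#'
#' A `scene_spec` fully determines a synthetic monitoring scene: duration,
#' sampling rate, ambient noise floor, an event list, and a seed. Two
#' renders of the same spec are bit-identical. Event timing jitter is
#' drawn from the seed before any noise, so the ground-truth log does not
#' depend on the noise realisation.
#'
#' @param duration scene length, seconds.
#' @param sample_rate sampling rate, Hz (default 200 kHz).
#' @param events list of [scene_event()] entries.
#' @param noise_floor_db ambient/instrument noise floor as a flat power
#'   spectral density, dB re 1 uPa^2/Hz (default 40, emulating recorder
#'   electronic self-noise).
#' @param seed integer seed; fully determines the rendered samples.
#' @param t0 UTC start time of the scene.
#' @param full_scale_db 16-bit full-scale peak pressure, dB re 1 uPa.
#' @param disk_write if `TRUE`, a broadband disk-write noise artifact is
#'   inserted for 15 s at the start of every 75-s cycle, emulating the
#'   recorder's periodic disk activity.
#' @param disk_write_offset_db disk-write artifact level above the noise
#'   floor, dB.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(duration, sample_rate = 200000, events = list(),
                       noise_floor_db = 40, seed = 1,
                       t0 = as.POSIXct("2019-01-01 00:00:00", tz = "UTC"),
                       full_scale_db = 140,
                       disk_write = FALSE, disk_write_offset_db = 20) {
  stopifnot(duration > 0, sample_rate > 0)
  if (is.character(t0)) t0 <- as.POSIXct(t0, tz = "UTC")
  for (ev in events) {
    if (!inherits(ev, "scene_event")) stop("events must be scene_event objects")
    if (ev$start < 0 || ev$start >= duration)
      stop("event start times must lie within [0, duration)")
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 events = events, noise_floor_db = noise_floor_db,
                 seed = as.integer(seed), t0 = t0,
                 full_scale_db = full_scale_db, disk_write = disk_write,
                 disk_write_offset_db = disk_write_offset_db),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param template a [source_template][template_cuvier] for the event.
#' @param start event start time, seconds from scene start.
#' @param n for pulsed sources (clicks, pings): number of emissions in
#'   the train.
#' @param ipi inter-pulse interval range `c(min, max)` in seconds,
#'   overriding the template default; gaps are drawn uniformly.
#' @param on_duration for continuous sources (`ua_comb`,
#'   `vessel_lowfreq`): on-time of the source, seconds.
#' @export
scene_event <- function(template, start, n = 1, ipi = NULL,
                        on_duration = NULL) {
  stopifnot(inherits(template, "source_template"))
  continuous <- template$kind %in% c("ua_comb", "vessel_lowfreq")
  if (continuous && is.null(on_duration))
    stop("continuous sources need on_duration")
  structure(list(template = template, start = start, n = n,
                 ipi = ipi, on_duration = on_duration,
                 continuous = continuous),
            class = "scene_event")
}

# snippet length (s) of a single emission of a pulsed template
.pulse_duration <- function(template) {
  switch(template$kind,
    cuvier_fm = , delphinid = template$duration * .fm_support_factor,
    echosounder_28 = , echosounder_50 = 8 / (2 * pi * template$sigma_f),
    stop("not a pulsed template"))
}

.chunk_len <- 75  # scene render granularity, s (matches the segment cycle)

# Draw all event timing from the scene seed and derive per-chunk noise
# seeds. Returns emissions table + seeds; called once per scene.
.prepare_scene <- function(spec) {
  set.seed(spec$seed)
  rows <- list()
  event_seeds <- integer(length(spec$events))
  for (i in seq_along(spec$events)) {
    ev <- spec$events[[i]]
    tpl <- ev$template
    event_seeds[i] <- sample.int(.Machine$integer.max - 1L, 1L)
    if (ev$continuous) {
      rows[[i]] <- data.frame(event_id = i, class = tpl$kind,
                              start = ev$start,
                              end = min(ev$start + ev$on_duration, spec$duration))
    } else {
      ipi <- if (!is.null(ev$ipi)) ev$ipi else tpl$ipi
      gaps <- if (ev$n > 1) stats::runif(ev$n - 1, ipi[1], ipi[2]) else numeric(0)
      starts <- ev$start + cumsum(c(0, gaps))
      pd <- .pulse_duration(tpl)
      keep <- starts + pd <= spec$duration
      rows[[i]] <- data.frame(event_id = i, class = tpl$kind,
                              start = starts[keep], end = starts[keep] + pd)
    }
  }
  n_chunks <- ceiling(spec$duration / .chunk_len)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L, n_chunks)
  emissions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(0), class = character(0),
               start = numeric(0), end = numeric(0))
  list(emissions = emissions, event_seeds = event_seeds,
       chunk_seeds = chunk_seeds, n_chunks = n_chunks)
}

#' Ground-truth event log of a scene
#'
#' Enumerates every emitted event of a [scene_spec()]: one row per pulse
#' for pulsed sources, one row per on-span for continuous sources, plus
#' rows for disk-write artifacts when enabled. Determined entirely by the
#' spec (noise-independent).
#'
#' @param spec a [scene_spec()].
#' @return data.frame with columns `class`, `start_s`, `end_s`,
#'   `start_utc`, `end_utc`; intervals are half-open `[start, end)`.
#' @export
ground_truth <- function(spec) {
  prep <- .prepare_scene(spec)
  em <- prep$emissions
  truth <- data.frame(class = em$class, start_s = em$start, end_s = em$end)
  if (spec$disk_write) {
    k <- 0:(prep$n_chunks - 1)
    dw <- data.frame(class = "disk_write", start_s = k * .chunk_len,
                     end_s = pmin(k * .chunk_len + 15, spec$duration))
    truth <- rbind(truth, dw[dw$end_s > dw$start_s, ])
  }
  truth <- truth[order(truth$start_s), , drop = FALSE]
  truth$start_utc <- spec$t0 + truth$start_s
  truth$end_utc <- spec$t0 + truth$end_s
  rownames(truth) <- NULL
  truth
}

# render one chunk [k*75, ...) fully; k is 1-based chunk index
.render_chunk <- function(spec, prep, k) {
  fs <- spec$sample_rate
  from <- (k - 1) * .chunk_len
  to <- min(k * .chunk_len, spec$duration)
  n <- round((to - from) * fs)
  set.seed(prep$chunk_seeds[k])
  sigma <- sqrt(power_from_db(spec$noise_floor_db) * fs / 2)
  x <- stats::rnorm(n, sd = sigma)
  if (spec$disk_write) {
    dw_end <- min(from + 15, to)
    n_dw <- round((dw_end - from) * fs)
    if (n_dw > 0) {
      extra <- power_from_db(spec$noise_floor_db + spec$disk_write_offset_db) -
        power_from_db(spec$noise_floor_db)
      x[seq_len(n_dw)] <- x[seq_len(n_dw)] +
        stats::rnorm(n_dw, sd = sqrt(extra * fs / 2))
    }
  }
  em <- prep$emissions
  hit <- which(em$start < to & em$end > from)
  for (j in hit) {
    ev <- spec$events[[em$event_id[j]]]
    tpl <- ev$template
    if (tpl$kind == "ua_comb") {
      x <- x + .render_comb(tpl, fs, t_on = em$start[j], t_off = em$end[j],
                            from = from, to = to)
    } else if (tpl$kind == "vessel_lowfreq") {
      v <- .render_vessel(tpl, fs, prep$event_seeds[em$event_id[j]], k, n)
      t_idx <- from + (seq_len(n) - 1) / fs
      v[t_idx < em$start[j] | t_idx >= em$end[j]] <- 0
      x <- x + v
    } else {
      snip <- if (tpl$kind %in% c("echosounder_28", "echosounder_50"))
        make_ping(tpl, fs) else make_fm_pulse(tpl, fs)
      i0 <- round((em$start[j] - from) * fs)  # may be negative
      src <- seq_along(snip)
      dst <- i0 + src
      keep <- dst >= 1L & dst <= n
      x[dst[keep]] <- x[dst[keep]] + snip[src[keep]]
    }
  }
  x
}

#' Render a time window of a scene
#'
#' Renders samples for `[from, to)` seconds of the scene. Rendering is
#' chunked internally on a fixed 75-s grid, so any window of the same
#' spec returns exactly the samples the full scene would contain there —
#' this is what allows long scenes to be processed in streaming fashion
#' without materialising them.
#'
#' @param spec a [scene_spec()].
#' @param from,to window bounds in seconds (defaults: whole scene).
#' @return numeric vector of pressure samples (uPa).
#' @export
render_scene_window <- function(spec, from = 0, to = spec$duration) {
  stopifnot(from >= 0, to <= spec$duration, to > from)
  prep <- .prepare_scene(spec)
  .render_window(spec, prep, from, to)
}

.render_window <- function(spec, prep, from, to) {
  fs <- spec$sample_rate
  k0 <- floor(from / .chunk_len) + 1L
  k1 <- ceiling(to / .chunk_len)
  pieces <- lapply(k0:k1, function(k) .render_chunk(spec, prep, k))
  x <- do.call(c, pieces)
  off <- round((from - (k0 - 1) * .chunk_len) * fs)
  x[(off + 1):(off + round((to - from) * fs))]
}

#' Assemble a synthetic scene into a calibrated recording
#'
#' Renders the full scene (scaled event waveforms plus Gaussian noise
#' shaped to the configured floor) and returns it together with its
#' ground-truth log. If any sample exceeds 16-bit full scale the whole
#' scene is rescaled to 95% of full scale with a warning, and the factor
#' is recorded in the result.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `recording` (a [calibrated_recording]),
#'   `truth` (see [ground_truth()]) and `rescale_factor` (1 when no
#'   rescaling was needed).
#' @export
assemble_scene <- function(spec) {
  prep <- .prepare_scene(spec)
  x <- .render_window(spec, prep, 0, spec$duration)
  fs_pa <- 10^(spec$full_scale_db / 20)
  rescale <- 1
  peak <- max(abs(x))
  if (peak > fs_pa) {
    rescale <- 0.95 * fs_pa / peak
    warning(sprintf(
      "scene peak %.1f dB re 1 uPa exceeds full scale (%.1f dB); rescaled by %.3g",
      20 * log10(peak), spec$full_scale_db, rescale))
    x <- x * rescale
  }
  rec <- calibrated_recording(x, sample_rate = spec$sample_rate, t0 = spec$t0,
                              full_scale_db = spec$full_scale_db)
  list(recording = rec, truth = ground_truth(spec), rescale_factor = rescale)
}

#' Write a ground-truth log to CSV
#'
#' @param truth a [ground_truth()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$start_utc <- format(out$start_utc, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  out$end_utc <- format(out$end_utc, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
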