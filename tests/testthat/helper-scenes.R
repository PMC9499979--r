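# Shared fixtures, built in code. Scenes are kept short and most use a
# 100 kHz rate to keep the suite quick; frequency content of all
# templates fits comfortably below that Nyquist.

FS_FULL <- 200000   # native recorder rate
FS_TEST <- 100000   # cheap rate for scene-level tests

quiet_scene <- function(duration = 30, fs = FS_TEST, seed = 1, ...) {
  scene_spec(duration = duration, sample_rate = fs, seed = seed, ...)
}

click_train_scene <- function(n = 10, start = 5, ipi = c(0.45, 0.45),
                              duration = 30, fs = FS_TEST, seed = 1,
                              level = 120) {
  scene_spec(duration = duration, sample_rate = fs, seed = seed,
             events = list(scene_event(template_cuvier(level = level),
                                       start, n = n, ipi = ipi)))
}

# brute-force re-application of the segment rules, independent of
# classify_segments(): operates on a plain candidate table
oracle_segment_labels <- function(cand, total_duration, cfg) {
  n_seg <- max(1, ceiling(total_duration / cfg$segment_len))
  sapply(seq_len(n_seg), function(i) {
    lo <- (i - 1) * cfg$segment_len
    hi <- min(lo + cfg$segment_len, total_duration)
    rows <- cand[cand$time >= lo & cand$time < hi, , drop = FALSE]
    nd <- nrow(rows)
    if (nd <= cfg$min_detections) return("insufficient")
    del <- (rows$peak_freq < cfg$peak_freq_min) &
      (rows$center_freq < cfg$center_freq_min) &
      (rows$duration < cfg$duration_min) &
      (rows$sweep_rate < cfg$sweep_rate_min)
    if (cfg$deletion_logic == "disjunctive")
      del <- (rows$peak_freq < cfg$peak_freq_min) |
        (rows$center_freq < cfg$center_freq_min) |
        (rows$duration < cfg$duration_min) |
        (rows$sweep_rate < cfg$sweep_rate_min)
    if (sum(!del) / nd > cfg$retained_fraction_min) "beaked_whale"
    else "not_beaked_whale"
  })
}

# random candidate table generator for property tests
random_candidates <- function(n, tmax = 75) {
  data.frame(time = sort(stats::runif(n, 0, tmax)),
             peak_freq = stats::runif(n, 15000, 60000),
             center_freq = stats::runif(n, 12000, 45000),
             duration = stats::runif(n, 50e-6, 900e-6),
             sweep_rate = stats::runif(n, 0, 50e6),
             tk_score = stats::rexp(n, 1 / 50))
}
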