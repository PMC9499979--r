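# Teager-Kaiser detection, feature extraction, deletion criteria and
# segment classification.

test_that("TK operator matches its closed form on constants and sinusoids", {
  psi <- tk_energy(rep(3.7, 100))
  expect_true(all(psi[2:99] == 0))
  expect_equal(psi[c(1, 100)], c(0, 0))
  # sinusoid: psi = A^2 sin^2(Omega), constant over interior samples
  for (A in c(0.5, 2)) {
    for (Om in c(0.1, 0.8, 2)) {
      x <- A * cos(Om * (0:499) + 0.3)
      psi <- tk_energy(x)[3:497]
      expect_equal(psi, rep(A^2 * sin(Om)^2, length(psi)), tolerance = 1e-10)
    }
  }
  expect_error(tk_energy(c(1, 2)), "at least 3")
})

test_that("a lone click is detected at its true time; silence yields none", {
  sp <- click_train_scene(n = 1, start = 3.2, duration = 10, seed = 21)
  rec <- assemble_scene(sp)$recording
  cand <- detect_candidates(rec)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$time - 3.2), 1e-3)
  silent <- assemble_scene(quiet_scene(duration = 10, seed = 22))$recording
  expect_equal(nrow(detect_candidates(silent)), 0L)
  expect_error(detect_candidates(calibrated_recording(rnorm(100), 20000)),
               "sample rate")
})

test_that("trains and confusers are all found before deletion", {
  ev <- list(scene_event(template_cuvier(), 5, n = 10, ipi = c(0.45, 0.45)),
             scene_event(template_delphinid(), 15, n = 5, ipi = c(0.3, 0.3)))
  sp <- scene_spec(duration = 30, sample_rate = FS_TEST, seed = 23,
                   events = ev)
  rec <- assemble_scene(sp)$recording
  cand <- detect_candidates(rec)
  expect_equal(nrow(cand), 15L)
  kept <- apply_deletion_criteria(cand)
  expect_equal(nrow(kept), 10L)   # delphinid confusers deleted
  expect_true(all(kept$time < 15))
})

test_that("feature extraction matches constructions", {
  fs <- FS_FULL
  # unmodulated tone burst: zero sweep, correct peak
  t <- (0:(fs * 1e-3)) / fs
  burst <- sin(2 * pi * 50000 * t) * exp(-0.5 * ((t - 5e-4) / 2e-4)^2)
  fe <- extract_features(burst, fs)
  expect_lt(abs(fe[["sweep_rate"]]), 2e6)
  expect_lt(abs(fe[["peak_freq"]] - 50000), 500)
  # constructed chirp 25 -> 45 kHz over 800 us: 25 kHz/ms
  tpl <- template_cuvier(duration = 800e-6, peak_freq = 35000,
                         sweep_rate = 25e6, secondary_peaks = numeric(0),
                         secondary_rel_db = numeric(0))
  fe2 <- extract_features(make_fm_pulse(tpl, fs), fs)
  expect_lt(abs(fe2[["sweep_rate"]] - 25e6) / 25e6, 0.10)
  expect_error(extract_features(numeric(256), fs), "all-zero")
})

test_that("deletion criteria follow the configured logic over all 16 feature corners", {
  cfg_c <- classifier_config(deletion_logic = "conjunctive")
  cfg_d <- classifier_config(deletion_logic = "disjunctive")
  lo <- list(peak_freq = 20000, center_freq = 18000,
             duration = 100e-6, sweep_rate = 5e6)
  hi <- list(peak_freq = 40000, center_freq = 33000,
             duration = 500e-6, sweep_rate = 30e6)
  corners <- expand.grid(p = c(TRUE, FALSE), c = c(TRUE, FALSE),
                         d = c(TRUE, FALSE), s = c(TRUE, FALSE))
  for (i in seq_len(nrow(corners))) {
    below <- unlist(corners[i, ])
    cand <- data.frame(time = 1,
                       peak_freq = if (below[1]) lo$peak_freq else hi$peak_freq,
                       center_freq = if (below[2]) lo$center_freq else hi$center_freq,
                       duration = if (below[3]) lo$duration else hi$duration,
                       sweep_rate = if (below[4]) lo$sweep_rate else hi$sweep_rate)
    expect_equal(nrow(apply_deletion_criteria(cand, cfg_c)),
                 as.integer(!all(below)))
    expect_equal(nrow(apply_deletion_criteria(cand, cfg_d)),
                 as.integer(!any(below)))
  }
})

test_that("threshold comparisons are strict: a feature at the cutoff never deletes", {
  cfg <- classifier_config(deletion_logic = "conjunctive")
  base <- data.frame(time = 1, peak_freq = 20000, center_freq = 18000,
                     duration = 100e-6, sweep_rate = 5e6)
  expect_equal(nrow(apply_deletion_criteria(base, cfg)), 0L)
  for (f in c("peak_freq", "center_freq", "duration", "sweep_rate")) {
    at <- base
    at[[f]] <- cfg[[paste0(f, "_min")]]
    expect_equal(nrow(apply_deletion_criteria(at, cfg)), 1L)
    eps <- at
    eps[[f]] <- cfg[[paste0(f, "_min")]] * (1 - 1e-9)
    expect_equal(nrow(apply_deletion_criteria(eps, cfg)), 0L)
  }
})

test_that("segment rules honour the exclusive count and fraction thresholds", {
  mk <- function(nd, nr) {
    # nr retained (all features high), nd - nr deleted (all low)
    data.frame(time = seq(1, 70, length.out = nd),
               peak_freq = c(rep(40000, nr), rep(20000, nd - nr)),
               center_freq = c(rep(33000, nr), rep(18000, nd - nr)),
               duration = c(rep(500e-6, nr), rep(100e-6, nd - nr)),
               sweep_rate = c(rep(30e6, nr), rep(5e6, nd - nr)))
  }
  expect_equal(classify_segments(mk(7, 7), 75)$label, "insufficient")
  expect_equal(classify_segments(mk(8, 8), 75)$label, "beaked_whale")
  expect_equal(classify_segments(mk(100, 13), 75)$label, "not_beaked_whale")
  expect_equal(classify_segments(mk(100, 14), 75)$label, "beaked_whale")
  seg <- classify_segments(mk(100, 14), 75)
  expect_equal(seg$n_detected, 100L)
  expect_equal(seg$n_retained, 14L)
  expect_equal(seg$fraction_retained, 0.14)
})

test_that("segment labels match a brute-force oracle on random candidate tables", {
  set.seed(77)
  cfgs <- list(classifier_config(),
               classifier_config(deletion_logic = "disjunctive"))
  for (i in 1:100) {
    cand <- random_candidates(sample(0:40, 1), tmax = 150)
    cfg <- cfgs[[1 + i %% 2]]
    got <- classify_segments(cand, 150, cfg)$label
    expect_identical(got, oracle_segment_labels(cand, 150, cfg))
  }
})

test_that("presence logging merges adjacent positive segments and bins correctly", {
  t0 <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC")
  seg <- data.frame(start = (0:47) * 75, end = (1:48) * 75,
                    n_detected = 0, n_retained = 0, fraction_retained = NA,
                    label = "insufficient")
  seg$label[5:8] <- "beaked_whale"   # 300..600 s
  log <- log_bw_presence(seg, t0 = t0)
  expect_equal(nrow(log), 1L)
  expect_equal(log$end_s - log$start_s, 300)
  cov <- data.frame(start_utc = t0, end_utc = t0 + 3600)
  hr <- hourly_assemble(log, NULL, cov)
  expect_equal(hr$bw_minutes, 5L)    # 300 s = 5 one-minute bins
  # no positives
  seg0 <- seg; seg0$label <- "insufficient"
  expect_equal(nrow(log_bw_presence(seg0, t0 = t0)), 0L)
  # overlapping segments are rejected
  bad <- seg[1:2, ]; bad$start[2] <- 10
  expect_error(log_bw_presence(bad, t0 = t0), "overlap")
  # positives in two different UTC hours give two hourly rows
  seg2 <- data.frame(start = (0:95) * 75, end = (1:96) * 75,
                     n_detected = 0, n_retained = 0, fraction_retained = NA,
                     label = "insufficient")
  seg2$label[c(10, 60)] <- "beaked_whale"   # hours 10:xx and 11:xx
  log2 <- log_bw_presence(seg2, t0 = t0)
  hr2 <- hourly_assemble(log2, NULL,
                         data.frame(start_utc = t0, end_utc = t0 + 7200))
  expect_equal(nrow(hr2), 2L)
  expect_true(all(hr2$bw_minutes > 0))
})

test_that("presence summaries bin minutes, hours and ISO weeks consistently", {
  t0 <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC")  # Saturday, week 22
  log <- data.frame(signal_class = "beaked_whale",
                    start_s = NA, end_s = NA,
                    start_utc = c(t0 + 120, t0 + 9 * 86400),
                    end_utc = c(t0 + 420, t0 + 9 * 86400 + 60))
  ps <- presence_summary(log)
  # first encounter: 10:02-10:07 -> 5 minute bins in one hour
  expect_equal(ps$hourly$minutes[1], 5L)
  expect_equal(nrow(ps$minutes), 6L)
  expect_equal(ps$weekly$hours, c(1L, 1L))
  expect_equal(ps$weekly$week, c("2019-W22", "2019-W24"))
  # minute sums conserve into hours
  expect_equal(sum(ps$hourly$minutes), nrow(ps$minutes))
  # empty log
  expect_equal(nrow(presence_summary(NULL)$weekly), 0L)
})
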