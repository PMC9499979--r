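# Synthetic source waveforms and scene assembly.

test_that("default Cuvier FM pulse has the nominal spectral and temporal features", {
  x <- make_fm_pulse(template_cuvier(), FS_FULL)
  fe <- extract_features(x, FS_FULL)
  expect_lt(abs(fe[["peak_freq"]] - 40000), 1000)
  expect_lt(abs(fe[["duration"]] - 450e-6) / 450e-6, 0.10)
  expect_lt(abs(fe[["sweep_rate"]] - 30e6) / 30e6, 0.10)
  # characteristic secondary spectral peaks near 17 and 23 kHz
  pk <- spectral_peaks(x, FS_FULL, band = c(10000, 30000), min_rel_db = 10)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$freq_hz[1] - 17000), 1000)
  expect_lt(abs(pk$freq_hz[2] - 23000), 1000)
  # received level honoured
  expect_equal(20 * log10(sqrt(mean(x^2))), 120, tolerance = 1e-6)
})

test_that("FM pulse synthesis rejects degenerate and aliased templates", {
  expect_error(make_fm_pulse(template_cuvier(duration = 0), FS_FULL),
               "duration")
  # sweeping past Nyquist at a low rate must be refused
  expect_error(make_fm_pulse(template_cuvier(), 80000), "Nyquist")
  expect_error(make_fm_pulse(template_echosounder("28"), FS_FULL), "kind")
})

test_that("custom chirp sweep rates are recovered within 10%", {
  tpl <- template_cuvier(duration = 500e-6, peak_freq = 40000,
                         sweep_rate = 30e6)
  fe <- extract_features(make_fm_pulse(tpl, FS_FULL), FS_FULL)
  expect_gte(fe[["sweep_rate"]], 27e6)
  expect_lte(fe[["sweep_rate"]], 33e6)
})

test_that("echosounder pings are narrowband at their class frequencies", {
  p28 <- make_ping(template_echosounder("28"), FS_FULL)
  pk <- spectral_peaks(p28, FS_FULL, band = c(20000, 60000))
  expect_lt(abs(pk$freq_hz[which.max(pk$level_db)] - 28800), 100)
  # >= 95% of energy inside the stated band, both classes
  band_frac <- function(x, lo, hi) {
    nfft <- 2^18
    m2 <- Mod(stats::fft(c(x, numeric(nfft - length(x))))[1:(nfft / 2)])^2
    f <- (0:(nfft / 2 - 1)) * FS_FULL / nfft
    sum(m2[f >= lo & f <= hi]) / sum(m2)
  }
  expect_gte(band_frac(p28, 27000, 31000), 0.95)
  p50 <- make_ping(template_echosounder("50"), FS_FULL)
  expect_gte(band_frac(p50, 49000, 51000), 0.95)
  expect_error(make_ping(template_echosounder("50"), 60000), "Nyquist")
})

test_that("UA comb presets span the reported frequency ranges", {
  fs <- 200000
  x <- make_ua_comb(template_ua_comb("anchored"), fs, 0.5)
  pk <- spectral_peaks(x, fs, band = c(5000, 95000), smooth_hz = 300,
                       min_rel_db = 15)
  expect_lt(abs(min(pk$freq_hz) - 19000), 500)   # lowest component ~19 kHz
  expect_gt(max(pk$freq_hz), 40000)              # anchored: up to ~42 kHz
  expect_lt(max(pk$freq_hz), 43000)
  xt <- make_ua_comb(template_ua_comb("transiting"), fs, 0.5)
  pkt <- spectral_peaks(xt, fs, band = c(5000, 95000), smooth_hz = 300,
                        min_rel_db = 15)
  expect_gt(max(pkt$freq_hz), 85000)             # transiting: up to ~88 kHz
  expect_error(template_ua_comb(freqs = numeric(0)), "at least one")
  expect_error(template_ua_comb(freqs = 500), ">= 1 kHz")
  expect_error(make_ua_comb(template_ua_comb("transiting"), 100000, 0.5),
               "Nyquist")
})

test_that("a single continuous comb component matches the analytic sinusoid PSD", {
  # one tone at 19.4 kHz, received level L: the 19.3-19.5 kHz 200-Hz proxy
  # bin reads L - 10*log10(200) because the tone's power lands in a
  # single 1-Hz bin of a 200-bin average
  L <- 100
  tpl <- template_ua_comb(freqs = 19400, level = L,
                          pulse_duration = 1, pulse_interval = 1)
  sp <- scene_spec(duration = 60, sample_rate = FS_TEST, seed = 2,
                   noise_floor_db = 40,
                   events = list(scene_event(tpl, 0, on_duration = 60)))
  rec <- assemble_scene(sp)$recording
  cfg <- soundscape_config(FS_TEST)
  px <- proxy_bin_levels(welch_psd(rec, cfg), cfg)
  expect_lt(abs(px$proxy_ua_db[1] - (L - 10 * log10(200))), 1)
})

test_that("scene rendering is deterministic and window-consistent", {
  sp <- click_train_scene(duration = 10, seed = 99)
  a <- assemble_scene(sp)
  b <- assemble_scene(sp)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  w <- render_scene_window(sp, 4, 6)
  expect_identical(w, a$recording$samples[(4 * FS_TEST + 1):(6 * FS_TEST)])
})

test_that("ground truth enumerates every emission with the scheduled spacing", {
  sp <- click_train_scene(n = 10, start = 5, ipi = c(0.45, 0.45),
                          duration = 30)
  tr <- ground_truth(sp)
  expect_equal(nrow(tr), 10L)
  expect_equal(max(tr$start_s) - min(tr$start_s), 4.05, tolerance = 1e-9)
  expect_true(all(tr$start_s >= 0 & tr$end_s <= sp$duration))
  # jittered IPIs stay inside the template range
  sp2 <- click_train_scene(n = 50, start = 1, ipi = c(0.4, 0.5),
                           duration = 40, seed = 3)
  gaps <- diff(ground_truth(sp2)$start_s)
  expect_true(all(gaps >= 0.4 - 1e-9 & gaps <= 0.5 + 1e-9))
})

test_that("silent scenes sit flat at the configured noise floor", {
  sp <- quiet_scene(duration = 60, fs = FS_FULL, seed = 8)
  rec <- assemble_scene(sp)$recording
  cfg <- soundscape_config(FS_FULL)
  cp <- coarse_psd(welch_psd(rec, cfg), cfg)
  sel <- cp$freq >= 1000 & cp$freq <= 90000
  expect_true(all(abs(cp$psd_db[sel, 1] - 40) < 1))
})

test_that("scenes that clip full scale are rescaled with a warning", {
  loud <- template_cuvier(level = 145)  # above the 140 dB full scale
  sp <- scene_spec(duration = 2, sample_rate = FS_TEST, seed = 1,
                   events = list(scene_event(loud, 0.5)))
  expect_warning(out <- assemble_scene(sp), "full scale")
  expect_lt(out$rescale_factor, 1)
  expect_lte(max(abs(out$recording$samples)), 10^(140 / 20))
})

test_that("disk-write artifacts appear on the 75-s cycle and in the truth log", {
  sp <- quiet_scene(duration = 160, seed = 4, disk_write = TRUE)
  tr <- ground_truth(sp)
  dw <- tr[tr$class == "disk_write", ]
  expect_equal(dw$start_s, c(0, 75, 150))
  expect_equal(dw$end_s, c(15, 90, 160))
  # artifact is hot: mean square during burst >> floor
  x <- render_scene_window(sp, 0, 30)
  p_on <- mean(x[1:(14 * FS_TEST)]^2)
  p_off <- mean(x[(16 * FS_TEST):(29 * FS_TEST)]^2)
  expect_gt(10 * log10(p_on / p_off), 15)
})

test_that("scene specs can be built from a nested YAML config", {
  skip_if_not_installed("yaml")
  cfg <- list(duration = 30, sample_rate = 100000, seed = 9,
              noise_floor_db = 45,
              events = list(
                list(template = "cuvier", start = 5, n = 8,
                     ipi = c(0.45, 0.45)),
                list(template = "ua_comb", preset = "anchored", level = 90,
                     start = 10, on_duration = 10)))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  sp <- scene_from_config(path)
  expect_s3_class(sp, "scene_spec")
  expect_equal(sp$duration, 30)
  expect_equal(sp$noise_floor_db, 45)
  expect_equal(length(sp$events), 2L)
  expect_equal(sp$events[[2]]$template$level, 90)
  tr <- ground_truth(sp)
  expect_equal(sum(tr$class == "cuvier_fm"), 8L)
  expect_error(scene_from_config(list(duration = 10, events = list(
    list(template = "kazoo", start = 1)))), "unknown template")
})
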