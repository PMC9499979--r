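# Welch PSD, per-minute medians, third-octave levels, proxy bands.

test_that("a calibrated sinusoid integrates to its mean-square level (Parseval)", {
  fs <- FS_FULL
  L <- 110   # dB re 1 uPa RMS
  A <- sqrt(2) * 10^(L / 20)
  t <- (0:(fs * 5 - 1)) / fs
  rec <- calibrated_recording(A * sin(2 * pi * 1000 * t), fs)
  cfg <- soundscape_config(fs)
  fr <- welch_psd(rec, cfg)
  i0 <- which.min(abs(fr$freq - 1000))
  nb <- (i0 - 3):(i0 + 3)
  tot <- db_from_power(sum(rowMeans(fr$power[nb, , drop = FALSE])))
  expect_lt(abs(tot - L), 0.5)
})

test_that("white noise frames report the generating density", {
  sp <- quiet_scene(duration = 60, fs = FS_FULL, seed = 61,
                    noise_floor_db = 70)
  rec <- assemble_scene(sp)$recording
  cfg <- soundscape_config(FS_FULL, floor_db = 0)
  fr <- welch_psd(rec, cfg)
  sel <- fr$freq >= 1000 & fr$freq <= 90000
  per_frame <- db_from_power(colMeans(fr$power[sel, ]))
  expect_true(all(abs(per_frame - 70) < 1))
  # zero signal: clamped at the configured floor, no error
  z <- calibrated_recording(numeric(FS_FULL * 2), FS_FULL)
  mz <- minute_median(welch_psd(z, soundscape_config(FS_FULL)),
                      soundscape_config(FS_FULL))
  expect_true(all(mz$psd_db == 40 | is.na(mz$psd_db)))
})

test_that("short segments yield zero frames, flagged", {
  rec <- calibrated_recording(rnorm(1000), FS_FULL)
  fr <- welch_psd(rec, soundscape_config(FS_FULL))
  expect_equal(length(fr$time), 0L)
})

test_that("the per-minute median follows the coverage and median rules", {
  mk_frames <- function(powers_db, excluded) {
    structure(list(freq = 0:10,
                   power = matrix(rep(power_from_db(powers_db),
                                      each = 11), nrow = 11),
                   time = seq_along(powers_db) - 1,
                   excluded = excluded,
                   t0 = as.POSIXct("2019-01-01 00:00:00", tz = "UTC"),
                   frame_s = 1),
              class = "psd_frames")
  }
  cfg <- soundscape_config(floor_db = 0)
  # 60 frames with 45 excluded -> 15 usable < 30 -> missing
  fr <- mk_frames(rep(80, 60), c(rep(TRUE, 45), rep(FALSE, 15)))
  expect_true(all(is.na(minute_median(fr, cfg)$psd_db)))
  # constant frames -> median equals the constant
  fr2 <- mk_frames(rep(83, 60), rep(FALSE, 60))
  expect_equal(unique(as.vector(minute_median(fr2, cfg)$psd_db)), 83)
  # 31 usable frames alternating two levels -> the more frequent level
  lv <- c(rep(90, 16), rep(70, 15), rep(60, 29))
  fr3 <- mk_frames(lv, c(rep(FALSE, 31), rep(TRUE, 29)))
  expect_equal(unique(as.vector(minute_median(fr3, cfg)$psd_db)), 90)
})

test_that("the third-octave machinery has 39 standard bands", {
  b <- tol_bands()
  expect_equal(nrow(b), 39L)
  expect_equal(b$nominal_hz[1], 12.5)
  expect_equal(b$nominal_hz[39], 80000)
  expect_equal(b$center_hz, 10^(seq(11, 49) / 10))
  expect_true(all(diff(b$center_hz) > 0))
  expect_equal(b$lo_hz[-1], b$hi_hz[-39], tolerance = 1e-12)  # contiguous
  # bandwidth of the nominal 125 Hz band, used for the density conversion
  expect_equal(b$bw_hz[b$nominal_hz == 125], 29.0, tolerance = 0.01)
})

test_that("white-noise band levels equal density + 10*log10(bandwidth)", {
  sp <- quiet_scene(duration = 120, fs = FS_FULL, seed = 62,
                    noise_floor_db = 70)
  rec <- assemble_scene(sp)$recording
  cfg <- soundscape_config(FS_FULL, floor_db = 0)
  fr <- welch_psd(rec, cfg)
  tl <- tol_levels(fr, cfg)
  expect_equal(nrow(tl$tol_db), 39L)
  expect_false(any(is.na(tl$tol_db)))   # full band available at 200 kHz
  expected <- 70 + 10 * log10(tl$bands$bw_hz)
  got <- db_from_power(rowMeans(power_from_db(tl$tol_db)))
  # the per-minute median of a band power summed over k 1-Hz bins has a
  # small negative bias of order -log(2)/k in power; it only matters for
  # the narrowest (few-bin) bands, so those get a wider tolerance
  wide <- tl$bands$bw_hz >= 20
  expect_true(all(abs(got[wide] - expected[wide]) < 0.5))
  expect_true(all(abs(got[!wide] - expected[!wide]) < 1.5))
  # a 125-Hz-band density recovers the flat density (bandwidth cancels)
  expect_true(all(abs(tol125_density(tl) - 70) < 0.5))
})

test_that("tol125 conversion is plain bandwidth arithmetic", {
  v <- rep(NA_real_, 39)
  v[which(tol_bands()$nominal_hz == 125)] <- 80
  bw <- tol_bands()$bw_hz[tol_bands()$nominal_hz == 125]
  expect_equal(tol125_density(v), 80 - 10 * log10(bw))
})

test_that("summed third-octave power matches the integrated PSD within 1%", {
  sp <- quiet_scene(duration = 60, fs = FS_FULL, seed = 63,
                    noise_floor_db = 70)
  rec <- assemble_scene(sp)$recording
  cfg <- soundscape_config(FS_FULL, floor_db = 0)
  fr <- welch_psd(rec, cfg)
  b <- tol_bands()
  # per-second: total band-limited power from the 39 bands vs direct
  # integral of the 1-Hz PSD over the same range
  sel <- fr$freq >= b$lo_hz[1] & fr$freq < b$hi_hz[39]
  direct <- colSums(fr$power[sel, ])
  tol_lin <- sapply(seq_len(39), function(i) {
    s <- fr$freq >= b$lo_hz[i] & fr$freq < b$hi_hz[i]
    colSums(fr$power[s, , drop = FALSE])
  })
  expect_lt(max(abs(rowSums(tol_lin) - direct) / direct), 0.01)
})

test_that("proxy bands single out their target sources", {
  cfg <- soundscape_config(FS_TEST)
  # silent scene: all proxies at the clamp floor
  silent <- assemble_scene(quiet_scene(duration = 60, seed = 64))$recording
  px0 <- proxy_bin_levels(welch_psd(silent, cfg), cfg)
  expect_true(all(abs(px0$proxy_ua_db - 40) < 1.5))
  expect_true(all(abs(px0$proxy_echosounder_28_db - 40) < 1.5))
  # 28-kHz pings: the 29.1-29.3 kHz proxy rises, the 49.9-50.1 stays put
  # jittered ping interval so pings fall at varying phases of the 1-s
  # Hann analysis window
  sp28 <- scene_spec(duration = 60, sample_rate = FS_TEST, seed = 65,
                     events = list(scene_event(template_echosounder("28"),
                                               1, n = 55, ipi = c(0.85, 1.1))))
  px28 <- proxy_bin_levels(welch_psd(assemble_scene(sp28)$recording, cfg), cfg)
  expect_gt(px28$proxy_echosounder_28_db[1], 46)
  expect_lt(abs(px28$proxy_echosounder_50_db[1] - 40), 1.5)
  # UA on vs off minutes differ by at least 6 dB in the UA proxy
  spua <- scene_spec(duration = 120, sample_rate = FS_TEST, seed = 66,
                     events = list(scene_event(template_ua_comb("anchored"),
                                               60, on_duration = 60)))
  pxua <- proxy_bin_levels(welch_psd(assemble_scene(spua)$recording, cfg), cfg)
  expect_gte(pxua$proxy_ua_db[2] - pxua$proxy_ua_db[1], 6)
})

test_that("the 30-s coverage rule is enforced identically across all outputs", {
  sp <- quiet_scene(duration = 120, fs = FS_TEST, seed = 67,
                    disk_write = TRUE)
  rec <- assemble_scene(sp)$recording
  # disk-write periods: 15 s per 75-s cycle; minute 2 (60-120 s) loses
  # only 75-90 -> kept; shrink coverage instead with a custom exclusion
  excl <- rbind(disk_write_intervals(120),
                data.frame(start = 90, end = 120))
  cfg <- soundscape_config(FS_TEST, exclude = excl)
  fr <- welch_psd(rec, cfg)
  mm <- minute_median(fr, cfg)
  tl <- tol_levels(fr, cfg)
  px <- proxy_bin_levels(fr, cfg)
  # minute 1: usable 15-60 = 45 s; minute 2: usable 60-75 = 15 s < 30
  expect_equal(mm$coverage_s, c(45, 15))
  flagged <- c(FALSE, TRUE)
  expect_equal(apply(mm$psd_db, 2, function(col) all(is.na(col))), flagged)
  expect_equal(apply(tl$tol_db, 2, function(col) all(is.na(col))), flagged)
  expect_equal(is.na(px$proxy_ua_db), flagged)
})
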