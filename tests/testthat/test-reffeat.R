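test_that("delineation recovers clean fiducials (Q/S within 10 ms, T end within 20 ms)", {
  cfg <- pinned_config(seed = 3, ecg_noise_sd = 0)
  e <- simulate_ecg(cfg)
  fid <- delineate(e$clean, e$truth$time)
  ok_q <- abs(fid$q - e$truth$q) <= 0.010
  ok_s <- abs(fid$s - e$truth$s) <= 0.010
  ok_t <- abs(fid$t_end - e$truth$t_end) <= 0.020
  expect_gte(mean(ok_q, na.rm = TRUE), 0.90)
  expect_gte(mean(ok_s, na.rm = TRUE), 0.90)
  expect_gte(mean(ok_t, na.rm = TRUE), 0.90)
  expect_true(all(fid$q < fid$s, na.rm = TRUE))
})

test_that("a flat T wave flags the beat instead of inventing a T end", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- numeric(length(tt))
  r_times <- c(2, 4, 6, 8)
  for (r in r_times) {   # QRS only, no T wave at all
    x <- x + 1.0 * exp(-(tt - r)^2 / (2 * 0.009^2)) -
      0.12 * exp(-(tt - r + 0.030)^2 / (2 * 0.006^2)) -
      0.20 * exp(-(tt - r - 0.030)^2 / (2 * 0.007^2))
  }
  fid <- delineate(signal_record(x, fs, "ecg"), r_times)
  expect_true(all(is.na(fid$t_end)))
  expect_true(all(!is.na(fid$q)))
})

test_that("measured PVC QRS width is at least 120 ms", {
  cfg <- subject_sim_config("clinical", seed = 11, pvc_prob = 0.10,
                            paced_fraction = 0, ecg_noise_sd = 0, length_s = 300)
  e <- simulate_ecg(cfg)
  fid <- delineate(e$clean, e$truth$time)
  qrs <- fid$s - fid$q
  pvc <- e$truth$type == "pvc"
  expect_true(all(qrs[pvc] >= 0.120, na.rm = TRUE))
})

test_that("interval arithmetic and the linear QT correction", {
  # QTc = QT at RR = 1 s; worked case at RR = 0.8 s
  fid <- tibble::tibble(time = c(0, 1), q = c(-0.02, 0.98),
                        s = c(0.08, 1.08), t_end = c(0.38, 1.38))
  iv <- beat_intervals(fid)
  expect_true(is.na(iv$rr[1]))
  expect_equal(iv$rr[2], 1)
  expect_equal(iv$qtc_base[2], iv$qt_base[2])        # correction vanishes
  fid2 <- tibble::tibble(time = c(0, 0.8), q = c(0, 0.8) - 0.02,
                         s = c(0, 0.8) + 0.08, t_end = c(0, 0.8) + 0.38)
  iv2 <- beat_intervals(fid2)
  expect_equal(iv2$qt_base[2], 0.400)
  expect_equal(iv2$qtc_base[2], 0.4308)              # 0.400 + 0.154 * 0.2
  # QRS = 100 ms < 120 ms: no excess subtracted
  expect_equal(iv2$qt_qrs[2], iv2$qt_base[2])
  # wide QRS: excess over 120 ms subtracted, so QT_QRS < QT_BASE
  fid3 <- tibble::tibble(time = 0, q = -0.1, s = 0.1, t_end = 0.42)
  iv3 <- beat_intervals(fid3)
  expect_equal(iv3$qrs, 0.2)
  expect_equal(iv3$qt_qrs, iv3$qt_base - 0.08)
})

test_that("QTc slopes match the formula: +1 in QT, -0.154 s/s in RR", {
  set.seed(61)
  for (i in 1:20) {
    qt <- runif(1, 0.3, 0.5); rr <- runif(1, 0.6, 1.2); d <- runif(1, 0.01, 0.1)
    base <- qt + 0.154 * (1 - rr)
    fid <- function(rr_v, qt_v) {
      tibble::tibble(time = c(0, rr_v), q = c(0, rr_v), s = c(0.05, rr_v + 0.05),
                     t_end = c(qt_v, rr_v + qt_v))
    }
    expect_equal(beat_intervals(fid(rr, qt))$qtc_base[2], base, tolerance = 1e-12)
    expect_equal(beat_intervals(fid(rr, qt + d))$qtc_base[2], base + d,
                 tolerance = 1e-12)
    expect_equal(beat_intervals(fid(rr + d, qt))$qtc_base[2] -
                   beat_intervals(fid(rr, qt))$qtc_base[2], -0.154 * d,
                 tolerance = 1e-12)
  }
})

test_that("BP offset correction recovers an injected offset", {
  cfg <- pinned_config(seed = 12, bp_offset_mmhg = -12, bp_noise_sd_mmhg = 2)
  sch <- simulate_beat_schedule(cfg)
  bp <- simulate_bp(sch$time, cfg)
  corr <- bp_offset_correction(
    tibble::tibble(time = bp$beat$time, value = bp$beat$sbp),
    tibble::tibble(time = bp$cuff$time, value = bp$cuff$sbp))
  expect_identical(length(corr$differences), 5L)
  expect_lt(abs(corr$constant - 12), 1)
  expect_lt(abs(mean(corr$corrected$value - bp$beat$sbp_true)), 1)
  # zero offset, zero noise: the constant is zero
  cfg0 <- pinned_config(seed = 12, bp_offset_mmhg = 0, bp_noise_sd_mmhg = 0)
  bp0 <- simulate_bp(sch$time, cfg0)
  corr0 <- bp_offset_correction(
    tibble::tibble(time = bp0$beat$time, value = bp0$beat$sbp),
    tibble::tibble(time = bp0$cuff$time, value = bp0$cuff$sbp))
  expect_lt(abs(corr0$constant), 0.5)   # cuff = windowed mean of the same series
  # cuff windows without device samples are skipped, all skipped is an error
  expect_warning(
    bp_offset_correction(tibble::tibble(time = c(100, 130), value = c(120, 122)),
                         tibble::tibble(time = c(60, 180), value = c(118, 119))),
    "skipped")
  expect_error(
    quiet(bp_offset_correction(tibble::tibble(time = 500, value = 120),
                               tibble::tibble(time = 60, value = 118))),
    "cannot correct")
})

test_that("windowed statistics mirror the WFMR windowing", {
  beats <- dense_beats(300, rr = 0.9)
  ep <- select_epochs(beats, 300)
  vals <- rnorm(nrow(beats), mean = 5)
  st <- windowed_stats(vals, beats$time, ep, t_ea = 8)
  expect_true(all(st$n_windows == 12))   # 12 window means per 20-s epoch at 8 s
  crops <- matrix(0, nrow = nrow(beats), ncol = 700)
  es <- quiet(sliding_ensemble_averages(crops, ep[1, ], 8, r_times = beats$time))
  expect_identical(st$n_windows[1], es$n_total)
  # constant series: SD = 0 before log, floored at ln(1e-12)
  stc <- windowed_stats(rep(2, nrow(beats)), beats$time, ep, t_ea = 8)
  expect_true(all(abs(stc$sd_log - log(1e-12)) < 1e-9))
  expect_true(all(abs(stc$mean_log - log(2)) < 1e-12))
})

test_that("hand-built three-window toy reproduces hand arithmetic", {
  # beats at 0.5..19.5 s; T_EA = 17 gives starts 0,1,2 -> three windows
  times <- seq(0.5, 19.5, by = 1)
  vals <- seq_along(times)          # 1..20
  ep <- tibble::tibble(epoch_id = 1L, start = 0, end = 20,
                       dominant = "intrinsic", n_admitted = length(times),
                       admitted = list(seq_along(times)))
  st <- windowed_stats(vals, times, ep, t_ea = 15)
  # windows [0,15), [1,16), [2,17) ... [4,19) -> means of 1:15, 2:16, ..., 5:19
  wm <- c(mean(1:15), mean(2:16), mean(3:17), mean(4:18), mean(5:19))
  expect_identical(st$n_windows, 5L)
  expect_equal(st$mean_log, log(mean(wm)), tolerance = 1e-12)
  expect_equal(st$sd_log, log(sd(wm)), tolerance = 1e-12)
  expect_equal(st$window_means[[1]], log(wm), tolerance = 1e-12)
})

test_that("reference feature extraction runs end-to-end on a rendered subject", {
  s <- simulate_subject("nonclinical", seed = 55, render = TRUE, length_s = 120)
  ft <- quiet(reference_features(s, n_epochs = 5L))
  expect_setequal(unique(ft$feature),
                  c("rr", "qrs", "qt_base", "qt_qrs", "qtc_base", "qtc_qrs",
                    "sbp", "dbp"))
  expect_true(all(ft$n_windows == 12))
  # RR on the natural scale: exp(mean_log) should sit near 60/HR
  rr <- exp(ft$mean_log[ft$feature == "rr"])
  expect_true(all(abs(rr - 60 / s$config$heart_rate_bpm) < 0.1))
})
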