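test_that("configuration validation names the offending field", {
  expect_error(subject_sim_config("nonclinical", seed = 1, noise_sd = -1), "noise_sd")
  expect_error(subject_sim_config("nonclinical", seed = 1, pvc_prob = 1.5), "pvc_prob")
  expect_error(subject_sim_config("nonclinical", seed = 1, fs = 0), "fs")
  expect_error(subject_sim_config("bogus", seed = 1), "unknown profile")
  expect_error(subject_sim_config("nonclinical", seed = 1, length_s = 60), "length_s")
})

test_that("beat schedule: jitter-free RR intervals equal 60/HR to one sample", {
  cfg <- subject_sim_config("nonclinical", seed = 5, heart_rate_bpm = 60,
                            rr_jitter_sd_s = 0, pvc_prob = 0, paced_fraction = 0)
  sch <- simulate_beat_schedule(cfg)
  expect_true(all(abs(diff(sch$time) - 1.0) <= 1e-3))
  expect_true(all(sch$type == "intrinsic"))
})

test_that("five-minute ECG at 1000 Hz has 300,000 samples", {
  cfg <- pinned_config(seed = 8)
  e <- simulate_ecg(cfg)
  expect_identical(length(e$signal$x), 300000L)
  expect_equal(e$signal$fs, 1000)
  expect_identical(nrow(e$truth), nrow(simulate_beat_schedule(cfg)))
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_subject("clinical", seed = 33, render = TRUE, length_s = 120)
  s2 <- simulate_subject("clinical", seed = 33, render = TRUE, length_s = 120)
  expect_identical(s1$ecg$x, s2$ecg$x)
  expect_identical(s1$bcg$x, s2$bcg$x)
  expect_identical(s1$bp$beat, s2$bp$beat)
  expect_identical(s1$schedule, s2$schedule)
})

test_that("ECG ground-truth R time sits at the R-component maximum", {
  cfg <- pinned_config(seed = 4, ecg_noise_sd = 0)
  e <- simulate_ecg(cfg)
  x <- e$clean$x
  err <- vapply(e$truth$time, function(r) {
    i <- round(r * 1000) + 1
    w <- (i - 20):(i + 20)
    abs(w[which.max(x[w])] - i)
  }, numeric(1))
  expect_true(all(err <= 1))
})

test_that("ECG beat types carry their signatures (spike, wide QRS)", {
  cfg <- subject_sim_config("clinical", seed = 9, pvc_prob = 0.1,
                            paced_fraction = 0.5, ecg_noise_sd = 0)
  e <- simulate_ecg(cfg)
  tr <- e$truth
  # PVC QRS (S - Q ground truth) always at least 120 ms, intrinsic below
  qrs <- tr$s - tr$q
  expect_true(all(qrs[tr$type == "pvc"] >= 0.120))
  expect_true(all(qrs[tr$type == "intrinsic"] < 0.120))
  expect_true(all(tr$q < tr$time & tr$time < tr$s & tr$s < tr$t_end))
  # paced beats have a large narrow deflection 35-80 ms before R
  x <- e$clean$x
  paced <- tr$time[tr$type == "paced"][1:10]
  spike_amp <- vapply(paced, function(r) {
    max(abs(x[(round((r - 0.080) * 1000):round((r - 0.035) * 1000)) + 1]))
  }, numeric(1))
  expect_true(all(spike_amp > 3))
})

test_that("degenerate BCG (no jitter, no noise) repeats the template beat", {
  # 60 bpm puts every beat exactly on the 1 ms sample grid, so crops are
  # free of sub-sample phase differences
  cfg <- pinned_config(seed = 10, heart_rate_bpm = 60, rr_jitter_sd_s = 0,
                       amp_jitter_sd = 0, phase_jitter_sd_s = 0,
                       shape_innov_sd = 0, resp_depth = 0, noise_sd = 0,
                       drift_sd = 0)
  sch <- simulate_beat_schedule(cfg)
  b <- simulate_bcg(cfg, sch$time, sch$type)
  crops <- quiet(crop_heartbeats(b$clean, sch$time))
  ref <- crops[1, ]
  # identical up to the 5-sigma support truncation of the renderer (~4e-6)
  expect_lt(max(abs(sweep(crops, 2, ref))), 1e-5)
  # and the rendered beat matches the template components
  tpl <- bcg_beat_template()
  tg <- (0:699) / 1000
  expected <- rowSums(vapply(seq_len(nrow(tpl)), function(j) {
    tpl$amp[j] * exp(-(tg - tpl$center[j])^2 / (2 * tpl$width[j]^2))
  }, numeric(700)))
  expect_lt(max(abs(ref - expected)), 1e-5)
})

test_that("doubling amplitude jitter doubles the SD of beat peak amplitudes", {
  peak_sd <- function(amp_sd) {
    cfg <- pinned_config(seed = 42, amp_jitter_sd = amp_sd, phase_jitter_sd_s = 0,
                         shape_innov_sd = 0, resp_depth = 0, noise_sd = 0,
                         drift_sd = 0)
    sch <- simulate_beat_schedule(cfg)
    b <- simulate_bcg(cfg, sch$time, sch$type)
    crops <- quiet(crop_heartbeats(b$clean, sch$time))
    sd(apply(crops[1:200, ], 1, max))
  }
  ratio <- peak_sd(0.10) / peak_sd(0.05)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("respiratory modulation imprints a recoverable sinusoid envelope", {
  cfg <- pinned_config(seed = 7, rr_jitter_sd_s = 0.02, amp_jitter_sd = 0,
                       phase_jitter_sd_s = 0, shape_innov_sd = 0,
                       resp_depth = 0.2, resp_rate_hz = 0.25, noise_sd = 0,
                       drift_sd = 0)
  sch <- simulate_beat_schedule(cfg)
  b <- simulate_bcg(cfg, sch$time, sch$type)
  crops <- quiet(crop_heartbeats(b$clean, sch$time))
  pk <- apply(crops, 1, max)
  tt <- sch$time
  fit <- lm(pk ~ sin(2 * pi * 0.25 * tt) + cos(2 * pi * 0.25 * tt))
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("beat-to-beat waveform variance is monotone in each jitter dial", {
  beat_var <- function(dial, g) {
    args <- list(seed = 17, rr_jitter_sd_s = 0.02, amp_jitter_sd = 0.02,
                 phase_jitter_sd_s = 0.002, shape_innov_sd = 0.01,
                 resp_depth = 0, noise_sd = 0, drift_sd = 0)
    args[[dial]] <- g
    cfg <- do.call(pinned_config, args)
    sch <- simulate_beat_schedule(cfg)
    crops <- simulate_bcg_crops(cfg, sch, which = 1:100)
    mean(apply(crops, 2, var))
  }
  for (dial in c("amp_jitter_sd", "phase_jitter_sd_s", "shape_innov_sd")) {
    v <- vapply(c(0.005, 0.02, 0.08), function(g) beat_var(dial, g), numeric(1))
    expect_true(all(diff(v) > 0), label = sprintf("variance increasing in %s", dial))
  }
})

test_that("blood pressure: offset injection, cuff cadence, zero-noise identity", {
  cfg <- pinned_config(seed = 12, bp_offset_mmhg = 12, bp_noise_sd_mmhg = 0.5)
  sch <- simulate_beat_schedule(cfg)
  bp <- simulate_bp(sch$time, cfg)
  expect_identical(nrow(bp$cuff), 5L)  # one per minute over 300 s
  expect_equal(mean(bp$beat$sbp - bp$beat$sbp_true), 12, tolerance = 0.05)
  cfg0 <- pinned_config(seed = 12, bp_offset_mmhg = 0, bp_noise_sd_mmhg = 0)
  bp0 <- simulate_bp(sch$time, cfg0)
  expect_equal(bp0$beat$sbp, bp0$beat$sbp_true)
  expect_error(simulate_bp(numeric(0), cfg), "non-empty")
})

test_that("profiles: non-clinical subjects are purely intrinsic, cohort matches design", {
  for (seed in 1:5) {
    s <- simulate_subject("nonclinical", seed = seed, render = FALSE)
    expect_true(all(s$schedule$type == "intrinsic"))
  }
  coh <- simulate_cohort(seed = 2)
  expect_identical(nrow(coh), 55L)
  expect_identical(sum(coh$population == "nonclinical"), 29L)
  expect_identical(sum(coh$population == "clinical"), 26L)
  expect_identical(coh$subject_id[1], "N01")
})

test_that("crop-grid renderer agrees with the full-record renderer", {
  cfg <- pinned_config(seed = 19, heart_rate_bpm = 60, rr_jitter_sd_s = 0,
                       noise_sd = 0, drift_sd = 0)
  sch <- simulate_beat_schedule(cfg)
  full <- simulate_bcg(cfg, sch$time, sch$type)
  crops_full <- quiet(crop_heartbeats(full$clean, sch$time))
  crops_fast <- simulate_bcg_crops(cfg, sch, which = 5:20)
  # same latent states; residual differences only from neighbouring-beat
  # overlap and the sub-sample phase of the jittered component centers
  expect_lt(max(abs(crops_fast - crops_full[5:20, ])), 0.05)
})
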