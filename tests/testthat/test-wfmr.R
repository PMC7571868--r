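test_that("ensemble averaging is the sample-wise mean", {
  b <- matrix(rnorm(700), nrow = 1)[rep(1, 7), ]
  expect_identical(ensemble_average(b), b[1, ])
  two <- rbind(rep(1, 700), rep(3, 700))
  expect_identical(ensemble_average(two), rep(2, 700))
})

test_that("averaging 30 noisy copies shrinks the residual SD by sqrt(30)", {
  set.seed(23)
  template <- bcg_beat_template()
  tg <- (0:699) / 1000
  clean <- rowSums(vapply(seq_len(nrow(template)), function(j) {
    template$amp[j] * exp(-(tg - template$center[j])^2 / (2 * template$width[j]^2))
  }, numeric(700)))
  sigma <- 0.2
  beats <- matrix(rep(clean, each = 30), nrow = 30) + rnorm(30 * 700, 0, sigma)
  resid <- ensemble_average(beats) - clean
  expect_lt(abs(sd(resid) - sigma / sqrt(30)) / (sigma / sqrt(30)), 0.25)
})

test_that("sliding windows reproduce the printed counts: 12 at 8 s, 15 at 5 s", {
  crops <- matrix(rnorm(33 * 700), nrow = 33)
  r_times <- seq(0.5, 19.9, by = 0.6)[1:33]
  epoch <- list(start = 0, admitted = seq_along(r_times))
  es8 <- sliding_ensemble_averages(crops, epoch, t_ea = 8, r_times = r_times)
  es5 <- sliding_ensemble_averages(crops, epoch, t_ea = 5, r_times = r_times)
  expect_identical(es8$n_total, 12L)
  expect_identical(es5$n_total, 15L)
  # window-count law with dense distinct sets: N_Total = 20 - T_EA
  for (tt in c(2, 6, 11, 15)) {
    es <- sliding_ensemble_averages(crops, epoch, t_ea = tt, r_times = r_times)
    expect_identical(es$n_total, as.integer(20 - tt))
  }
})

test_that("duplicate beat-index sets collapse and empty windows drop", {
  # a single beat at t = 2 s: windows starting 0,1,2 contain it (identical
  # sets collapse to the first); later windows are empty and dropped
  crops <- matrix(rnorm(700), nrow = 1)
  epoch <- list(start = 0, admitted = 1L)
  expect_warning(
    es <- sliding_ensemble_averages(crops, epoch, t_ea = 8, r_times = 2),
    "empty window"
  )
  expect_identical(es$n_total, 1L)
  expect_identical(es$starts, 0)
  # an epoch whose windows never contain a beat is invalid
  expect_error(
    quiet(sliding_ensemble_averages(crops, list(start = 0, admitted = integer(0)),
                                    t_ea = 8, r_times = numeric(0))),
    "no window"
  )
})

test_that("mse is the raw sum of squared differences", {
  expect_identical(mse(c(1, 0), c(0, 1)), 2)
  f <- rnorm(700); g <- rnorm(700)
  expect_identical(mse(f, f), 0)
  expect_equal(mse(f, g), mse(g, f))
  brute <- 0; for (t in 1:700) brute <- brute + (f[t] - g[t])^2
  expect_equal(mse(f, g), brute, tolerance = 1e-9)
  expect_error(mse(1:3, 1:4), "equal length")
})

test_that("wfmr_epoch matches hand and brute-force oracles", {
  # identical ensemble averages: floored at ln(1e-12)
  same <- matrix(rep(rnorm(700), 3), nrow = 3, byrow = TRUE)
  expect_identical(wfmr_epoch(same), log(1e-12))
  # two waveforms at MSE = e^2 from each other: WFMR = 2
  f <- rep(0, 700)
  g <- rep(sqrt(exp(2) / 700), 700)
  expect_equal(wfmr_epoch(rbind(f, g)), 2, tolerance = 1e-12)
  # N_Total = 12 random waveforms vs the naive ordered-pairs double loop
  set.seed(77)
  w <- matrix(rnorm(12 * 700), nrow = 12)
  expect_equal(wfmr_epoch(w), wfmr_oracle(w), tolerance = 1e-9)
  expect_error(wfmr_epoch(matrix(rnorm(700), nrow = 1)), "at least two")
})

test_that("WFMR algebraic invariants hold on random ensembles", {
  set.seed(88)
  for (rep_i in 1:25) {
    n <- sample(3:10, 1)
    w <- matrix(rnorm(n * 700, sd = runif(1, 0.5, 2)), nrow = n)
    base <- wfmr_epoch(w)
    expect_equal(wfmr_epoch(w[sample(n), ]), base, tolerance = 1e-12)
    expect_equal(wfmr_epoch(w + 3.7), base, tolerance = 1e-9)
    a <- runif(1, 0.2, 5)
    expect_equal(wfmr_epoch(a * w), base + 2 * log(a), tolerance = 1e-9)
  }
})

test_that("the window sweep averages subjects, not epochs", {
  # single subject, single epoch: the curve is that epoch's WFMR per T_EA
  tbl <- tibble::tibble(subject_id = "A", t_ea = 2:15, wfmr = rnorm(14))
  sw <- wfmr_sweep(tbl)
  expect_equal(sw$wfmr, tbl$wfmr[order(tbl$t_ea)])
  # two subjects with unequal epoch counts weigh equally
  tbl2 <- tibble::tibble(
    subject_id = c("A", "A", "A", "B"),
    t_ea = 8, wfmr = c(1, 2, 3, 10)
  )
  sw2 <- wfmr_sweep(tbl2)
  expect_equal(sw2$wfmr, mean(c(mean(c(1, 2, 3)), 10)))  # 6, not mean of 4 epochs
  expect_error(wfmr_sweep(tibble::tibble()), "empty")
})

test_that("mean WFMR decreases with window size on simulated cohorts", {
  curves <- vapply(1:20, function(seed) {
    coh <- simulate_cohort(n_nonclinical = 2, n_clinical = 2, seed = seed)
    wfmr_sweep(coh)$wfmr
  }, numeric(14))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) < 0))
})

test_that("the elbow rule picks the documented window sizes", {
  toy <- tibble::tibble(t_ea = 2:8, wfmr = c(10, 6, 4, 3, 2.9, 2.85, 2.84))
  # total drop 7.16; first marginal drop below 0.716 is at the 4th point
  expect_identical(select_optimal_window(toy), 5L)
  flat <- tibble::tibble(t_ea = 2:6, wfmr = rep(1.5, 5))
  expect_identical(select_optimal_window(flat), 2L)
  lin3 <- tibble::tibble(t_ea = 2:4, wfmr = c(3, 2, 1))
  # marginal drop is half the total everywhere: no elbow before the end
  expect_identical(select_optimal_window(lin3), 4L)
  expect_error(select_optimal_window(tibble::tibble(t_ea = 2:3, wfmr = c(1, 0))),
               "3 points")
  expect_error(select_optimal_window(tibble::tibble(t_ea = 2:4, wfmr = c(1, NA, 0))),
               "non-finite")
})

test_that("WFMR responds monotonically to the amplitude-jitter dial", {
  grid <- c(0.03, 0.10, 0.25)
  mean_wfmr <- vapply(grid, function(a) {
    per_seed <- vapply(1:20, function(seed) {
      coh <- simulate_cohort(n_nonclinical = 2, n_clinical = 2, seed = seed,
                             amp_jitter_sd = a)
      mean(wfmr_features(coh)$wfmr)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(mean_wfmr) > 0))
})
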