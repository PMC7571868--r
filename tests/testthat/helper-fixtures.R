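# shared fixtures, all generated in code

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a point config with every jitter pinned, for controlled experiments
pinned_config <- function(seed = 42, ...) {
  defaults <- list(heart_rate_bpm = 72, rr_jitter_sd_s = 0.03,
                   amp_jitter_sd = 0.05, phase_jitter_sd_s = 0.003,
                   shape_innov_sd = 0.02, resp_rate_hz = 0.25,
                   resp_depth = 0.1, noise_sd = 0.03, drift_sd = 0.05,
                   ecg_noise_sd = 0.01, length_s = 300)
  dots <- list(...)
  dots <- dots[!duplicated(names(dots), fromLast = TRUE)]
  args <- utils::modifyList(defaults, dots)
  do.call(subject_sim_config,
          c(list(profile = "nonclinical", seed = seed), args))
}

# dense regular beat table: one beat every `rr` seconds from t0
dense_beats <- function(record_length = 300, rr = 0.9, t0 = 0.5,
                        type = "intrinsic") {
  t <- seq(t0, record_length - 0.75, by = rr)
  tibble::tibble(time = t, type = type)
}

# matched-pairs scoring of detected vs true event times
score_events <- function(detected, truth, tol) {
  sens <- mean(vapply(truth, function(t0) any(abs(detected - t0) <= tol), logical(1)))
  ppv <- if (length(detected)) {
    mean(vapply(detected, function(d) any(abs(truth - d) <= tol), logical(1)))
  } else NA_real_
  list(sens = sens, ppv = ppv)
}

# naive Welch t-test from the textbook formulas (independent oracle)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

# naive all-ordered-pairs WFMR (independent oracle)
wfmr_oracle <- function(waves) {
  n <- nrow(waves)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) tot <- tot + sum((waves[i, ] - waves[j, ])^2)
  }
  log(max(1e-12, tot / (n * (n - 1))))
}
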