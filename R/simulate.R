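#' Simulate the beat schedule for one subject
#'
#' RR intervals are i.i.d. Gaussian around 60/HR (floored at 0.35 s so beats
#' stay separable), with no long-range heart-rate-variability structure.
#' Beat types are drawn per beat: PVC with probability `pvc_prob`, otherwise
#' paced with probability `paced_fraction`, otherwise intrinsic. A PVC
#' arrives prematurely (its RR shortened by 30%) and is followed by a
#' compensatory pause.
#'
#' @param config A [subject_sim_config()].
#' @return A tibble with columns `time` (R-wave time, s) and `type`
#'   (`intrinsic`, `paced` or `pvc`).
#' @export
simulate_beat_schedule <- function(config) {
  config <- validate_sim_config(config)
  set.seed(.stage_seed(config$seed, "schedule"))
  mu <- 60 / config$heart_rate_bpm
  n_draw <- ceiling(config$length_s / 0.35) + 5L
  z <- rnorm(n_draw)
  u_pvc <- runif(n_draw)
  u_paced <- runif(n_draw)
  rr <- pmax(0.35, mu + config$rr_jitter_sd_s * z)
  type <- ifelse(u_pvc < config$pvc_prob, "pvc",
                 ifelse(u_paced < config$paced_fraction, "paced", "intrinsic"))
  for (k in which(type == "pvc")) {
    if (k == 1L) next
    rr[k] <- max(0.35, rr[k] * 0.70)
    if (k < n_draw) rr[k + 1L] <- rr[k + 1L] * 1.30
  }
  t <- 0.8 + cumsum(c(0, rr[-1]))
  keep <- t <= config$length_s - 0.75
  tibble::tibble(time = t[keep], type = type[keep])
}

# Per-beat latent jitter states shared by the full-record and crop renderers,
# drawn under their own stage seed so both paths see identical beats.
beat_latents <- function(config, schedule) {
  n <- nrow(schedule)
  set.seed(.stage_seed(config$seed, "latents"))
  z_amp <- rnorm(n)
  z_phase <- matrix(rnorm(n * 7L), nrow = n)
  e_shape <- rnorm(n)
  phi <- config$shape_ar_coef
  s0 <- if (abs(phi) < 1) config$shape_innov_sd / sqrt(1 - phi^2) else config$shape_innov_sd
  shape <- as.numeric(stats::filter(config$shape_innov_sd * e_shape, phi,
                                    method = "recursive", init = s0 * rnorm(1)))
  resp <- 1 + config$resp_depth * sin(2 * pi * config$resp_rate_hz * schedule$time)
  amp <- exp(config$amp_jitter_sd * z_amp) * resp
  type_amp <- c(intrinsic = 1, paced = 0.9, pvc = 0.55)[schedule$type]
  type_wid <- c(intrinsic = 1, paced = 1, pvc = 1.15)[schedule$type]
  list(
    amp = amp * unname(type_amp),
    width = exp(shape) * unname(type_wid),
    phase = z_phase * config$phase_jitter_sd_s
  )
}

# Add Gaussian bumps (center s, amp, width s) into a sample vector.
add_gaussians <- function(y, fs, center, amp, width) {
  n <- length(y)
  for (i in seq_along(center)) {
    lo <- max(1L, floor((center[i] - 5 * width[i]) * fs) + 1L)
    hi <- min(n, ceiling((center[i] + 5 * width[i]) * fs) + 1L)
    if (lo > hi) next
    tt <- (seq(lo, hi) - 1L) / fs
    y[lo:hi] <- y[lo:hi] + amp[i] * exp(-(tt - center[i])^2 / (2 * width[i]^2))
  }
  y
}

# BCG per-beat component table (one row per beat x wave) from the latents.
bcg_component_table <- function(schedule, latents) {
  tpl <- bcg_beat_template()
  n <- nrow(schedule)
  k <- rep(seq_len(n), each = nrow(tpl))
  j <- rep(seq_len(nrow(tpl)), times = n)
  data.frame(
    center = schedule$time[k] + tpl$center[j] + latents$phase[cbind(k, j)],
    amp = latents$amp[k] * tpl$amp[j],
    width = tpl$width[j] * latents$width[k]
  )
}

#' Simulate a single-lead ECG with ground-truth fiducials
#'
#' Each beat is rendered from its type's Gaussian component set: intrinsic
#' beats carry P-QRS-T; paced beats a narrow stimulus spike followed by a
#' widened QRS and no P wave; PVCs a wide (>120 ms) P-less QRS with a
#' discordant T. Ground-truth Q, S and T-end times are emitted for every
#' beat (T end is the tangent-method intercept of the Gaussian T wave).
#'
#' @param config A [subject_sim_config()].
#' @param schedule Optional beat schedule from [simulate_beat_schedule()];
#'   generated from `config` when omitted.
#' @return A list with `signal` (a [signal_record()] at `config$ecg_fs`),
#'   `clean` (noise-free signal) and `truth` (tibble: `time`, `type`, `q`,
#'   `s`, `t_end`, absolute seconds).
#' @export
simulate_ecg <- function(config, schedule = NULL) {
  config <- validate_sim_config(config)
  schedule <- schedule %||% simulate_beat_schedule(config)
  set.seed(.stage_seed(config$seed, "ecg"))
  n_beat <- nrow(schedule)
  amp_scale <- exp(config$ecg_amp_sd * rnorm(n_beat))
  t_scale <- exp(config$ecg_shape_sd * rnorm(n_beat))
  fs <- config$ecg_fs
  n <- round(config$length_s * fs)
  y <- numeric(n)
  truth <- data.frame(time = schedule$time, type = schedule$type,
                      q = NA_real_, s = NA_real_, t_end = NA_real_)
  for (k in seq_len(n_beat)) {
    comps <- ecg_beat_components(schedule$type[k], spike_amp = config$pacing_spike_amp)
    a <- comps$amp * amp_scale[k]
    if ("spike" %in% comps$wave) a[comps$wave == "spike"] <- comps$amp[comps$wave == "spike"]
    w <- comps$width
    w[comps$wave == "T"] <- w[comps$wave == "T"] * t_scale[k]
    y <- add_gaussians(y, fs, schedule$time[k] + comps$center, a, w)
    fid <- ecg_beat_fiducials(comps, t_width_scale = t_scale[k])
    truth$q[k] <- schedule$time[k] + fid$q
    truth$s[k] <- schedule$time[k] + fid$s
    truth$t_end[k] <- schedule$time[k] + fid$t_end
  }
  noisy <- y + rnorm(n, 0, config$ecg_noise_sd)
  list(signal = signal_record(noisy, fs, "ecg", "mV"),
       clean = signal_record(y, fs, "ecg", "mV"),
       truth = tibble::as_tibble(truth))
}

#' Simulate the BCG force channel for a known beat schedule
#'
#' Every beat is the canonical template ([bcg_beat_template()]) under
#' per-beat lognormal amplitude jitter, per-component Gaussian timing
#' jitter, AR(1) log-width shape drift and sinusoidal respiratory amplitude
#' modulation, summed into the record and overlaid with white noise plus a
#' smooth low-frequency baseline drift.
#'
#' @param config A [subject_sim_config()].
#' @param r_times Strictly increasing R-wave times (s).
#' @param beat_types Beat type per R time.
#' @return A list with `signal` (noisy [signal_record()] at `config$fs`),
#'   `clean` (noise- and drift-free channel) and `latents` (per-beat jitter
#'   states, useful as simulation ground truth).
#' @export
simulate_bcg <- function(config, r_times, beat_types) {
  config <- validate_sim_config(config)
  if (length(r_times) != length(beat_types)) {
    abort("`r_times` and `beat_types` must have the same length")
  }
  if (is.unsorted(r_times, strictly = TRUE)) abort("`r_times` must be strictly increasing")
  schedule <- tibble::tibble(time = as.numeric(r_times), type = as.character(beat_types))
  latents <- beat_latents(config, schedule)
  fs <- config$fs
  n <- round(config$length_s * fs)
  comps <- bcg_component_table(schedule, latents)
  clean <- add_gaussians(numeric(n), fs, comps$center, comps$amp, comps$width)
  set.seed(.stage_seed(config$seed, "bcg"))
  noise <- rnorm(n, 0, config$noise_sd)
  drift <- baseline_drift(n, fs, config$drift_sd)
  list(signal = signal_record(clean + noise + drift, fs, "bcg", "a.u."),
       clean = signal_record(clean, fs, "bcg", "a.u."),
       latents = latents)
}

# Smooth baseline wander: spline through Gaussian knots every 5 s.
baseline_drift <- function(n, fs, sd) {
  if (sd <= 0) return(numeric(n))
  knot_t <- seq(0, (n - 1) / fs + 5, by = 5)
  knots <- rnorm(length(knot_t), 0, sd)
  spline(knot_t, knots, xout = (seq_len(n) - 1) / fs)$y
}

#' Render BCG heartbeat crops directly on the 700-sample grid
#'
#' Fast path used for large Monte-Carlo cohorts: the selected beats are
#' rendered straight onto the 700-sample (1000 Hz) crop grid with the same
#' per-beat latent jitter states as [simulate_bcg()] (identical seed, so
#' the two renderers agree up to neighbouring-beat overlap), plus white
#' beat-level noise. Baseline drift is not rendered — the analysis
#' high-pass removes it in the full path anyway.
#'
#' @param config A [subject_sim_config()].
#' @param schedule Beat schedule from [simulate_beat_schedule()].
#' @param which Indices of the beats to render (default all).
#' @return A `length(which)` x 700 matrix with attribute `r_times`.
#' @export
simulate_bcg_crops <- function(config, schedule, which = seq_len(nrow(schedule))) {
  config <- validate_sim_config(config)
  latents <- beat_latents(config, schedule)
  tpl <- bcg_beat_template()
  tg <- (0:699) / 1000
  crops <- matrix(0, nrow = length(which), ncol = 700L)
  for (j in seq_len(nrow(tpl))) {
    ctr <- tpl$center[j] + latents$phase[which, j, drop = TRUE]
    amp <- latents$amp[which] * tpl$amp[j]
    wid <- tpl$width[j] * latents$width[which]
    d <- outer(ctr, tg, function(c0, t0) t0 - c0)
    crops <- crops + amp * exp(-d^2 / (2 * wid^2))
  }
  set.seed(.stage_seed(config$seed, "bcg"))
  crops <- crops + matrix(rnorm(length(crops), 0, config$noise_sd), nrow = nrow(crops))
  rownames(crops) <- NULL
  attr(crops, "r_times") <- schedule$time[which]
  crops
}

#' Simulate beat-to-beat and cuff blood pressure
#'
#' The true beat-to-beat SBP/DBP series is a slowly varying AR(1) plus
#' respiratory oscillation around the subject's mean pressures. The
#' continuous device reports true values plus a constant offset plus
#' measurement noise; the cuff reports one reading per minute, the mean of
#' the true pressure over the preceding 60 s.
#'
#' @param r_times Beat times (s), non-empty.
#' @param config A [subject_sim_config()].
#' @return A list with `beat` (tibble: `time`, `sbp_true`, `dbp_true`,
#'   `sbp`, `dbp` — device values) and `cuff` (tibble: `time`, `sbp`,
#'   `dbp`).
#' @export
simulate_bp <- function(r_times, config) {
  config <- validate_sim_config(config)
  if (length(r_times) == 0L) abort("`r_times` must be non-empty")
  set.seed(.stage_seed(config$seed, "bp"))
  n <- length(r_times)
  slow <- function(mean_v) {
    ar <- as.numeric(stats::filter(0.3 * config$bp_sd_mmhg * rnorm(n), 0.9,
                                   method = "recursive"))
    resp <- 0.5 * config$bp_sd_mmhg * sin(2 * pi * config$resp_rate_hz * r_times)
    mean_v + ar + resp
  }
  sbp_true <- slow(config$sbp_mean_mmhg)
  dbp_true <- slow(config$dbp_mean_mmhg)
  dev <- function(true_v) true_v + config$bp_offset_mmhg + rnorm(n, 0, config$bp_noise_sd_mmhg)
  beat <- tibble::tibble(time = as.numeric(r_times),
                         sbp_true = sbp_true, dbp_true = dbp_true,
                         sbp = dev(sbp_true), dbp = dev(dbp_true))
  cuff_t <- seq(60, config$length_s, by = 60)
  cuff_t <- cuff_t[cuff_t <= config$length_s]
  win_mean <- function(true_v, t0) {
    i <- r_times >= t0 - 60 & r_times < t0
    if (!any(i)) NA_real_ else mean(true_v[i])
  }
  cuff <- tibble::tibble(
    time = cuff_t,
    sbp = vapply(cuff_t, function(t0) win_mean(sbp_true, t0), numeric(1)),
    dbp = vapply(cuff_t, function(t0) win_mean(dbp_true, t0), numeric(1))
  )
  list(beat = beat, cuff = cuff)
}

#' Simulate one complete subject record
#'
#' Bundles ECG, BCG and blood pressure over a shared beat schedule, with
#' full ground truth. With `render = FALSE` only the schedule and
#' configuration are materialized; downstream WFMR code then renders the
#' 700-sample beat crops it needs directly, which is how large Monte-Carlo
#' cohorts stay cheap.
#'
#' @param profile `"nonclinical"` or `"clinical"`.
#' @param seed Integer seed.
#' @param render Render the full multichannel record (default `TRUE`)?
#' @param ... Config field overrides, passed to [subject_sim_config()].
#' @param profiles Profile list, defaults to [sim_profiles()].
#' @return A `subject_record` list: `config`, `schedule`, `truth`, and (if
#'   rendered) `ecg`, `bcg` ([signal_record()]s), `bcg_clean`, `bp`.
#' @export
#' @examples
#' s <- simulate_subject("nonclinical", seed = 7, render = FALSE)
#' nrow(s$schedule)
simulate_subject <- function(profile, seed, render = TRUE, ..., profiles = sim_profiles()) {
  config <- subject_sim_config(profile, seed, ..., profiles = profiles)
  schedule <- simulate_beat_schedule(config)
  rec <- list(config = config, schedule = schedule, profile = config$population)
  if (render) {
    ecg <- simulate_ecg(config, schedule)
    bcg <- simulate_bcg(config, schedule$time, schedule$type)
    bp <- simulate_bp(schedule$time, config)
    rec$ecg <- ecg$signal
    rec$ecg_clean <- ecg$clean
    rec$bcg <- bcg$signal
    rec$bcg_clean <- bcg$clean
    rec$bp <- bp
    rec$truth <- dplyr::left_join(ecg$truth,
                                  bp$beat[, c("time", "sbp_true", "dbp_true")],
                                  by = "time")
  } else {
    rec$truth <- schedule
  }
  structure(rec, class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s, %d beats over %g s%s\n",
              x$profile, nrow(x$schedule), x$config$length_s,
              if (is.null(x$ecg)) " (unrendered)" else ""))
  invisible(x)
}

#' Simulate a two-population study cohort
#'
#' Defaults mirror the study design: 29 non-clinical and 26 clinical
#' subjects, five minutes each. Subject seeds are derived deterministically
#' from `seed`.
#'
#' @param n_nonclinical,n_clinical Subjects per population.
#' @param seed Cohort seed.
#' @param render Render full records (slow) or schedules only (default).
#' @param ... Config overrides applied to every subject.
#' @param profiles Profile list, defaults to [sim_profiles()].
#' @return A tibble with columns `subject_id`, `population`, `subject`
#'   (list-column of `subject_record`s).
#' @export
#' @examples
#' coh <- simulate_cohort(n_nonclinical = 2, n_clinical = 2, seed = 1)
#' coh$subject_id
simulate_cohort <- function(n_nonclinical = 29, n_clinical = 26, seed = 1,
                            render = FALSE, ..., profiles = sim_profiles()) {
  if (n_nonclinical < 1 || n_clinical < 1) abort("both populations need at least one subject")
  pops <- c(rep("nonclinical", n_nonclinical), rep("clinical", n_clinical))
  ids <- c(sprintf("N%02d", seq_len(n_nonclinical)), sprintf("C%02d", seq_len(n_clinical)))
  seeds <- (as.numeric(seed) * 1009 + 7919 * seq_along(pops)) %% (2^31 - 1)
  subjects <- purrr::map2(pops, seeds, function(p, s) {
    simulate_subject(p, as.integer(s), render = render, ..., profiles = profiles)
  })
  tibble::tibble(subject_id = ids, population = pops, subject = subjects)
}
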