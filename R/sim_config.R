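#' Default population profiles for the synthetic cohort generator
#'
#' Profiles are declared in `inst/extdata/profiles.yaml` so the parameter
#' sets behind the clinical / non-clinical contrast are auditable in one
#' place. Two-element fields are `[lo, hi]` uniform priors sampled once per
#' subject; scalars are fixed.
#'
#' @param path Optional path to an alternative profiles YAML file.
#' @return A named list with one parameter block per profile.
#' @export
sim_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "profiles.yaml", package = "bcgfluct")
  if (!nzchar(path) || !file.exists(path)) abort("profiles file not found")
  yaml::read_yaml(path)
}

# every field a subject config must carry, with the validation class
.sim_config_fields <- c(
  "population", "length_s", "fs", "ecg_fs", "heart_rate_bpm",
  "rr_jitter_sd_s", "amp_jitter_sd", "phase_jitter_sd_s",
  "shape_ar_coef", "shape_innov_sd", "resp_rate_hz", "resp_depth",
  "pvc_prob", "paced_fraction", "pacing_spike_amp",
  "noise_sd", "drift_sd", "ecg_noise_sd", "ecg_shape_sd", "ecg_amp_sd",
  "sbp_mean_mmhg", "dbp_mean_mmhg", "bp_sd_mmhg", "bp_noise_sd_mmhg",
  "bp_offset_mmhg", "seed"
)

.sd_fields <- c("rr_jitter_sd_s", "amp_jitter_sd", "phase_jitter_sd_s",
                "shape_innov_sd", "noise_sd", "drift_sd", "ecg_noise_sd",
                "ecg_shape_sd", "ecg_amp_sd", "bp_sd_mmhg", "bp_noise_sd_mmhg")
.frac_fields <- c("resp_depth", "pvc_prob", "paced_fraction")

#' Build a per-subject simulation configuration
#'
#' Draws one scalar parameter set from the named profile's priors (see
#' [sim_profiles()]); any field can then be overridden through `...`, which
#' is how tests pin individual parameters (e.g. `rr_jitter_sd_s = 0`).
#'
#' @param profile `"nonclinical"` or `"clinical"`.
#' @param seed Integer seed; mandatory so every record is reproducible.
#' @param ... Named scalar overrides of any configuration field.
#' @param profiles Profile list, defaults to [sim_profiles()].
#' @return A validated list of class `subject_sim_config`.
#' @export
#' @examples
#' cfg <- subject_sim_config("nonclinical", seed = 1, amp_jitter_sd = 0.05)
#' cfg$amp_jitter_sd
subject_sim_config <- function(profile = c("nonclinical", "clinical"), seed,
                               ..., profiles = sim_profiles()) {
  if (is.character(profile) && !profile[1] %in% names(profiles)) {
    abort(sprintf("unknown profile '%s'; available: %s",
                  profile[1], paste(names(profiles), collapse = ", ")))
  }
  profile <- match.arg(profile, names(profiles))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number")
  }
  seed <- as.integer(seed %% .Machine$integer.max)
  prior <- profiles[[profile]]

  set.seed(seed)
  draw <- function(v) if (length(v) == 2L) runif(1, v[[1]], v[[2]]) else v[[1]]
  cfg <- lapply(prior[setdiff(names(prior), "paced_subject_prob")], draw)
  # a subject is either predominantly paced or not at all
  p_paced <- prior[["paced_subject_prob"]] %||% 0
  if (runif(1) >= p_paced) cfg$paced_fraction <- 0

  cfg$population <- profile
  cfg$seed <- seed
  dots <- list(...)
  # when a field is supplied more than once the last value wins
  if (length(dots)) dots <- dots[!duplicated(names(dots), fromLast = TRUE)]
  if (length(dots)) {
    bad <- setdiff(names(dots), .sim_config_fields)
    if (length(bad)) abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
    cfg <- modifyList(cfg, dots)
  }
  validate_sim_config(cfg)
}

#' @rdname subject_sim_config
#' @param cfg A candidate configuration list.
#' @export
validate_sim_config <- function(cfg) {
  missing_f <- setdiff(.sim_config_fields, names(cfg))
  if (length(missing_f)) abort(sprintf("config missing field(s): %s", paste(missing_f, collapse = ", ")))
  num1 <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("config field `%s` must be a single finite number", f))
    }
    v
  }
  for (f in .sd_fields) if (num1(f) < 0) abort(sprintf("config field `%s` must be >= 0", f))
  for (f in .frac_fields) {
    v <- num1(f)
    if (v < 0 || v > 1) abort(sprintf("config field `%s` must lie in [0, 1]", f))
  }
  if (num1("fs") <= 0) abort("config field `fs` must be > 0")
  if (num1("ecg_fs") <= 0) abort("config field `ecg_fs` must be > 0")
  if (num1("heart_rate_bpm") <= 0) abort("config field `heart_rate_bpm` must be > 0")
  if (num1("length_s") < 120) abort("config field `length_s` must be >= 120 s (five 20-s epochs)")
  structure(cfg, class = "subject_sim_config")
}

#' @export
print.subject_sim_config <- function(x, ...) {
  cat(sprintf("<subject_sim_config> %s, %g s @ %g Hz, HR %.1f bpm, seed %d\n",
              x$population, x$length_s, x$fs, x$heart_rate_bpm, x$seed))
  cat(sprintf("  jitter: amp %.3f, phase %.4f s, rr %.3f s, shape %.3f (AR %.2f)\n",
              x$amp_jitter_sd, x$phase_jitter_sd_s, x$rr_jitter_sd_s,
              x$shape_innov_sd, x$shape_ar_coef))
  cat(sprintf("  beats: pvc %.3f, paced %.2f; noise %.3f; bp offset %+.1f mmHg\n",
              x$pvc_prob, x$paced_fraction, x$noise_sd, x$bp_offset_mmhg))
  invisible(x)
}

# fixed per-stage seed offsets so channels have independent, reproducible streams
.stage_seed <- function(seed, stage) {
  off <- c(schedule = 101L, latents = 211L, ecg = 307L, bcg = 401L, bp = 503L)[[stage]]
  as.integer((as.numeric(seed) + off) %% .Machine$integer.max)
}
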