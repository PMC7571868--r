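#' Canonical BCG beat template
#'
#' The sitting-posture BCG heartbeat is modelled as a sum of Gaussian bumps,
#' one per named wave (H, I, J, K, L, M, N), over the 700 ms following the
#' ECG R wave. Only the wave ordering and sign pattern are meant to be
#' physiological: J is the dominant positive deflection, flanked by the
#' negative I and K waves, with the smaller diastolic L-M-N complex after.
#'
#' @return A tibble with columns `wave`, `center` (s after R), `amp`
#'   (arbitrary force units) and `width` (Gaussian sigma, s).
#' @export
bcg_beat_template <- function() {
  tibble::tibble(
    wave   = c("H", "I", "J", "K", "L", "M", "N"),
    center = c(0.12, 0.18, 0.24, 0.31, 0.39, 0.47, 0.55),
    amp    = c(0.40, -0.60, 1.00, -0.70, 0.35, -0.20, 0.15),
    width  = c(0.025, 0.022, 0.025, 0.030, 0.035, 0.040, 0.045)
  )
}

# ECG morphology per beat type: Gaussian components relative to the R wave.
# Paced beats carry a narrow stimulus spike before a widened QRS and no P
# wave; PVCs are wide (>120 ms), P-less, with a discordant (inverted) T.
ecg_beat_components <- function(type, spike_amp = 6) {
  switch(
    type,
    intrinsic = tibble::tibble(
      wave   = c("P", "Q", "R", "S", "T"),
      center = c(-0.160, -0.030, 0.000, 0.030, 0.300),
      amp    = c(0.12, -0.12, 1.00, -0.20, 0.30),
      width  = c(0.020, 0.006, 0.009, 0.007, 0.050)
    ),
    pvc = tibble::tibble(
      wave   = c("Q", "R", "S", "T"),
      center = c(-0.070, 0.000, 0.070, 0.340),
      amp    = c(-0.25, 0.90, -0.45, -0.35),
      width  = c(0.020, 0.025, 0.022, 0.060)
    ),
    paced = tibble::tibble(
      wave   = c("spike", "Q", "R", "S", "T"),
      center = c(-0.055, -0.020, 0.000, 0.050, 0.320),
      amp    = c(spike_amp, -0.15, 0.85, -0.30, 0.28),
      width  = c(0.0015, 0.012, 0.018, 0.016, 0.055)
    ),
    abort(sprintf("unknown beat type '%s'", type))
  )
}

# Analytic ground-truth fiducials for one rendered beat, relative to R.
# QRS onset/offset are the 2-sigma edges of the Q and S components; T end is
# the tangent-method intercept, which for a Gaussian T wave is exactly
# center + 2*sigma.
ecg_beat_fiducials <- function(comps, t_width_scale = 1) {
  q <- comps[comps$wave == "Q", ]
  s <- comps[comps$wave == "S", ]
  tw <- comps[comps$wave == "T", ]
  list(
    q = q$center - 2 * q$width,
    s = s$center + 2 * s$width,
    t_end = tw$center + 2 * tw$width * t_width_scale
  )
}
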