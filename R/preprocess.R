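#' FIR filter specification
#'
#' Linear-phase window-design FIR filters, the defaults matching the
#' analysis chain: a 2 Hz high-pass (Hamming window, 1000 taps) for offset
#' and drift removal, and role-bound low-passes (BCG 25 Hz; non-clinical
#' ECG 40 Hz — clinical ECG goes through wavelet denoising instead so
#' pacing spikes survive).
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff Cut-off frequency in Hz.
#' @param taps Filter order (number of taps minus one); order 1000 gives a
#'   1001-tap type-I filter.
#' @param window Window name; only `"hamming"` is implemented.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), cutoff, taps = 1000,
                        window = "hamming") {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    abort("`cutoff` must be a positive scalar (Hz)")
  }
  if (taps < 1) abort("`taps` must be >= 1")
  if (window != "hamming") abort("only the 'hamming' window is implemented")
  structure(list(kind = kind, cutoff = cutoff, taps = as.integer(taps), window = window),
            class = "filter_spec")
}

# linear convolution via FFT, padded to a highly composite length
fft_conv <- function(x, b) {
  n <- length(x) + length(b) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
              fft(c(b, numeric(nf - length(b)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Apply an FIR filter with zero phase
#'
#' The filter is applied in a single pass and its constant group delay
#' (`taps / 2` samples, exact for a linear-phase design) is removed, so
#' fiducial timing downstream is unaffected. Edges are reflection-padded.
#'
#' @param sig A [signal_record()].
#' @param spec A [filter_spec()].
#' @return The filtered [signal_record()].
#' @export
fir_filter <- function(sig, spec) {
  assert_signal(sig, "sig")
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= sig$fs / 2) {
    abort(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", spec$cutoff, sig$fs / 2))
  }
  if (spec$taps %% 2L == 1L && spec$kind == "highpass") {
    abort("high-pass FIR needs an even order (type-I filter)")
  }
  b <- as.numeric(signal::fir1(spec$taps, spec$cutoff / (sig$fs / 2),
                               type = if (spec$kind == "highpass") "high" else "low",
                               window = signal::hamming(spec$taps + 1)))
  x <- sig$x
  n <- length(x)
  pad <- min(n - 1L, spec$taps)
  # reflect about the end points to suppress edge transients
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  y <- fft_conv(xp, b)
  delay <- spec$taps / 2
  out <- y[pad + delay + seq_len(n)]
  signal_record(out, sig$fs, sig$channel, sig$units)
}

#' Resample a signal with band-limited interpolation
#'
#' Used to bring the 1024 Hz wireless ECG onto the common 1000 Hz clock.
#' Rational-ratio polyphase resampling via the signal package.
#'
#' @param sig A [signal_record()].
#' @param fs_out Target sampling rate (Hz).
#' @return A [signal_record()] at `fs_out`; duration is preserved to within
#'   one output sample.
#' @export
resample_signal <- function(sig, fs_out) {
  assert_signal(sig, "sig")
  if (!is.numeric(fs_out) || length(fs_out) != 1L || fs_out <= 0) {
    abort("`fs_out` must be a positive scalar (Hz)")
  }
  if (abs(fs_out - sig$fs) < 1e-9) return(sig)
  frac <- .rat_approx(fs_out / sig$fs)
  y <- signal::resample(sig$x, frac[1], frac[2])
  n_out <- round(length(sig$x) * fs_out / sig$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  signal_record(y, fs_out, sig$channel, sig$units)
}

# small-denominator rational approximation of a rate ratio
.rat_approx <- function(r, max_den = 4096L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  best
}

#' Synchronize two beat streams by RR-interval matching
#'
#' Finds the beat-index offset maximizing the correlation of the two RR
#' interval sequences, then converts it to a time lag (mean R-time
#' difference over the matched beats). Streams whose RR sequence has no
#' variance (e.g. fully paced rhythms) cannot be aligned this way and raise
#' a degenerate-input error.
#'
#' @param r_times_a,r_times_b R-wave times (s) of the two streams, each
#'   with at least 10 beats.
#' @return The lag in seconds such that `r_times_b + lag` aligns with
#'   `r_times_a`.
#' @export
align_by_rr <- function(r_times_a, r_times_b) {
  if (length(r_times_a) < 10L || length(r_times_b) < 10L) {
    abort("each stream needs at least 10 beats")
  }
  rr_a <- diff(r_times_a)
  rr_b <- diff(r_times_b)
  if (sd(rr_a) < 1e-9 || sd(rr_b) < 1e-9) {
    abort("degenerate input: RR intervals have no variance; RR matching impossible")
  }
  na <- length(rr_a); nb <- length(rr_b)
  # require a substantial overlap so a short coincidental match cannot win
  min_ov <- max(5L, floor(min(na, nb) / 2))
  best_k <- 0L; best_c <- -Inf
  for (k in seq(-(nb - min_ov), na - min_ov)) {
    ia <- max(1L, 1L + k):min(na, nb + k)
    ib <- ia - k
    if (length(ia) < min_ov) next
    a <- rr_a[ia]; b <- rr_b[ib]
    if (sd(a) < 1e-12 || sd(b) < 1e-12) next
    cc <- sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sd(a) * sd(b))
    if (cc > best_c) { best_c <- cc; best_k <- k }
  }
  ia <- max(1L, 1L + best_k):min(na, nb + best_k)
  ib <- ia - best_k
  mean(r_times_a[ia + 1L] - r_times_b[ib + 1L])
}
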