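#' Detect R waves with a simplified Pan-Tompkins chain
#'
#' Band-pass 5-15 Hz, five-point derivative, squaring, 150 ms moving-window
#' integration, adaptive signal/noise-peak thresholding with a 250 ms
#' refractory period. Each detection is then localized to the R maximum of
#' the raw ECG within +/-50 ms. All filtering stages are zero-phase so the
#' reported times carry no group delay.
#'
#' @param ecg A [signal_record()] at least 5 s long.
#' @return Numeric vector of R-wave times (s); empty (with a warning) for a
#'   flat signal.
#' @export
detect_r_peaks <- function(ecg) {
  assert_signal(ecg, "ecg")
  fs <- ecg$fs
  if (duration(ecg) < 5) abort("ECG must be at least 5 s long")
  x <- ecg$x
  if (sd(x) < 1e-12) {
    warn("flat ECG: no R peaks detected")
    return(numeric(0))
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # five-point derivative (zero-phase: symmetric kernel)
  dx <- stats::filter(xf, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  dx[is.na(dx)] <- 0
  sq <- as.numeric(dx)^2
  w <- max(1L, as.integer(round(0.150 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima at least 200 ms apart
  refr <- as.integer(round(0.250 * fs))
  half <- max(1L, as.integer(round(0.100 * fs)))
  n <- length(mwi)
  is_max <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_max)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    lo <- max(1L, cand[i] - half); hi <- min(n, cand[i] + half)
    keep[i] <- mwi[cand[i]] >= max(mwi[lo:hi])
  }
  cand <- cand[keep]

  init <- mwi[seq_len(min(n, 2L * round(fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init)
  peaks <- integer(0)
  last <- -Inf
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] > thr && (p - last) > refr) {
      peaks <- c(peaks, p)
      last <- p
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  if (!length(peaks)) {
    warn("no R peaks found above the adaptive threshold")
    return(numeric(0))
  }
  # localize on the raw ECG within +/-50 ms of the integrated-peak crossing
  hw <- as.integer(round(0.050 * fs))
  r_idx <- vapply(peaks, function(p) {
    lo <- max(1L, p - hw); hi <- min(length(x), p + hw)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  sort(unique(r_idx - 1L)) / fs
}

#' Label beat types from the ECG
#'
#' Rule-based surrogate for expert labelling: a beat is `paced` when a
#' narrow (<10 ms at half height), large (>= 5x the local baseline scale)
#' stimulus spike precedes the R wave by less than 80 ms; `pvc` when the
#' measured QRS envelope is at least 120 ms wide without a spike; otherwise
#' `intrinsic`.
#'
#' @param ecg A [signal_record()].
#' @param r_times R-wave times (s).
#' @return Character vector of labels, one per R time.
#' @export
label_beat_types <- function(ecg, r_times) {
  assert_signal(ecg, "ecg")
  fs <- ecg$fs
  x <- ecg$x
  n <- length(x)
  win <- function(lo, hi) {
    i <- (floor(lo * fs):ceiling(hi * fs)) + 1L
    i[i >= 1L & i <= n]
  }
  smooth_abs <- function(v) {
    k <- max(1L, round(0.010 * fs))
    out <- as.numeric(stats::filter(abs(v), rep(1 / k, k), sides = 2))
    out[is.na(out)] <- 0
    out
  }
  vapply(r_times, function(r) {
    r_amp <- abs(x[min(n, max(1L, round(r * fs) + 1L))])
    if (!is.finite(r_amp) || r_amp == 0) return("intrinsic")
    # pacing spike: narrow outlier well before the QRS upstroke
    pre <- win(r - 0.100, r - 0.035)
    iso <- win(r - 0.350, r - 0.250)
    base_scale <- if (length(iso)) mad(x[iso], constant = 1.4826) else 0
    base_scale <- max(base_scale, 0.04 * r_amp)
    spike <- FALSE
    if (length(pre)) {
      pk <- pre[which.max(abs(x[pre]))]
      if (abs(x[pk]) >= 5 * base_scale) {
        above <- abs(x[pre]) >= abs(x[pk]) / 2
        runs <- rle(above)
        wpk <- max(runs$lengths[runs$values], 0) / fs
        spike <- wpk < 0.010
      }
    }
    if (spike) return("paced")
    # QRS width: span between first and last excursion above 15% of |R|
    # (a span, not a contiguous run: Q-R and R-S zero crossings dip through
    # the baseline inside a wide complex)
    qw <- win(r - 0.120, r + 0.150)
    env <- smooth_abs(x[qw])
    above <- which(env > 0.15 * r_amp)
    if (length(above) < 2L) return("intrinsic")
    if ((max(above) - min(above)) / fs >= 0.120) "pvc" else "intrinsic"
  }, character(1))
}

#' Crop 700-sample heartbeats from the BCG
#'
#' Each heartbeat is the 700 samples (700 ms at the required 1000 Hz)
#' beginning at the R wave. Beats whose crop would run past the end of the
#' record are dropped with a warning.
#'
#' @param bcg A [signal_record()] sampled at 1000 Hz.
#' @param r_times R-wave times (s).
#' @return A beats x 700 matrix with attribute `r_times` giving the kept
#'   beat times.
#' @export
crop_heartbeats <- function(bcg, r_times) {
  assert_signal(bcg, "bcg")
  if (abs(bcg$fs - 1000) > 1e-9) {
    abort("`bcg` must be sampled at 1000 Hz (the 700-sample crop is defined at this rate)")
  }
  idx0 <- round(r_times * 1000)
  ok <- idx0 >= 0 & (idx0 + 700L) <= length(bcg$x)
  if (any(!ok)) {
    warn(sprintf("%d beat(s) dropped: crop extends past the record boundary", sum(!ok)))
  }
  if (!any(ok)) abort("no beats lie fully inside the record")
  kept <- idx0[ok]
  m <- t(vapply(kept, function(i) bcg$x[(i + 1L):(i + 700L)], numeric(700)))
  attr(m, "r_times") <- r_times[ok]
  m
}

#' Select analysis epochs of the dominant beat type
#'
#' The dominant type is the majority label over the record (ties broken
#' toward intrinsic). Non-overlapping 20-s windows containing only
#' dominant-type beats are placed greedily left to right on a 1-s start
#' grid; if fewer than `n_epochs` pure windows exist, the remaining epochs
#' are the non-overlapping windows with the fewest non-dominant beats,
#' whose non-dominant beats are excluded from the admitted set. Each epoch
#' must admit at least `min_beats` beats.
#'
#' @param beats A tibble/data frame with columns `time` (R time, s) and
#'   `type`.
#' @param record_length Record length (s).
#' @param n_epochs Number of epochs to place (default 5).
#' @param epoch_s Epoch duration (fixed at 20 s in the analysis).
#' @param min_beats Minimum admitted beats per epoch (default 8, so an 8-s
#'   ensemble window always holds at least one beat).
#' @return A tibble: `epoch_id`, `start`, `end`, `dominant`, `n_admitted`,
#'   `admitted` (list-column of row indices into `beats`).
#' @export
select_epochs <- function(beats, record_length, n_epochs = 5L, epoch_s = 20,
                          min_beats = 8L) {
  if (n_epochs == 0L) {
    return(tibble::tibble(epoch_id = integer(0), start = numeric(0), end = numeric(0),
                          dominant = character(0), n_admitted = integer(0),
                          admitted = list()))
  }
  if (record_length < n_epochs * epoch_s) {
    abort("record shorter than n_epochs x 20 s of usable signal")
  }
  tab <- table(beats$type)
  dominant <- if ("intrinsic" %in% names(tab) && tab[["intrinsic"]] == max(tab)) {
    "intrinsic"
  } else {
    names(tab)[which.max(tab)]
  }
  starts_grid <- seq(0, floor(record_length - epoch_s))
  win_info <- lapply(starts_grid, function(s) {
    in_win <- which(beats$time >= s & beats$time < s + epoch_s)
    dom <- in_win[beats$type[in_win] == dominant]
    list(start = s, idx = in_win, dom = dom, n_bad = length(in_win) - length(dom))
  })

  chosen <- list()
  overlaps <- function(s) {
    any(vapply(chosen, function(w) s < w$start + epoch_s && w$start < s + epoch_s,
               logical(1)))
  }
  # pass 1: greedy left-to-right pure windows
  for (w in win_info) {
    if (length(chosen) >= n_epochs) break
    if (w$n_bad == 0L && length(w$dom) >= min_beats && !overlaps(w$start)) {
      chosen <- c(chosen, list(w))
    }
  }
  # pass 2: fill with the least-contaminated remaining windows
  if (length(chosen) < n_epochs) {
    rest <- win_info[order(vapply(win_info, `[[`, numeric(1), "n_bad"),
                           vapply(win_info, `[[`, numeric(1), "start"))]
    for (w in rest) {
      if (length(chosen) >= n_epochs) break
      if (length(w$dom) >= min_beats && !overlaps(w$start)) chosen <- c(chosen, list(w))
    }
  }
  # pass 3: greedy placement can paint itself into a corner on short
  # records; fall back to a regular 20-s tiling and exclude the
  # non-dominant beats inside it
  if (length(chosen) < n_epochs) {
    tiles <- win_info[vapply(win_info, function(w) {
      w$start %% epoch_s == 0 && length(w$dom) >= min_beats
    }, logical(1))]
    if (length(tiles) >= n_epochs) {
      tiles <- tiles[order(vapply(tiles, `[[`, numeric(1), "n_bad"),
                           vapply(tiles, `[[`, numeric(1), "start"))]
      chosen <- tiles[seq_len(n_epochs)]
    }
  }
  if (length(chosen) < n_epochs) {
    abort(sprintf(
      "epoch selection failed: only %d of %d windows with >= %d admitted beats",
      length(chosen), n_epochs, min_beats))
  }
  chosen <- chosen[order(vapply(chosen, `[[`, numeric(1), "start"))]
  tibble::tibble(
    epoch_id = seq_along(chosen),
    start = vapply(chosen, `[[`, numeric(1), "start"),
    end = vapply(chosen, `[[`, numeric(1), "start") + epoch_s,
    dominant = dominant,
    n_admitted = vapply(chosen, function(w) length(w$dom), integer(1)),
    admitted = lapply(chosen, `[[`, "dom")
  )
}
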