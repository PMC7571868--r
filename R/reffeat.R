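#' Rule-based ECG delineation
#'
#' For each beat: Q is where the signal last returns to baseline (3% of the
#' local R amplitude) walking back from the Q trough, within 80 ms before
#' R; S is the first return to baseline after the S trough, within 120 ms
#' after R; T end comes from the tangent method — the line through the
#' steepest point of the T downslope intersected with the baseline — in
#' `[S + 80 ms, S + 400 ms]`. Beats whose T wave is too flat to delineate
#' are flagged (`NA` fiducial) and excluded from interval features.
#'
#' @param ecg A clean or denoised [signal_record()].
#' @param r_times Detected R-wave times (s).
#' @return A tibble: `time` (R), `q`, `s`, `t_end` (absolute s; `NA` where
#'   a fiducial could not be found).
#' @export
delineate <- function(ecg, r_times) {
  assert_signal(ecg, "ecg")
  fs <- ecg$fs
  x <- ecg$x
  n <- length(x)
  at <- function(t) min(n, max(1L, round(t * fs) + 1L))
  win <- function(lo, hi) {
    i <- (floor(lo * fs):ceiling(hi * fs)) + 1L
    i[i >= 1L & i <= n]
  }
  # light smoothing for slope estimates
  k <- max(3L, round(0.008 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  slope <- c(0, diff(xs)) * fs

  one <- function(r) {
    ri <- at(r)
    r_amp <- abs(x[ri])
    thr <- 0.03 * r_amp
    q_t <- NA_real_; s_t <- NA_real_; t_t <- NA_real_
    # Q: trough then walk back to baseline, window [R-80ms, R-8ms]
    qw <- win(r - 0.080, r - 0.008)
    if (length(qw) > 2) {
      tr <- qw[which.min(x[qw])]
      i <- tr
      while (i > qw[1] && abs(x[i]) >= thr) i <- i - 1L
      if (abs(x[i]) < thr) q_t <- (i - 1L) / fs
    }
    # S: trough then walk forward to baseline, window [R+8ms, R+120ms]
    sw <- win(r + 0.008, r + 0.120)
    if (length(sw) > 2) {
      tr <- sw[which.min(x[sw])]
      i <- tr
      while (i < sw[length(sw)] && abs(x[i]) >= thr) i <- i + 1L
      if (abs(x[i]) < thr) s_t <- (i - 1L) / fs
    }
    # T end: tangent method on the downslope after the T apex
    if (!is.na(s_t)) {
      tw <- win(s_t + 0.080, s_t + 0.400)
      if (length(tw) > 10) {
        apex <- tw[which.max(abs(xs[tw]))]
        t_amp <- xs[apex]
        if (abs(t_amp) >= 5 * thr) {
          seg <- apex:min(n, apex + round(0.150 * fs))
          m_i <- if (t_amp > 0) seg[which.min(slope[seg])] else seg[which.max(slope[seg])]
          s_m <- slope[m_i]
          if (is.finite(s_m) && abs(s_m) > 1e-9) {
            cand <- (m_i - 1L) / fs - xs[m_i] / s_m
            if (cand > (apex - 1L) / fs && cand < (apex - 1L) / fs + 0.4) t_t <- cand
          }
        }
      }
    }
    c(q = q_t, s = s_t, t_end = t_t)
  }
  out <- t(vapply(r_times, one, numeric(3)))
  tibble::tibble(time = as.numeric(r_times), q = out[, "q"], s = out[, "s"],
                 t_end = out[, "t_end"])
}

#' Per-beat interval features with linear QT correction
#'
#' Computes RR (from the second beat on), QRS = S - Q, QT_BASE = Tend - Q,
#' QT_QRS = QT_BASE minus the portion of QRS exceeding 120 ms, and the
#' rate-corrected `QTc = QT + 0.154 (1 - RR)` (Framingham linear
#' correction; RR and QT in seconds) for both QT variants.
#'
#' @param fiducials A tibble from [delineate()] (columns `time`, `q`, `s`,
#'   `t_end`).
#' @param r_times Optional R times; defaults to `fiducials$time`.
#' @return A tibble of per-beat intervals (seconds): `time`, `rr`, `qrs`,
#'   `qt_base`, `qt_qrs`, `qtc_base`, `qtc_qrs`.
#' @export
beat_intervals <- function(fiducials, r_times = fiducials$time) {
  stopifnot(all(c("q", "s", "t_end") %in% names(fiducials)))
  rr <- c(NA_real_, diff(r_times))
  qrs <- fiducials$s - fiducials$q
  qt_base <- fiducials$t_end - fiducials$q
  qt_qrs <- qt_base - pmax(0, qrs - 0.120)
  qtc <- function(qt) qt + 0.154 * (1 - rr)
  tibble::tibble(time = as.numeric(r_times), rr = rr, qrs = qrs,
                 qt_base = qt_base, qt_qrs = qt_qrs,
                 qtc_base = qtc(qt_base), qtc_qrs = qtc(qt_qrs))
}

#' Correct a continuous blood-pressure series against cuff readings
#'
#' For each cuff reading, the difference between the cuff value and the
#' mean of the device samples over the preceding 60 s is computed; the mean
#' of these differences (five over a five-minute record) is the constant
#' added to the whole device series. SBP and DBP are corrected
#' independently by calling this once per series.
#'
#' @param device A tibble with columns `time` and `value` (beat-to-beat
#'   device readings, mmHg).
#' @param cuff A tibble with columns `time` and `value` (periodic cuff
#'   readings, mmHg).
#' @return A list: `corrected` (tibble like `device`), `constant` (mmHg),
#'   `differences` (one per usable cuff reading).
#' @export
bp_offset_correction <- function(device, cuff) {
  stopifnot(all(c("time", "value") %in% names(device)),
            all(c("time", "value") %in% names(cuff)))
  if (nrow(cuff) < 1L) abort("need at least one cuff reading")
  diffs <- vapply(seq_len(nrow(cuff)), function(i) {
    sel <- device$time >= cuff$time[i] - 60 & device$time < cuff$time[i]
    if (!any(sel)) return(NA_real_)
    cuff$value[i] - mean(device$value[sel])
  }, numeric(1))
  if (anyNA(diffs)) {
    warn(sprintf("%d cuff window(s) without device samples skipped", sum(is.na(diffs))))
  }
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs)) abort("no cuff window contained device samples; cannot correct")
  constant <- mean(diffs)
  list(corrected = dplyr::mutate(device, value = .data$value + constant),
       constant = constant, differences = diffs)
}

#' Windowed epoch statistics of a per-beat feature series
#'
#' Mirrors the ensemble windowing: the feature values of the beats inside
#' each retained sliding window (same start convention, duplicate-set and
#' empty-window handling as [sliding_ensemble_averages()]) are averaged;
#' the window means then give the epoch mean and SD, and all three
#' statistics are natural-log transformed (the SD with the same `1e-12`
#' floor as the WFMR). An epoch with fewer than two retained windows has no
#' SD and is flagged.
#'
#' @param values Per-beat feature values (`NA` allowed: beats excluded by
#'   delineation failure drop out of their windows' means).
#' @param times Beat times (s), same length as `values`.
#' @param epochs An epoch table from [select_epochs()].
#' @param t_ea Window size (s), default 8 to match the WFMR analysis.
#' @return A tibble: `epoch_id`, `n_windows`, `window_means` (list-column,
#'   log scale), `mean_log`, `sd_log`, `flagged`.
#' @export
windowed_stats <- function(values, times, epochs, t_ea = 8) {
  stopifnot(length(values) == length(times))
  purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    adm <- epochs$admitted[[i]]
    t_adm <- times[adm]
    v_adm <- values[adm]
    w <- window_beat_sets(t_adm, epochs$start[i], t_ea)
    wm <- vapply(w$sets, function(s) mean(v_adm[s], na.rm = TRUE), numeric(1))
    wm <- wm[is.finite(wm)]
    nw <- length(wm)
    m <- if (nw) mean(wm) else NA_real_
    s <- if (nw >= 2L) sd(wm) else NA_real_
    tibble::tibble(
      epoch_id = epochs$epoch_id[i],
      n_windows = nw,
      window_means = list(log(pmax(.wfmr_eps, wm))),
      mean_log = if (is.na(m)) NA_real_ else log(max(.wfmr_eps, m)),
      sd_log = if (is.na(s)) NA_real_ else log(max(.wfmr_eps, s)),
      flagged = nw < 2L
    )
  })
}

#' Reference feature table for a rendered subject
#'
#' Full chain: delineation on the (denoised) ECG, per-beat intervals, BP
#' offset correction, then windowed epoch statistics for every reference
#' feature, mirroring the WFMR windowing.
#'
#' @param subject A rendered `subject_record`.
#' @param t_ea Window size (s), default 8.
#' @param n_epochs Epochs, default 5.
#' @param use_truth_beats Use ground-truth beat times/types (default) or
#'   run detection and labelling.
#' @return A long tibble: `epoch_id`, `feature`, `n_windows`, `mean_log`,
#'   `sd_log`, `flagged`.
#' @export
reference_features <- function(subject, t_ea = 8, n_epochs = 5L,
                               use_truth_beats = TRUE) {
  stopifnot(inherits(subject, "subject_record"))
  if (is.null(subject$ecg)) abort("subject must be rendered (render = TRUE)")
  if (use_truth_beats) {
    r_times <- subject$schedule$time
    types <- subject$schedule$type
  } else {
    r_times <- detect_r_peaks(subject$ecg)
    types <- label_beat_types(subject$ecg, r_times)
  }
  beats <- tibble::tibble(time = r_times, type = types)
  epochs <- select_epochs(beats, record_length = subject$config$length_s,
                          n_epochs = n_epochs)
  fid <- delineate(subject$ecg, r_times)
  iv <- beat_intervals(fid, r_times)
  bp_s <- bp_offset_correction(
    dplyr::transmute(subject$bp$beat, time = .data$time, value = .data$sbp),
    dplyr::transmute(subject$bp$cuff, time = .data$time, value = .data$sbp))
  bp_d <- bp_offset_correction(
    dplyr::transmute(subject$bp$beat, time = .data$time, value = .data$dbp),
    dplyr::transmute(subject$bp$cuff, time = .data$time, value = .data$dbp))
  feats <- list(
    rr = iv$rr, qrs = iv$qrs, qt_base = iv$qt_base, qt_qrs = iv$qt_qrs,
    qtc_base = iv$qtc_base, qtc_qrs = iv$qtc_qrs,
    sbp = bp_s$corrected$value, dbp = bp_d$corrected$value
  )
  purrr::imap_dfr(feats, function(v, nm) {
    st <- suppressWarnings(windowed_stats(v, r_times, epochs, t_ea))
    dplyr::mutate(st[, c("epoch_id", "n_windows", "mean_log", "sd_log", "flagged")],
                  feature = nm, .after = "epoch_id")
  })
}
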