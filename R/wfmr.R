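#' Sliding ensemble windows within an epoch
#'
#' Window starts are `epoch_start + 0, 1, ..., epoch_s - t_ea - 1` seconds
#' (the window whose end coincides with the epoch boundary is not
#' generated); a beat belongs to a window iff its R time lies in
#' `[start, start + t_ea)`. Windows with no beats are dropped with a
#' warning, and windows whose beat-index set duplicates an earlier window's
#' are removed.
#'
#' @param r_times Admitted beat R times (s).
#' @param epoch_start Epoch start (s).
#' @param t_ea Window size (s), in `[2, 15]`.
#' @param epoch_s Epoch duration (default 20 s).
#' @return A list with `starts` and `sets` (beat-index sets per retained
#'   window, indices into `r_times`).
#' @keywords internal
window_beat_sets <- function(r_times, epoch_start, t_ea, epoch_s = 20) {
  if (t_ea < 2 || t_ea > 15) abort("`t_ea` must lie in [2, 15] s")
  if (t_ea >= epoch_s) abort("`t_ea` must be smaller than the epoch duration")
  starts <- epoch_start + seq(0, epoch_s - t_ea - 1)
  sets <- lapply(starts, function(s) which(r_times >= s & r_times < s + t_ea))
  nonempty <- lengths(sets) > 0L
  if (any(!nonempty)) warn(sprintf("%d empty window(s) dropped", sum(!nonempty)))
  starts <- starts[nonempty]; sets <- sets[nonempty]
  key <- vapply(sets, paste, character(1), collapse = ",")
  first <- !duplicated(key)
  list(starts = starts[first], sets = sets[first])
}

#' Ensemble average of heartbeats
#'
#' Sample-wise mean of R-aligned cropped heartbeats: suppresses everything
#' not phase-locked to the cardiac cycle.
#'
#' @param beats A beats x 700 matrix (one cropped heartbeat per row).
#' @return A 700-sample waveform.
#' @export
ensemble_average <- function(beats) {
  if (is.null(dim(beats))) beats <- matrix(beats, nrow = 1)
  if (nrow(beats) < 1L) abort("empty window: no heartbeats to average")
  colMeans(beats)
}

#' Sliding-window ensemble averages of one epoch
#'
#' @param crops A beats x 700 crop matrix with attribute `r_times` (as from
#'   [crop_heartbeats()]), or with `r_times` supplied explicitly.
#' @param epoch One row of the [select_epochs()] table (or any list with
#'   `start` and `admitted`).
#' @param t_ea Ensemble window size (s).
#' @param r_times Beat times; defaults to `attr(crops, "r_times")`.
#' @param epoch_s Epoch duration (default 20 s).
#' @return An `ensemble_set`: `waveforms` (N_Total x 700 matrix), `sets`
#'   (beat-index sets), `n_total`, `t_ea`, `start`.
#' @export
sliding_ensemble_averages <- function(crops, epoch, t_ea,
                                      r_times = attr(crops, "r_times"),
                                      epoch_s = 20) {
  if (is.null(r_times)) abort("beat times missing: supply `r_times`")
  admitted <- epoch$admitted
  if (is.list(admitted)) admitted <- admitted[[1]]
  if (is.null(admitted)) admitted <- seq_along(r_times)
  t_adm <- r_times[admitted]
  w <- window_beat_sets(t_adm, epoch$start, t_ea, epoch_s)
  if (!length(w$sets)) abort("invalid epoch: no window retains a beat")
  waves <- t(vapply(w$sets, function(s) {
    ensemble_average(crops[admitted[s], , drop = FALSE])
  }, numeric(ncol(crops))))
  structure(list(waveforms = waves, sets = w$sets, starts = w$starts,
                 n_total = nrow(waves), t_ea = t_ea, start = epoch$start),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> t_ea=%g s, N_Total=%d, epoch start %g s\n",
              x$t_ea, x$n_total, x$start))
  invisible(x)
}

#' Mean square error between two waveforms
#'
#' The raw sum of squared sample differences over the 700-sample support
#' (no division by the sample count; the constant offset this induces on
#' the log scale cancels in every between-group comparison).
#'
#' @param f,g Equal-length numeric waveforms.
#' @return `sum((f - g)^2)`.
#' @export
mse <- function(f, g) {
  if (length(f) != length(g)) abort("`f` and `g` must have equal length")
  sum((f - g)^2)
}

#' Waveform fluctuation metric of one epoch
#'
#' The natural log of the mean MSE over all ordered off-diagonal pairs of
#' the epoch's ensemble averages,
#' `ln( (1 / (N (N - 1))) * sum_{i != j} MSE_ij )`,
#' floored at `ln(1e-12)` so a zero-fluctuation epoch stays finite.
#'
#' @param es An `ensemble_set` from [sliding_ensemble_averages()], or a
#'   waveform matrix (rows = ensemble averages).
#' @return The WFMR value (dimensionless, natural-log scale).
#' @export
wfmr_epoch <- function(es) {
  w <- if (inherits(es, "ensemble_set")) es$waveforms else as.matrix(es)
  n <- nrow(w)
  if (n < 2L) abort("invalid epoch: need at least two ensemble averages")
  d2 <- as.matrix(stats::dist(w))^2  # squared L2 = per-pair MSE sum
  mean_off <- sum(d2) / (n * (n - 1))
  log(max(.wfmr_eps, mean_off))
}

#' Per-epoch WFMR for a cohort of simulated subjects
#'
#' Runs epoch selection and the sliding-window ensemble/WFMR chain for
#' every subject of a [simulate_cohort()] tibble. Unrendered subjects use
#' the ground-truth beat schedule and render only the admitted beats'
#' crops; rendered subjects are cropped from their (noisy) BCG channel.
#'
#' @param cohort A tibble with columns `subject_id`, `population`,
#'   `subject`.
#' @param t_ea Ensemble window size (s), default 8.
#' @param n_epochs Epochs per subject, default 5.
#' @return A tibble: `subject_id`, `population`, `epoch_id`, `t_ea`,
#'   `n_total`, `wfmr`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_nonclinical = 2, n_clinical = 2, seed = 3)
#' wfmr_features(coh)
wfmr_features <- function(cohort, t_ea = 8, n_epochs = 5L) {
  stopifnot(all(c("subject_id", "population", "subject") %in% names(cohort)))
  purrr::pmap_dfr(cohort[c("subject_id", "population", "subject")],
                  function(subject_id, population, subject) {
    res <- subject_wfmr(subject, t_ea = t_ea, n_epochs = n_epochs)
    dplyr::mutate(res, subject_id = subject_id, population = population,
                  .before = 1)
  })
}

#' @rdname wfmr_features
#' @param subject A `subject_record`.
#' @export
subject_wfmr <- function(subject, t_ea = 8, n_epochs = 5L) {
  stopifnot(inherits(subject, "subject_record"))
  sched <- subject$schedule
  epochs <- select_epochs(sched, record_length = subject$config$length_s,
                          n_epochs = n_epochs)
  if (is.null(subject$bcg)) {
    admitted_all <- sort(unique(unlist(epochs$admitted)))
    crops_sub <- suppressWarnings(
      simulate_bcg_crops(subject$config, sched, which = admitted_all))
    crops <- matrix(NA_real_, nrow = nrow(sched), ncol = 700L)
    crops[admitted_all, ] <- crops_sub
    r_times <- sched$time
  } else {
    crops <- suppressWarnings(crop_heartbeats(subject$bcg, sched$time))
    r_times <- attr(crops, "r_times")
  }
  purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    es <- suppressWarnings(
      sliding_ensemble_averages(crops, epochs[i, ], t_ea, r_times = r_times))
    tibble::tibble(epoch_id = epochs$epoch_id[i], t_ea = t_ea,
                   n_total = es$n_total, wfmr = wfmr_epoch(es))
  })
}

#' Window-size sweep of the mean WFMR
#'
#' For each window size 2..15 s: per-subject mean over epochs, then the
#' grand mean over subjects (subjects weighted equally regardless of epoch
#' count).
#'
#' @param features Either a cohort tibble (see [simulate_cohort()]) or a
#'   precomputed long feature table with columns `subject_id`, `t_ea`,
#'   `wfmr`.
#' @param t_ea_grid Window sizes to evaluate (default 2:15 s).
#' @param n_epochs Epochs per subject when computing from a cohort.
#' @return A tibble of class `wfmr_sweep`: `t_ea`, `wfmr` (grand mean).
#' @export
wfmr_sweep <- function(features, t_ea_grid = 2:15, n_epochs = 5L) {
  if (!is.data.frame(features)) abort("`features` must be a data frame")
  if (!nrow(features)) abort("empty cohort")
  if ("subject" %in% names(features)) {
    features <- purrr::map_dfr(t_ea_grid, function(tt) {
      wfmr_features(features, t_ea = tt, n_epochs = n_epochs)
    })
  }
  stopifnot(all(c("subject_id", "t_ea", "wfmr") %in% names(features)))
  out <- features |>
    dplyr::group_by(.data$t_ea, .data$subject_id) |>
    dplyr::summarise(wfmr = mean(.data$wfmr), .groups = "drop_last") |>
    dplyr::summarise(wfmr = mean(.data$wfmr), .groups = "drop") |>
    dplyr::arrange(.data$t_ea)
  class(out) <- c("wfmr_sweep", class(out))
  out
}

#' Pick the ensemble window size at the sweep curve's elbow
#'
#' The optimal window is the smallest size whose marginal decrease
#' (`curve[T] - curve[T + 1]`) falls below `frac` (default 10%) of the
#' total decrease over the sweep; if no marginal drop is that small the
#' largest window is returned, and a flat or non-decreasing curve returns
#' the smallest.
#'
#' @param curve A `wfmr_sweep` tibble (columns `t_ea`, `wfmr`) with at
#'   least 3 points.
#' @param frac Elbow criterion as a fraction of the total decrease.
#' @return The selected window size (s).
#' @export
select_optimal_window <- function(curve, frac = 0.10) {
  stopifnot(is.data.frame(curve), all(c("t_ea", "wfmr") %in% names(curve)))
  if (nrow(curve) < 3L) abort("`curve` needs at least 3 points")
  if (any(!is.finite(curve$wfmr))) abort("non-finite curve values")
  curve <- curve[order(curve$t_ea), ]
  y <- curve$wfmr
  total <- y[1] - y[length(y)]
  if (total <= 0) return(curve$t_ea[1])
  marg <- -diff(y)
  hit <- which(marg < frac * total)
  if (!length(hit)) curve$t_ea[nrow(curve)] else curve$t_ea[hit[1]]
}

#' @exportS3Method ggplot2::autoplot
autoplot.wfmr_sweep <- function(object, ...) {
  t_star <- select_optimal_window(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ea, y = .data$wfmr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = t_star, linetype = "dashed") +
    ggplot2::labs(x = "ensemble window size (s)", y = "mean WFMR",
                  title = sprintf("WFMR window sweep (elbow at %g s)", t_star))
}

#' Plot the per-subject WFMR distribution by population
#'
#' @param features A WFMR feature table from [wfmr_features()].
#' @return A ggplot box plot.
#' @export
plot_wfmr_distribution <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$population, y = .data$wfmr)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "WFMR (ln scale)")
}
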