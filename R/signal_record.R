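#' Single-channel physiological signal
#'
#' A `signal_record` bundles one channel's samples with its sampling rate,
#' channel role and units. All time arguments elsewhere in the package are in
#' seconds; a sample at time `t` has 0-based index `round(t * fs)`.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel Channel role, e.g. `"bcg"`, `"ecg"`, `"sbp"`, `"dbp"`.
#' @param units Unit string, kept for provenance only.
#'
#' @return An object of class `signal_record`.
#' @export
#' @examples
#' s <- signal_record(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000, channel = "ecg")
#' duration(s)
signal_record <- function(x, fs, channel = "signal", units = "a.u.") {
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz)")
  }
  structure(
    list(x = as.numeric(x), fs = as.numeric(fs),
         channel = as.character(channel)[1], units = as.character(units)[1]),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> channel=%s fs=%g Hz n=%d (%.3f s) units=%s\n",
              x$channel, x$fs, length(x$x), duration(x), x$units))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$x)

#' Duration of a signal record in seconds
#' @param x A `signal_record`.
#' @return Duration in seconds (`n / fs`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  length(x$x) / x$fs
}

#' Convert a signal record to a tibble
#'
#' @param x A `signal_record`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s) and `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.signal_record <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$x) - 1) / x$fs, value = x$x)
}

is_signal_record <- function(x) inherits(x, "signal_record")

assert_signal <- function(x, what = "signal") {
  if (!is_signal_record(x)) abort(sprintf("`%s` must be a signal_record", what))
  if (length(x$x) == 0L) abort(sprintf("`%s` is empty", what))
  invisible(x)
}
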