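#' Write a subject record as delimited text
#'
#' Signals go to `<id>.tsv` in long format (`channel`, `value`) preceded by
#' `# channel=<role> fs=<Hz> units=<u>` metadata lines, one per channel;
#' blood pressure to `<id>_bp.tsv` and `<id>_cuff.tsv`; ground truth to the
#' sidecar `<id>_truth.tsv` (beat time, type, Q/S/T-end fiducials).
#'
#' @param subject A rendered `subject_record`.
#' @param dir Output directory (created if missing).
#' @param id Record id used as the file stem.
#' @return Invisibly, the paths written.
#' @export
write_record <- function(subject, dir, id = "subject") {
  stopifnot(inherits(subject, "subject_record"))
  if (is.null(subject$ecg)) abort("subject must be rendered (render = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(id, ".tsv"))
  channels <- list(bcg = subject$bcg, ecg = subject$ecg)
  con <- file(sig_path, "w")
  for (ch in channels) {
    writeLines(sprintf("# channel=%s fs=%g units=%s", ch$channel, ch$fs, ch$units), con)
  }
  writeLines("channel\tvalue", con)
  for (ch in channels) {
    writeLines(sprintf("%s\t%.10g", ch$channel, ch$x), con)
  }
  close(con)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    sig_path,
    tsv(subject$bp$beat, file.path(dir, paste0(id, "_bp.tsv"))),
    tsv(subject$bp$cuff, file.path(dir, paste0(id, "_cuff.tsv"))),
    tsv(subject$truth, file.path(dir, paste0(id, "_truth.tsv")))
  )
  invisible(paths)
}

#' Read a delimited-text signal record
#'
#' Parses the format written by [write_record()]: `#` metadata lines
#' declaring each channel's sampling rate, a `channel<TAB>value` header,
#' then one sample per line. A file without the header or without a
#' sampling-rate declaration for a channel is a format error; channels with
#' roles outside bcg/ecg/sbp/dbp are kept with a warning.
#'
#' @param path Path to the `.tsv` signal file.
#' @return A named list of [signal_record()]s keyed by channel role.
#' @export
read_record <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta_i <- grep("^#", lines)
  meta <- lines[meta_i]
  fs_map <- list()
  units_map <- list()
  for (m in meta) {
    ch <- sub(".*channel=(\\S+).*", "\\1", m)
    fs <- suppressWarnings(as.numeric(sub(".*fs=(\\S+).*", "\\1", m)))
    un <- if (grepl("units=", m)) sub(".*units=(\\S+).*", "\\1", m) else "a.u."
    if (!is.na(fs)) { fs_map[[ch]] <- fs; units_map[[ch]] <- un }
  }
  body <- lines[setdiff(seq_along(lines), meta_i)]
  if (!length(body) || !identical(strsplit(body[1], "\t")[[1]], c("channel", "value"))) {
    abort("format error: missing 'channel\\tvalue' header line")
  }
  body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ch_col <- vapply(parts, `[[`, character(1), 1L)
  val <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  out <- list()
  for (ch in unique(ch_col)) {
    if (is.null(fs_map[[ch]])) {
      abort(sprintf("format error: no sampling rate declared for channel '%s'", ch))
    }
    if (!ch %in% c("bcg", "ecg", "sbp", "dbp")) {
      warn(sprintf("unknown channel role '%s' kept as-is", ch))
    }
    out[[ch]] <- signal_record(val[ch_col == ch], fs_map[[ch]], ch, units_map[[ch]])
  }
  out
}
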