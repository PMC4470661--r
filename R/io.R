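# Plain-text interchange: recordings are a two- or three-column CSV plus a
# JSON metadata sidecar; events and masks are fixed-column-order CSVs.
# Numeric columns are written with "%.17g" so round trips are bit-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Construct a two-channel recording
#'
#' A recording holds the fetal-abdomen (FM) and maternal-thigh (MM)
#' acceleration channels, uniformly sampled at `sampling_rate`. Sample `i`
#' (1-based) is at time `start_offset + (i - 1) / sampling_rate` seconds.
#'
#' @param fm,mm numeric vectors of equal length (device units).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param gestational_week gestational age in weeks.
#' @param start_offset start time of sample 1 in seconds (default 0).
#' @return An object of class `fm_recording`.
#' @export
fm_recording <- function(fm, mm, sampling_rate, subject_id = "anon",
                         gestational_week = NA_integer_, start_offset = 0) {
  if (length(fm) != length(mm)) {
    stop_fm("fm_format_error", "fm and mm channels must have identical length")
  }
  if (length(fm) < 1L) stop_fm("fm_format_error", "recording must be non-empty")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_fm("fm_format_error", "sampling_rate must be positive")
  }
  structure(list(subject_id = as.character(subject_id),
                 gestational_week = as.integer(gestational_week),
                 sampling_rate = as.numeric(sampling_rate),
                 start_offset = as.numeric(start_offset),
                 fm = as.numeric(fm), mm = as.numeric(mm)),
            class = "fm_recording")
}

#' @export
print.fm_recording <- function(x, ...) {
  cat(sprintf("<fm_recording> subject %s, week %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$gestational_week, length(x$fm),
              x$sampling_rate, length(x$fm) / x$sampling_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `fm_recording`.
#' @export
recording_duration <- function(recording) {
  length(recording$fm) / recording$sampling_rate
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read / write a recording (CSV + JSON sidecar)
#'
#' The CSV holds columns `(fm, mm)` or `(time_s, fm, mm)`; the sidecar JSON
#' holds `sampling_rate`, `subject_id`, `gestational_week` and optionally
#' `start_offset`. When `time_s` is present it must be uniform at the
#' sidecar's rate within 1e-6 s.
#'
#' @param path CSV file path; the sidecar is `path` with `.json` extension.
#' @param recording an `fm_recording`.
#' @param write_time also write an explicit `time_s` column (default FALSE).
#' @return `read_recording` returns an `fm_recording`.
#' @export
read_recording <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(path)) stop_fm("fm_io_error", "recording CSV not found: %s", path)
  if (!file.exists(side)) stop_fm("fm_format_error", "metadata sidecar not found: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("sampling_rate", "subject_id", "gestational_week")) {
    if (is.null(meta[[field]])) {
      stop_fm("fm_format_error", "sidecar missing required field: %s", field)
    }
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("fm", "mm") %in% names(df))) {
    stop_fm("fm_format_error", "recording CSV must have fm and mm columns")
  }
  offset <- meta$start_offset %||% 0
  if ("time_s" %in% names(df) && nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(abs(dt - 1 / meta$sampling_rate) > 1e-6)) {
      stop_fm("fm_sampling_error",
              "time_s is not uniform at %g Hz within 1e-6 s", meta$sampling_rate)
    }
    offset <- df$time_s[1]
  }
  fm_recording(df$fm, df$mm, meta$sampling_rate, meta$subject_id,
               meta$gestational_week, offset)
}

#' @rdname read_recording
#' @export
write_recording <- function(recording, path, write_time = FALSE) {
  stopifnot(inherits(recording, "fm_recording"))
  cols <- list(fm = fmt_num(recording$fm), mm = fmt_num(recording$mm))
  if (write_time) {
    t <- recording$start_offset +
      (seq_along(recording$fm) - 1) / recording$sampling_rate
    cols <- c(list(time_s = fmt_num(t)), cols)
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = recording$subject_id,
               gestational_week = recording$gestational_week,
               sampling_rate = recording$sampling_rate,
               start_offset = recording$start_offset)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

EVENT_COLS <- c("channel", "start_s", "end_s", "peak_integral", "status", "reason")

#' Read / write event tables
#'
#' Events are one CSV row per detected burst with fixed column order
#' `channel, start_s, end_s, peak_integral, status, reason`. Writing
#' requires the events to be sorted by `start_s`; the round trip
#' `read_events(write_events(x))` is bit-identical.
#'
#' @param events event data frame (see [detect_candidate_events()]).
#' @param path CSV file path.
#' @export
write_events <- function(events, path) {
  stopifnot(all(EVENT_COLS %in% names(events)))
  assert_events_sorted(events)
  out <- events[, EVENT_COLS]
  out$start_s <- fmt_num(out$start_s)
  out$end_s <- fmt_num(out$end_s)
  out$peak_integral <- fmt_num(out$peak_integral)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_fm("fm_io_error", "events file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(channel = "character",
                                             start_s = "numeric",
                                             end_s = "numeric",
                                             peak_integral = "numeric",
                                             status = "character",
                                             reason = "character"))
  if (!identical(names(df), EVENT_COLS)) {
    stop_fm("fm_format_error", "events CSV must have columns: %s",
            paste(EVENT_COLS, collapse = ", "))
  }
  df$reason[is.na(df$reason)] <- ""
  df
}

#' Read / write analysis masks
#'
#' @param mask an `fm_mask` (see [build_mask()]).
#' @param path CSV file path. The mask's totals are stored in two comment
#'   header lines (`#total_recording_s=`, `#analysis_time_s=`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "fm_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#total_recording_s=%s", fmt_num(attr(mask, "total_recording_s"))),
               sprintf("#analysis_time_s=%s", fmt_num(attr(mask, "analysis_time_s")))),
             con)
  df <- as.data.frame(mask)
  df$start_s <- fmt_num(df$start_s)
  df$end_s <- fmt_num(df$end_s)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_fm("fm_io_error", "mask file not found: %s", path)
  hdr <- readLines(path, n = 2L)
  total <- as.numeric(sub("#total_recording_s=", "", hdr[1], fixed = TRUE))
  at <- as.numeric(sub("#analysis_time_s=", "", hdr[2], fixed = TRUE))
  df <- utils::read.csv(path, skip = 2L,
                        colClasses = c(start_s = "numeric", end_s = "numeric",
                                       reason = "character"))
  m <- new_mask(df, total)
  if (abs(attr(m, "analysis_time_s") - at) > 1e-9) {
    stop_fm("fm_format_error", "mask analysis_time_s inconsistent with intervals")
  }
  m
}
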