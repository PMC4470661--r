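# Inter-event-interval histogram QC. Respiration leaking past the filters
# piles intervals into the 3-5 s columns; hiccups pile into the 2 s column.
# Either pattern means detection should be re-run after adjusting the
# minimum integral thresholds.

#' Inter-event-interval histogram of accepted FM events
#'
#' Successive onset-to-onset intervals binned into 1.0-s half-open bins
#' `[0,1), ..., [39,40)` plus one overflow bin for intervals >= 40 s.
#'
#' @param events sorted event data frame; only `status == "accepted"` rows
#'   contribute.
#' @param cfg an [fm_config()] used for the artifact flag rule.
#' @return A list of class `fm_histogram` with `bin_edges` (0:40),
#'   `counts` (length 41, last = overflow), `n_events` and `flags`.
#' @export
interval_histogram <- function(events, cfg = fm_config()) {
  assert_events_sorted(events)
  onsets <- accepted(events)$start_s
  counts <- integer(41L)
  if (length(onsets) > 1L) {
    iv <- diff(onsets)
    bin <- pmin(floor(iv), 40)
    counts <- tabulate(bin + 1L, nbins = 41L)
  }
  h <- structure(list(bin_edges = 0:40, counts = counts,
                      n_events = length(onsets),
                      flags = list(respiration_suspect = FALSE,
                                   hiccup_suspect = FALSE)),
                 class = "fm_histogram")
  h$flags <- flag_artifacts(h, cfg)
  h
}

#' Raise artifact-suspect flags from an interval histogram
#'
#' `respiration_suspect` is raised when the mass in the 3-5 s columns
#' (bins `[3,6)`) exceeds `flag_factor` (default 3) times the median count
#' of the non-zero bins outside that band and is at least `flag_min_count`
#' (default 20); `hiccup_suspect` is the analogous rule for the 2-s column
#' (bin `[2,3)`). Deterministic surrogate for the visual "extremely high
#' column" judgment.
#'
#' @param hist an `fm_histogram`.
#' @param cfg an [fm_config()].
#' @return Named list of the two logical flags.
#' @export
flag_artifacts <- function(hist, cfg = fm_config()) {
  counts <- hist$counts
  band_flag <- function(band_bins) {
    s <- sum(counts[band_bins])
    others_nz <- counts[-band_bins]
    others_nz <- others_nz[others_nz > 0]
    ref <- if (length(others_nz)) stats::median(others_nz) else 0
    s > cfg$flag_factor * ref && s >= cfg$flag_min_count
  }
  list(respiration_suspect = band_flag(4:6),   # [3,4), [4,5), [5,6)
       hiccup_suspect = band_flag(3L))         # [2,3)
}

#' @export
print.fm_histogram <- function(x, ...) {
  cat(sprintf("<fm_histogram> %d events, %d intervals\n",
              x$n_events, sum(x$counts)))
  nz <- which(x$counts > 0)
  for (i in nz) {
    lab <- if (i == 41L) ">=40 s" else sprintf("[%d,%d) s", i - 1L, i)
    cat(sprintf("  %-9s %d\n", lab, x$counts[i]))
  }
  cat(sprintf("  flags: respiration_suspect=%s hiccup_suspect=%s\n",
              x$flags$respiration_suspect, x$flags$hiccup_suspect))
  invisible(x)
}

#' Write an interval histogram to CSV
#' @param hist an `fm_histogram`.
#' @param path CSV file path.
#' @export
write_histogram <- function(hist, path) {
  df <- data.frame(bin_start_s = c(0:40),
                   bin_end_s = c(1:40, Inf),
                   count = hist$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
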