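# Burst detection on 50-ms rectified integrals. A bin is supra-threshold
# when its integral exceeds ratio_threshold (200%) times the mean integral
# of the surrounding +/- baseline_window_s (excluding the bin itself,
# truncated at the series edges) AND clears the fixed channel minimum
# (15 FM / 20 MM device units). Runs of supra-threshold bins separated by
# gaps <= merge_gap_s merge into one event.

#' Rectified 50-ms bin integrals
#'
#' Converts a filtered acceleration series to per-bin integrals:
#' `values[k]` is the sum of `|sample|` over the samples falling in bin
#' `k` (half-open, bin k starts at `(k-1) * bin_s`). A trailing partial
#' bin is dropped. Non-integer samples-per-bin rates are handled by
#' flooring bin boundaries.
#'
#' @param signal numeric vector (filtered acceleration, device units).
#' @param sampling_rate Hz.
#' @param bin_ms bin width in milliseconds (default 50).
#' @param channel `"FM"` or `"MM"` label carried on the result.
#' @return A list of class `fm_integrals` with `channel`, `bin_s`, `values`.
#' @examples
#' compute_bin_integrals(rep(1, 100), 100)$values  # all 5.0
#' @export
compute_bin_integrals <- function(signal, sampling_rate, bin_ms = 50,
                                  channel = "FM") {
  spb <- sampling_rate * bin_ms / 1000
  if (spb < 1) {
    stop_fm("fm_config_error",
            "bin of %g ms holds less than one sample at %g Hz", bin_ms, sampling_rate)
  }
  n_bins <- floor(length(signal) / spb)
  if (n_bins < 1L) {
    return(structure(list(channel = channel, bin_s = bin_ms / 1000,
                          values = numeric(0)), class = "fm_integrals"))
  }
  cs <- c(0, cumsum(abs(signal)))
  hi <- floor(seq_len(n_bins) * spb)
  lo <- c(0L, hi[-n_bins])
  structure(list(channel = channel, bin_s = bin_ms / 1000,
                 values = cs[hi + 1L] - cs[lo + 1L]),
            class = "fm_integrals")
}

# Mean of the +/- window_bins around each bin, excluding the bin itself,
# truncated at the edges; floored at machine epsilon.
adaptive_baseline <- function(values, window_bins) {
  n <- length(values)
  cs <- c(0, cumsum(values))
  k <- seq_len(n)
  lo <- pmax(k - window_bins, 1L)
  hi <- pmin(k + window_bins, n)
  tot <- cs[hi + 1L] - cs[lo]          # includes bin k
  cnt <- hi - lo + 1L
  base <- (tot - values) / pmax(cnt - 1L, 1L)
  pmax(base, .Machine$double.eps)
}

#' Detect candidate movement events with the adaptive 200% rule
#'
#' @param integrals an `fm_integrals` (see [compute_bin_integrals()]).
#' @param cfg an [fm_config()]; uses `ratio_threshold`, `baseline_window_s`,
#'   `merge_gap_s`, `edge_transient_s` and the per-channel minimum
#'   (`min_integral_fm` / `min_integral_mm` according to the series channel).
#' @param total_s total recording duration in seconds, for the trailing
#'   edge-transient zone; defaults to the binned duration.
#' @return Event data frame with columns `channel, start_s, end_s,
#'   peak_integral, status, reason`; events within the first or last
#'   `edge_transient_s` seconds are `rejected` with reason
#'   `edge_transient`, all others `accepted`.
#' @export
detect_candidate_events <- function(integrals, cfg = fm_config(),
                                    total_s = NULL) {
  stopifnot(inherits(integrals, "fm_integrals"))
  v <- integrals$values
  if (length(v) == 0L) stop_fm("fm_input_error", "empty integral series")
  bin_s <- integrals$bin_s
  w <- round(cfg$baseline_window_s / bin_s)
  if (length(v) <= 2L * w) {
    stop_fm("fm_input_error",
            "series of %d bins too short for a %g s baseline window",
            length(v), cfg$baseline_window_s)
  }
  min_integral <- if (integrals$channel == "MM") cfg$min_integral_mm else cfg$min_integral_fm
  base <- adaptive_baseline(v, w)
  hit <- which(v > cfg$ratio_threshold * base & v >= min_integral & v > 0)
  if (length(hit) == 0L) return(empty_events())

  gap_bins <- round(cfg$merge_gap_s / bin_s)
  brk <- which(diff(hit) > gap_bins + 1L)
  first <- hit[c(1L, brk + 1L)]
  last <- hit[c(brk, length(hit))]
  peak <- vapply(seq_along(first),
                 function(i) max(v[first[i]:last[i]]), numeric(1))
  ev <- data.frame(channel = integrals$channel,
                   start_s = (first - 1L) * bin_s,
                   end_s = last * bin_s,
                   peak_integral = peak,
                   status = "accepted", reason = "",
                   stringsAsFactors = FALSE)
  total_s <- total_s %||% (length(v) * bin_s)
  edge <- cfg$edge_transient_s
  in_edge <- ev$start_s < edge | ev$end_s > total_s - edge
  ev$status[in_edge] <- "rejected"
  ev$reason[in_edge] <- "edge_transient"
  ev
}

accepted <- function(events) events[events$status == "accepted", , drop = FALSE]
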