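# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: plain loops, plain arithmetic.

# O(n * w) reference for the adaptive 200% rule: returns the logical vector
# of detected bins (ratio AND channel minimum), recomputing every local
# baseline from scratch.
brute_detect_bins <- function(values, bin_s = 0.05, window_s = 3,
                              ratio = 2, min_integral = 15) {
  n <- length(values)
  w <- round(window_s / bin_s)
  out <- logical(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - w); hi <- min(n, k + w)
    base <- max((sum(values[lo:hi]) - values[k]) / (hi - lo),
                .Machine$double.eps)
    out[k] <- values[k] > ratio * base && values[k] >= min_integral
  }
  out
}

# Expand the package's event table back to detected bins for comparison.
events_to_bins <- function(events, n_bins, bin_s = 0.05) {
  out <- logical(n_bins)
  for (i in seq_len(nrow(events))) {
    k0 <- round(events$start_s[i] / bin_s) + 1L
    k1 <- round(events$end_s[i] / bin_s)
    out[k0:k1] <- TRUE
  }
  out
}

# Naive O(n^2) maximal-subsequence PLM oracle.
brute_plm_runs <- function(mm_events, min_dur = 1, max_dur = 5,
                           min_iv = 5, max_iv = 90, min_len = 4) {
  ok <- which(mm_events$status == "accepted" &
                (mm_events$end_s - mm_events$start_s) >= min_dur &
                (mm_events$end_s - mm_events$start_s) <= max_dur)
  runs <- list()
  i <- 1
  while (i <= length(ok)) {
    j <- i
    while (j < length(ok)) {
      gap <- mm_events$start_s[ok[j + 1]] - mm_events$start_s[ok[j]]
      if (gap >= min_iv && gap <= max_iv) j <- j + 1 else break
    }
    if (j - i + 1 >= min_len) runs[[length(runs) + 1]] <- ok[i:j]
    i <- j + 1
  }
  runs
}

# Build a sorted event table from onset/duration vectors.
make_events <- function(onsets, durations, channel = "FM", peak = 50,
                        status = "accepted", reason = "") {
  if (length(onsets) == 0L) {
    return(data.frame(channel = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_integral = numeric(0),
                      status = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(channel = channel, start_s = onsets,
                   end_s = onsets + durations,
                   peak_integral = peak, status = status, reason = reason,
                   stringsAsFactors = FALSE)
  df[order(df$start_s), ]
}

# Random event table for property tests.
random_events <- function(n, total_s = 3600, channel = "FM", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  onsets <- sort(round(runif(n, 0, total_s - 5) / 0.05) * 0.05)
  durations <- round(runif(n, 0.05, 3) / 0.05) * 0.05
  status <- sample(c("accepted", "rejected"), n, replace = TRUE, prob = c(0.8, 0.2))
  make_events(onsets, durations, channel = channel,
              peak = round(runif(n, 15, 200), 3),
              status = status,
              reason = ifelse(status == "rejected", "maternal_movement", ""))
}

# Spectral attenuation oracle: dominant-frequency magnitude ratio (dB) of a
# sinusoid before vs after preprocessing, steady-state section only.
spectral_attenuation_db <- function(freq, channel = "FM", fs = 50,
                                    dur_s = 600, cfg = fm_config()) {
  n <- dur_s * fs
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * freq * t)
  rec <- if (channel == "FM") fm_recording(x, numeric(n), fs)
         else fm_recording(numeric(n), x, fs)
  filt <- apply_preprocessing(rec, cfg)
  y <- if (channel == "FM") filt$fm else filt$mm
  keep <- (30 * fs):(n - 30 * fs)
  k <- which.max(Mod(stats::fft(x[keep]))[1:floor(length(keep) / 2)])
  20 * log10(Mod(stats::fft(y[keep]))[k] / Mod(stats::fft(x[keep]))[k])
}

# Short simulation used by several suites (5 min keeps tests fast).
short_sim <- function(seed = 11L, ...) {
  simulate_recording(sim_config(duration_s = 300, seed = seed,
                                wake = list(n_episodes = 0), ...))
}
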