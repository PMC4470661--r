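# Step-4 artifact rejection. Rejection precedence is fixed: wake/restroom >
# maternal_movement > plm > hiccup — the first applicable reason wins and a
# rejected event is never re-labeled.

new_mask <- function(intervals, total_recording_s) {
  stopifnot(all(c("start_s", "end_s", "reason") %in% names(intervals)))
  intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  rownames(intervals) <- NULL
  reduce <- intervals$reason %in% c("wake", "restroom", "edge_transient")
  excl <- merge_intervals(intervals$start_s[reduce], intervals$end_s[reduce])
  at <- total_recording_s - clipped_length(excl$start_s, excl$end_s, total_recording_s)
  structure(intervals, class = c("fm_mask", "data.frame"),
            total_recording_s = total_recording_s,
            analysis_time_s = at)
}

#' Build an analysis mask
#'
#' An analysis mask is a table of half-open intervals `(start_s, end_s,
#' reason)` with reason in `wake`, `restroom`, `hiccup_bout`,
#' `edge_transient`. Wake, restroom and edge intervals are subtracted from
#' analysis time (the movements-per-hour denominator); hiccup bouts remove
#' events but keep their time in the denominator.
#'
#' @param intervals data frame with `start_s`, `end_s`, `reason`.
#' @param total_recording_s recording duration in seconds.
#' @return An `fm_mask` with attributes `total_recording_s` and
#'   `analysis_time_s`.
#' @export
build_mask <- function(intervals, total_recording_s) {
  new_mask(intervals, total_recording_s)
}

#' @export
as.data.frame.fm_mask <- function(x, ...) {
  df <- x
  attr(df, "total_recording_s") <- NULL
  attr(df, "analysis_time_s") <- NULL
  class(df) <- "data.frame"
  df
}

#' @export
print.fm_mask <- function(x, ...) {
  cat(sprintf("<fm_mask> %d intervals; analysis time %.1f of %.1f s\n",
              nrow(x), attr(x, "analysis_time_s"), attr(x, "total_recording_s")))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Analysis time of a mask in seconds
#' @param mask an `fm_mask`.
#' @export
analysis_time <- function(mask) attr(mask, "analysis_time_s")

reject_where <- function(fm_events, hit, reason) {
  hit <- hit & fm_events$status == "accepted"
  fm_events$status[hit] <- "rejected"
  fm_events$reason[hit] <- reason
  fm_events
}

#' Reject FM events that coincide with maternal movement
#'
#' An FM event is rejected (reason `maternal_movement`) when its interval
#' intersects any accepted MM event dilated by `guard_s` on both sides.
#' Already-rejected FM events are left untouched.
#'
#' @param fm_events,mm_events sorted event data frames.
#' @param guard_s dilation of MM events in seconds (default 1.0).
#' @export
mask_maternal_movement <- function(fm_events, mm_events, guard_s = 1.0) {
  assert_events_sorted(fm_events, "fm_events")
  assert_events_sorted(mm_events, "mm_events")
  mm <- accepted(mm_events)
  hit <- any_overlap(fm_events$start_s, fm_events$end_s,
                     mm$start_s - guard_s, mm$end_s + guard_s)
  reject_where(fm_events, hit, "maternal_movement")
}

#' Detect periodic limb movement (PLM) runs on the MM channel
#'
#' A PLM run is a maximal sequence of at least `min_run_length` accepted MM
#' events, each lasting between `min_duration_s` (default 1.0 s) and
#' `max_duration_s` (5 s), with successive onset-to-onset intervals between
#' `min_interval_s` (5 s) and `max_interval_s` (90 s) — the standard sleep
#' scoring series convention.
#'
#' @param mm_events sorted event data frame.
#' @param cfg an [fm_config()] (its `$plm` section is used).
#' @return Data frame of runs: `start_s`, `end_s`, `n_movements`, plus a
#'   `members` list-column of member row indices into `mm_events`.
#' @export
detect_plm <- function(mm_events, cfg = fm_config()) {
  assert_events_sorted(mm_events, "mm_events")
  p <- cfg$plm
  idx <- which(mm_events$status == "accepted" &
                 (mm_events$end_s - mm_events$start_s) >= p$min_duration_s &
                 (mm_events$end_s - mm_events$start_s) <= p$max_duration_s)
  runs <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     n_movements = integer(0))
  runs$members <- list()
  if (length(idx) == 0L) return(runs)
  onset <- mm_events$start_s[idx]
  ok_gap <- diff(onset) >= p$min_interval_s & diff(onset) <= p$max_interval_s
  # maximal runs of consecutive qualifying gaps
  brk <- which(!ok_gap)
  first <- c(1L, brk + 1L)
  last <- c(brk, length(idx))
  keep <- (last - first + 1L) >= p$min_run_length
  if (!any(keep)) return(runs)
  first <- first[keep]; last <- last[keep]
  members <- lapply(seq_along(first), function(i) idx[first[i]:last[i]])
  out <- data.frame(
    start_s = mm_events$start_s[idx[first]],
    end_s = mm_events$end_s[idx[last]],
    n_movements = last - first + 1L)
  out$members <- members
  out
}

#' Reject FM events coinciding with PLM run members
#'
#' @param fm_events sorted FM event data frame.
#' @param plm_runs result of [detect_plm()].
#' @param mm_events the MM events the runs index into.
#' @param guard_s dilation of each run member (default 1.0 s).
#' @export
mask_plm <- function(fm_events, plm_runs, mm_events, guard_s = 1.0) {
  assert_events_sorted(fm_events, "fm_events")
  if (nrow(plm_runs) == 0L) return(fm_events)
  mi <- unlist(plm_runs$members)
  hit <- any_overlap(fm_events$start_s, fm_events$end_s,
                     mm_events$start_s[mi] - guard_s,
                     mm_events$end_s[mi] + guard_s)
  reject_where(fm_events, hit, "plm")
}

# Count event onsets per fixed 60-s clock minute (0-based minute index).
events_per_minute <- function(onsets, total_s) {
  n_min <- ceiling(total_s / 60)
  tabulate(pmin(floor(onsets / 60), n_min - 1) + 1L, nbins = n_min)
}

# Maximal runs of TRUE in a logical vector -> (first, last) minute indices.
true_runs <- function(flag) {
  if (!any(flag)) return(data.frame(first = integer(0), last = integer(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

#' Classify maternal wake and restroom time
#'
#' Each fixed 60-s clock minute containing at least `wake_events_per_minute`
#' (default 4) accepted MM event onsets is marked wake — brief awakenings
#' (fewer than four movements in a minute) are not removed from analysis
#' time. Maximal runs of consecutive wake minutes lasting at least
#' `restroom_min_duration_s` (default 300 s) are re-labeled restroom. Both
#' are subtracted from analysis time.
#'
#' @param mm_events sorted MM event data frame.
#' @param total_s recording duration in seconds.
#' @param cfg an [fm_config()].
#' @return An `fm_mask` containing the wake/restroom intervals.
#' @export
classify_wake_and_restroom <- function(mm_events, total_s, cfg = fm_config()) {
  stopifnot(total_s > 0)
  assert_events_sorted(mm_events, "mm_events")
  cnt <- events_per_minute(accepted(mm_events)$start_s, total_s)
  wake_min <- cnt >= cfg$wake_events_per_minute
  runs <- true_runs(wake_min)
  if (nrow(runs) == 0L) {
    return(new_mask(data.frame(start_s = numeric(0), end_s = numeric(0),
                               reason = character(0)), total_s))
  }
  start_s <- (runs$first - 1L) * 60
  end_s <- pmin(runs$last * 60, total_s)
  reason <- ifelse(end_s - start_s >= cfg$restroom_min_duration_s,
                   "restroom", "wake")
  new_mask(data.frame(start_s = start_s, end_s = end_s, reason = reason,
                      stringsAsFactors = FALSE), total_s)
}

#' Detect fetal hiccup bouts and exclude their events
#'
#' Hiccup candidates are accepted FM events of duration at least
#' `min_event_duration_s` (0.2 s). Any fixed clock minute containing more
#' than `events_per_minute_threshold` (15) candidate onsets is a hiccup
#' minute; maximal runs of consecutive hiccup minutes form bouts. All FM
#' events intersecting a bout are rejected with reason `hiccup`. Bout time
#' stays in the analysis denominator.
#'
#' @param fm_events sorted FM event data frame.
#' @param total_s recording duration in seconds.
#' @param cfg an [fm_config()].
#' @return List with `bouts` (data frame `start_s`, `end_s`, `n_signals`)
#'   and `fm_events` (statuses updated).
#' @export
detect_hiccup_bouts <- function(fm_events, total_s, cfg = fm_config()) {
  assert_events_sorted(fm_events, "fm_events")
  h <- cfg$hiccup
  acc <- accepted(fm_events)
  cand <- acc[acc$end_s - acc$start_s >= h$min_event_duration_s, , drop = FALSE]
  cnt <- events_per_minute(cand$start_s, total_s)
  runs <- true_runs(cnt > h$events_per_minute_threshold)
  if (nrow(runs) == 0L) {
    return(list(bouts = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   n_signals = integer(0)),
                fm_events = fm_events))
  }
  start_s <- (runs$first - 1L) * 60
  end_s <- pmin(runs$last * 60, total_s)
  n_sig <- vapply(seq_along(start_s), function(i) {
    sum(cand$start_s >= start_s[i] & cand$start_s < end_s[i])
  }, integer(1))
  hit <- any_overlap(fm_events$start_s, fm_events$end_s, start_s, end_s)
  list(bouts = data.frame(start_s = start_s, end_s = end_s, n_signals = n_sig),
       fm_events = reject_where(fm_events, hit, "hiccup"))
}

#' Apply the full artifact-rejection cascade to FM events
#'
#' Applies, in fixed precedence order: wake/restroom exclusion, maternal
#' movement masking, PLM masking, hiccup-bout exclusion. Returns the
#' updated FM events, the combined analysis mask (wake/restroom +
#' edge-transient zones + hiccup bouts) and the PLM runs.
#'
#' @param fm_events,mm_events sorted event data frames (both channels).
#' @param total_s recording duration in seconds.
#' @param cfg an [fm_config()].
#' @export
apply_artifact_rejection <- function(fm_events, mm_events, total_s,
                                     cfg = fm_config()) {
  wr <- classify_wake_and_restroom(mm_events, total_s, cfg)
  hit <- any_overlap(fm_events$start_s, fm_events$end_s, wr$start_s, wr$end_s)
  fm_events <- reject_where(fm_events, hit, "wake")
  fm_events <- mask_maternal_movement(fm_events, mm_events, cfg$mm_guard_s)
  plm_runs <- detect_plm(mm_events, cfg)
  fm_events <- mask_plm(fm_events, plm_runs, mm_events, cfg$mm_guard_s)
  hic <- detect_hiccup_bouts(fm_events, total_s, cfg)
  fm_events <- hic$fm_events

  edge <- cfg$edge_transient_s
  edge_iv <- data.frame(start_s = c(0, max(total_s - edge, 0)),
                        end_s = c(min(edge, total_s), total_s),
                        reason = "edge_transient", stringsAsFactors = FALSE)
  hb <- hic$bouts
  iv <- rbind(as.data.frame(wr),
              if (nrow(hb)) data.frame(start_s = hb$start_s, end_s = hb$end_s,
                                       reason = "hiccup_bout",
                                       stringsAsFactors = FALSE),
              edge_iv)
  list(fm_events = fm_events,
       mask = new_mask(iv, total_s),
       plm_runs = plm_runs,
       hiccup_bouts = hic$bouts)
}
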