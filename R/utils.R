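# Internal helpers shared across modules. All time intervals are half-open
# [start_s, end_s) in seconds from recording start.

# Does interval [a1, a2) intersect [b1, b2)?
intervals_intersect <- function(a1, a2, b1, b2) {
  a1 < b2 & b1 < a2
}

# TRUE for each row interval in `x` (start_s, end_s) that intersects any
# interval in `ref` (already dilated if needed). Both data frames sorted or not.
any_overlap <- function(x_start, x_end, ref_start, ref_end) {
  if (length(ref_start) == 0L || length(x_start) == 0L) {
    return(rep(FALSE, length(x_start)))
  }
  vapply(seq_along(x_start), function(i) {
    any(x_start[i] < ref_end & ref_start < x_end[i])
  }, logical(1))
}

# Merge sorted half-open intervals that touch or overlap.
merge_intervals <- function(start_s, end_s) {
  if (length(start_s) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start_s, end_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  ms <- start_s[1]; me <- end_s[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] <= me) {
      me <- max(me, end_s[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start_s[i]; me <- end_s[i]
    }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}

# Total length covered by a set of disjoint intervals clipped to [0, total_s).
clipped_length <- function(start_s, end_s, total_s) {
  if (length(start_s) == 0L) return(0)
  s <- pmax(start_s, 0); e <- pmin(end_s, total_s)
  sum(pmax(e - s, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fm <- function(class, msg, ...) {
  stop(structure(class = c(class, "fm_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Empty event table with canonical column order.
empty_events <- function() {
  data.frame(channel = character(0), start_s = numeric(0), end_s = numeric(0),
             peak_integral = numeric(0), status = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

assert_events_sorted <- function(events, what = "events") {
  if (nrow(events) > 1L && is.unsorted(events$start_s)) {
    stop_fm("fm_order_error", "%s must be sorted by start_s", what)
  }
  invisible(events)
}
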