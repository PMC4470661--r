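# 10-s epoch scoring and inter-rater agreement. PABAK (prevalence-adjusted
# bias-adjusted kappa) = 2*po - 1, where po is the observed epoch-wise
# agreement proportion; it is insensitive to movement prevalence and rater
# bias, which matters because most overnight epochs contain no movement.

#' Binary 10-s epoch movement labels
#'
#' Epoch `k` (0-based) covers `[k*epoch_s, (k+1)*epoch_s)` and is labeled 1
#' when any accepted FM event intersects it. Epochs intersecting
#' wake/restroom/edge-transient mask intervals are dropped entirely (label
#' `NA`) and their indices listed.
#'
#' @param fm_events sorted event data frame.
#' @param mask an `fm_mask` or `NULL`.
#' @param total_s recording duration in seconds.
#' @param epoch_s epoch length (default 10 s).
#' @return A list of class `fm_epochs`: `labels` (0/1/NA integer vector),
#'   `dropped` (0-based indices of dropped epochs), `epoch_s`, `n_epochs`.
#' @export
epoch_labels <- function(fm_events, mask = NULL, total_s, epoch_s = 10) {
  stopifnot(epoch_s > 0)
  assert_events_sorted(fm_events)
  n_epochs <- floor(total_s / epoch_s)
  starts <- (seq_len(n_epochs) - 1L) * epoch_s
  ends <- starts + epoch_s
  acc <- accepted(fm_events)
  labels <- as.integer(any_overlap(starts, ends, acc$start_s, acc$end_s))
  dropped <- integer(0)
  if (!is.null(mask) && nrow(mask)) {
    excl <- mask[mask$reason %in% c("wake", "restroom", "edge_transient"), ,
                 drop = FALSE]
    drop <- any_overlap(starts, ends, excl$start_s, excl$end_s)
    labels[drop] <- NA_integer_
    dropped <- which(drop) - 1L
  }
  structure(list(labels = labels, dropped = dropped, epoch_s = epoch_s,
                 n_epochs = n_epochs),
            class = "fm_epochs")
}

#' Agreement between two epoch labelings: PABAK and Cohen's kappa
#'
#' Both labelings must share the epoch grid; only epochs kept (non-NA) by
#' both contribute. `po` is the proportion of common epochs with equal
#' labels; `pabak = 2*po - 1`; `kappa` is Cohen's kappa from the 2x2 table
#' (defined as `po` when chance agreement equals 1). The Landis-Koch
#' category of the PABAK value is attached.
#'
#' @param a,b `fm_epochs` objects or plain 0/1 vectors (NA = dropped).
#' @return List of class `fm_agreement`: `po`, `pabak`, `kappa`, `label`,
#'   `n_epochs`.
#' @export
pabak <- function(a, b) {
  la <- if (inherits(a, "fm_epochs")) a$labels else as.integer(a)
  lb <- if (inherits(b, "fm_epochs")) b$labels else as.integer(b)
  if (length(la) != length(lb)) {
    stop_fm("fm_input_error", "labelings are on different epoch grids")
  }
  keep <- !is.na(la) & !is.na(lb)
  n <- sum(keep)
  if (n < 1L) stop_fm("fm_input_error", "no common non-dropped epochs")
  la <- la[keep]; lb <- lb[keep]
  po <- mean(la == lb)
  p1a <- mean(la == 1L); p1b <- mean(lb == 1L)
  pe <- p1a * p1b + (1 - p1a) * (1 - p1b)
  kappa <- if (pe == 1) po else (po - pe) / (1 - pe)
  structure(list(po = po, pabak = 2 * po - 1, kappa = kappa,
                 label = kappa_label(2 * po - 1), n_epochs = n),
            class = "fm_agreement")
}

#' @export
print.fm_agreement <- function(x, ...) {
  cat(sprintf("<fm_agreement> n=%d  po=%.3f  PABAK=%.3f (%s)  kappa=%.3f\n",
              x$n_epochs, x$po, x$pabak, x$label, x$kappa))
  invisible(x)
}

#' Landis-Koch strength-of-agreement category for a kappa value
#'
#' `<= 0` poor; `(0, 0.20]` slight; `(0.20, 0.40]` fair; `(0.40, 0.60]`
#' moderate; `(0.60, 0.80]` substantial; `(0.80, 1]` almost perfect.
#'
#' @param k kappa-type statistic in `[-1, 1]`.
#' @return Category string.
#' @examples
#' kappa_label(0.83)  # "almost perfect"
#' @export
kappa_label <- function(k) {
  if (!is.numeric(k) || is.na(k) || k < -1 || k > 1) {
    stop_fm("fm_input_error", "kappa must lie in [-1, 1]")
  }
  if (k <= 0) "poor"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}
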