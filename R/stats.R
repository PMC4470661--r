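# Session summaries and the longitudinal statistics: per-hour movement
# counts, mean/SD aggregation, one-way repeated-measures ANOVA by classical
# sums of squares, and Scheffe post-hoc contrasts on the session means.

#' Per-session movement summary
#'
#' @param fm_events final FM event data frame.
#' @param mask an `fm_mask` giving the analysis time.
#' @param subject_id,gestational_week session metadata.
#' @param n_hiccup_bouts number of detected hiccup bouts.
#' @param flags QC flag list (see [flag_artifacts()]).
#' @return List of class `fm_summary` with `n_movements`,
#'   `analysis_time_h`, `movements_per_hour` and the metadata.
#' @export
session_summary <- function(fm_events, mask, subject_id = "anon",
                            gestational_week = NA_integer_,
                            n_hiccup_bouts = 0L, flags = NULL) {
  at_s <- analysis_time(mask)
  if (!is.numeric(at_s) || at_s <= 0) {
    stop_fm("fm_degenerate_session", "analysis time is zero; nothing to summarize")
  }
  n <- nrow(accepted(fm_events))
  structure(list(subject_id = subject_id,
                 gestational_week = gestational_week,
                 n_movements = n,
                 analysis_time_h = at_s / 3600,
                 movements_per_hour = n / (at_s / 3600),
                 n_hiccup_bouts = n_hiccup_bouts,
                 flags = flags),
            class = "fm_summary")
}

#' @export
print.fm_summary <- function(x, ...) {
  cat(sprintf("<fm_summary> subject %s wk %s: %d movements in %.2f h = %.1f /h\n",
              x$subject_id, x$gestational_week, x$n_movements,
              x$analysis_time_h, x$movements_per_hour))
  invisible(x)
}

#' Mean and sample standard deviation
#'
#' Sample SD uses the n - 1 denominator. Values are returned at full
#' precision with 2-decimal display strings alongside, matching the
#' reporting convention for agreement and count aggregates.
#'
#' @param values numeric vector (n >= 1; n >= 2 for the SD).
#' @return List with `mean`, `sd`, `mean_2dp`, `sd_2dp`, `n`.
#' @examples
#' aggregate_mean_sd(c(0.83, 0.90, 0.79, 0.85, 0.81, 0.83))
#' @export
aggregate_mean_sd <- function(values) {
  if (length(values) == 0L) stop_fm("fm_input_error", "no values to aggregate")
  m <- mean(values)
  s <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  list(mean = m, sd = s,
       mean_2dp = sprintf("%.2f", m),
       sd_2dp = if (is.na(s)) NA_character_ else sprintf("%.2f", s),
       n = length(values))
}

check_rm_table <- function(table, drop_incomplete) {
  table <- as.matrix(table)
  if (anyNA(table)) {
    if (!drop_incomplete) {
      stop_fm("fm_incomplete_design",
              "table has missing cells; set drop_incomplete = TRUE to use complete cases")
    }
    table <- table[stats::complete.cases(table), , drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop_fm("fm_input_error", "need at least 2 subjects and 2 sessions")
  }
  table
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition of a complete subjects x sessions
#' matrix: `SS_total = SS_subjects + SS_conditions + SS_error`, with
#' `F_condition = MS_cond / MS_error` on `(s - 1, (s - 1)(n - 1))` degrees
#' of freedom, plus the subject (individual-differences) effect tested
#' against the same error term. A zero error mean square yields `F = Inf`
#' with a note.
#'
#' @param table numeric matrix or data frame, rows = subjects, columns =
#'   sessions (e.g. per-hour counts at gestational weeks 24/28/32/36).
#' @param drop_incomplete drop subjects with missing sessions instead of
#'   erroring (default FALSE; no imputation is offered).
#' @return List of class `fm_anova` with the SS/df/MS table, `F_condition`,
#'   `p_condition`, `F_subject`, `p_subject`.
#' @export
rm_anova <- function(table, drop_incomplete = FALSE) {
  x <- check_rm_table(table, drop_incomplete)
  n <- nrow(x); s <- ncol(x)
  g <- mean(x)
  ss_total <- sum((x - g)^2)
  ss_subj <- s * sum((rowMeans(x) - g)^2)
  ss_cond <- n * sum((colMeans(x) - g)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df_cond <- s - 1L
  df_subj <- n - 1L
  df_err <- (s - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_cond
  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  note <- NULL
  if (ms_err <= 0) {
    f_cond <- if (ms_cond > 0) Inf else 0
    f_subj <- if (ms_subj > 0) Inf else 0
    note <- "zero error mean square; F reported as Inf"
  } else {
    f_cond <- ms_cond / ms_err
    f_subj <- ms_subj / ms_err
  }
  structure(list(
    ss = c(subjects = ss_subj, conditions = ss_cond, error = ss_err,
           total = ss_total),
    df = c(subjects = df_subj, conditions = df_cond, error = df_err),
    ms = c(subjects = ms_subj, conditions = ms_cond, error = ms_err),
    F_condition = f_cond, df_condition = df_cond, df_error = df_err,
    p_condition = stats::pf(f_cond, df_cond, df_err, lower.tail = FALSE),
    F_subject = f_subj,
    p_subject = stats::pf(f_subj, df_subj, df_err, lower.tail = FALSE),
    n_subjects = n, n_sessions = s, note = note),
    class = "fm_anova")
}

#' @export
print.fm_anova <- function(x, ...) {
  cat(sprintf("<fm_anova> %d subjects x %d sessions\n", x$n_subjects, x$n_sessions))
  cat(sprintf("  condition: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_condition, x$df_error, x$F_condition, x$p_condition))
  cat(sprintf("  subject:   F(%d, %d) = %.3f, p = %.4g\n",
              x$df["subjects"], x$df_error, x$F_subject, x$p_subject))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Scheffe post-hoc contrasts between sessions
#'
#' For each session pair the contrast F statistic is
#' `n * diff^2 / (2 * MS_error)`; the Scheffe criterion declares the pair
#' significant when `F_contrast >= (s - 1) * qf(1 - alpha, s - 1, df_error)`.
#' The p-value is `P(F(s-1, df_error) >= F_contrast / (s - 1))`, so Scheffe
#' is never more liberal than the unadjusted paired contrast.
#'
#' @param table the subjects x sessions matrix passed to [rm_anova()].
#' @param fit the corresponding `fm_anova` result.
#' @param alpha significance level (default 0.05).
#' @param drop_incomplete as in [rm_anova()].
#' @return Data frame with one row per pair: `session_a`, `session_b`,
#'   `diff`, `F_contrast`, `F_critical`, `p`, `significant`.
#' @export
scheffe_posthoc <- function(table, fit, alpha = 0.05, drop_incomplete = FALSE) {
  stopifnot(inherits(fit, "fm_anova"))
  x <- check_rm_table(table, drop_incomplete)
  n <- nrow(x); s <- ncol(x)
  cm <- colMeans(x)
  labs <- colnames(x) %||% paste0("S", seq_len(s))
  pairs <- utils::combn(s, 2L)
  ms_err <- fit$ms["error"]
  crit <- (s - 1L) * stats::qf(1 - alpha, s - 1L, fit$df_error)
  out <- data.frame(
    session_a = labs[pairs[1L, ]],
    session_b = labs[pairs[2L, ]],
    diff = cm[pairs[1L, ]] - cm[pairs[2L, ]],
    stringsAsFactors = FALSE)
  out$F_contrast <- if (ms_err > 0) n * out$diff^2 / (2 * ms_err) else
    ifelse(out$diff == 0, 0, Inf)
  out$F_critical <- crit
  out$p <- stats::pf(out$F_contrast / (s - 1L), s - 1L, fit$df_error,
                     lower.tail = FALSE)
  out$significant <- out$F_contrast >= crit
  rownames(out) <- NULL
  out
}
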