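#' Default analysis configuration
#'
#' Builds the full pipeline configuration with the published default
#' constants: 50-ms integral bins, the 200% (ratio 2.0) adaptive threshold
#' over a +/- 3-s baseline, fixed minimum integral thresholds of 15 (FM
#' channel) and 20 (MM channel), the periodic-limb-movement (PLM) and
#' fetal-hiccup rules, and the wake/restroom analysis-time exclusions.
#' Every value can be overridden via `...` using the same nested names.
#'
#' @param ... named overrides, e.g. `min_integral_fm = 0`,
#'   `filter = list(notch_respiration_hz = NA)`. Unknown names are an error.
#' @return A list of class `fm_config`.
#' @examples
#' cfg <- fm_config()
#' cfg$min_integral_fm
#' fm_config(min_integral_fm = 0, min_integral_mm = 0)$min_integral_fm
#' @export
fm_config <- function(...) {
  cfg <- list(
    filter = list(
      highpass_hz         = 0.5,   # 1st order, -6 dB/oct
      lowpass_hz          = 2.5,   # 2nd order, -12 dB/oct
      notch_heartbeat_hz  = 1.0,   # both channels
      notch_respiration_hz = 0.3,  # FM channel only; NA disables
      notch_heartbeat_bw_hz   = 0.2,
      notch_respiration_bw_hz = 0.1,
      zero_phase          = TRUE
    ),
    bin_ms              = 50,
    ratio_threshold     = 2.0,
    baseline_window_s   = 3.0,
    min_integral_fm     = 15,
    min_integral_mm     = 20,
    merge_gap_s         = 0.25,
    edge_transient_s    = 10,
    mm_guard_s          = 1.0,
    plm = list(
      min_duration_s = 1.0,
      max_duration_s = 5.0,
      min_interval_s = 5,
      max_interval_s = 90,
      min_run_length = 4
    ),
    hiccup = list(
      min_event_duration_s        = 0.2,
      events_per_minute_threshold = 15
    ),
    wake_events_per_minute = 4,
    restroom_min_duration_s = 300,
    flag_factor   = 3,
    flag_min_count = 20,
    epoch_s = 10,
    seed    = 0L
  )
  cfg <- modify_config(cfg, list(...))
  validate_config(cfg)
}

# Recursive override with unknown-key rejection.
modify_config <- function(cfg, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) {
      stop_fm("fm_config_error", "unknown config key: %s%s", path, nm)
    }
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- modify_config(cfg[[nm]], over[[nm]], paste0(path, nm, "$"))
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

validate_config <- function(cfg) {
  f <- cfg$filter
  # note: the 0.3 Hz respiration notch sits BELOW the 0.5 Hz high-pass
  # corner by design, so only notch_resp < notch_hb < lowpass is enforced.
  if (!is.na(f$notch_respiration_hz) &&
      !(f$notch_respiration_hz < f$notch_heartbeat_hz)) {
    stop_fm("fm_config_error", "notch_respiration_hz must be below notch_heartbeat_hz")
  }
  if (!(f$notch_heartbeat_hz < f$lowpass_hz && f$highpass_hz < f$lowpass_hz)) {
    stop_fm("fm_config_error", "notch_heartbeat_hz and highpass_hz must be below lowpass_hz")
  }
  if (cfg$ratio_threshold <= 1) {
    stop_fm("fm_config_error", "ratio_threshold must exceed 1")
  }
  positive <- c("bin_ms", "baseline_window_s", "mm_guard_s", "epoch_s",
                "wake_events_per_minute", "restroom_min_duration_s")
  for (nm in positive) {
    if (cfg[[nm]] <= 0) stop_fm("fm_config_error", "%s must be positive", nm)
  }
  if (cfg$min_integral_fm < 0 || cfg$min_integral_mm < 0) {
    stop_fm("fm_config_error", "minimum integral thresholds must be >= 0")
  }
  structure(cfg, class = "fm_config")
}

#' Read / write an analysis configuration
#'
#' Configurations serialize to a single human-readable JSON file. Unknown
#' keys in the file are rejected rather than ignored.
#'
#' @param cfg an `fm_config` object.
#' @param path file path of the JSON configuration.
#' @return `read_config` returns an `fm_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_fm("fm_io_error", "config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_to_na <- function(x) {
    if (!is.list(x)) return(x)
    for (nm in names(x)) {
      x[[nm]] <- if (is.null(x[[nm]])) NA else null_to_na(x[[nm]])
    }
    x
  }
  do.call(fm_config, null_to_na(raw))
}
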