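#' Construct an EEG recording
#'
#' A recording is a tibble with columns `t` (seconds from start) and `v`
#' (voltage in volts), carrying the sampling rate and free-text labels as
#' attributes. All package functions hold voltages internally in volts;
#' microvolt inputs are converted at the boundary (`unit = "uV"`).
#'
#' @param v Numeric vector of samples. Must be finite throughout.
#' @param fs Sampling rate in Hz (> 0).
#' @param unit Unit of `v`: `"V"` (default) or `"uV"`.
#' @param subject,task,channel Free-text labels, e.g. `channel = "Cz-A2"`.
#' @param filter_setup Provenance flag: name of the pre-filter chain already
#'   applied, or `"raw"` for an unfiltered signal.
#' @return A tibble of class `bci_recording` with columns `t`, `v`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:999) / 250) * 1e-5, fs = 250)
#' rec_fs(rec)
#' @export
recording <- function(v, fs, unit = c("V", "uV"), subject = NA_character_,
                      task = NA_character_, channel = NA_character_,
                      filter_setup = "raw") {
  unit <- arg_match(unit)
  v <- as.numeric(v)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(v) == 0L) abort("recording must contain at least one sample.")
  if (!all(is.finite(v))) {
    abort(sprintf("recording contains %d non-finite sample(s).",
                  sum(!is.finite(v))))
  }
  if (unit == "uV") v <- v / 1e6
  out <- tibble(t = (seq_along(v) - 1) / fs, v = v)
  class(out) <- c("bci_recording", class(out))
  attr(out, "fs") <- fs
  attr(out, "subject") <- subject
  attr(out, "task") <- task
  attr(out, "channel") <- channel
  attr(out, "filter_setup") <- filter_setup
  out
}

#' Recording accessors
#'
#' @param rec A `bci_recording`.
#' @return `rec_fs()`: the sampling rate in Hz; `rec_duration()`: the
#'   duration in seconds; `rec_samples()`: the bare numeric sample vector in
#'   volts; `rec_filter_setup()`: the provenance flag.
#' @export
rec_fs <- function(rec) {
  check_recording(rec)
  attr(rec, "fs")
}

#' @rdname rec_fs
#' @export
rec_duration <- function(rec) nrow(rec) / rec_fs(rec)

#' @rdname rec_fs
#' @export
rec_samples <- function(rec) {
  check_recording(rec)
  rec$v
}

#' @rdname rec_fs
#' @export
rec_filter_setup <- function(rec) {
  check_recording(rec)
  attr(rec, "filter_setup")
}

check_recording <- function(rec, arg = caller_arg(rec)) {
  if (!inherits(rec, "bci_recording")) {
    abort(sprintf("`%s` must be a bci_recording (see `recording()`).", arg))
  }
  invisible(rec)
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf(
    "<bci_recording> %d samples @ %g Hz (%.1f s), filter: %s\n",
    nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"), attr(x, "filter_setup")))
  meta <- c(subject = attr(x, "subject"), task = attr(x, "task"),
            channel = attr(x, "channel"))
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Read a recording from a delimited text file
#'
#' Accepts a single- or multi-column table (delimiter sniffed among tab,
#' comma and whitespace); one sample per row. Values are converted to volts
#' internally.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz. Never defaulted silently: the file format
#'   does not carry it, so it must be given.
#' @param unit `"V"` or `"uV"`.
#' @param column Which column holds the samples (default 1).
#' @param ... Labels passed on to [recording()].
#' @return A `bci_recording`.
#' @export
read_recording <- function(path, fs, unit = c("V", "uV"), column = 1L, ...) {
  unit <- arg_match(unit)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty recording file: %s", path))
  sep <- sniff_delimiter(lines[[1]])
  fields <- strsplit(lines, sep, perl = TRUE)
  vals <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    f <- f[nzchar(f)]
    if (length(f) < column) {
      abort(sprintf("line %d of %s has %d column(s), need column %d.",
                    i, path, length(f), column))
    }
    x <- suppressWarnings(as.numeric(f[[column]]))
    if (is.na(x)) {
      abort(sprintf("non-numeric value %s on line %d of %s.",
                    encodeString(f[[column]], quote = "'"), i, path))
    }
    x
  }, numeric(1))
  recording(vals, fs = fs, unit = unit, ...)
}

sniff_delimiter <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "[ ]+"
}

#' Write a recording to a plain-text file
#'
#' One sample per line, in volts, full double precision. Round-trips exactly
#' through [read_recording()].
#'
#' @param rec A `bci_recording`.
#' @param path Output path.
#' @export
write_recording <- function(rec, path) {
  check_recording(rec)
  writeLines(formatC(rec$v, format = "g", digits = 17), path)
  invisible(path)
}

#' Construct / read / write an oddball event series
#'
#' Event onsets in seconds from recording start, strictly increasing. Event
#' files carry seconds (not sample indices) so recordings at different
#' sampling rates can share event lists.
#'
#' @param times Numeric vector of onset times in seconds.
#' @param duration If given, every event must lie in `[0, duration)`.
#' @return A tibble of class `bci_events` with column `time_s` (possibly
#'   zero rows).
#' @export
events <- function(times = numeric(), duration = NULL) {
  times <- as.numeric(times)
  if (anyNA(times) || !all(is.finite(times))) {
    abort("event times must all be finite.")
  }
  if (any(times < 0)) abort("event times must be non-negative.")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("event times must be strictly increasing (refusing to sort silently).")
  }
  if (!is.null(duration) && length(times) && any(times >= duration)) {
    abort(sprintf("event time %.3f s lies beyond the recording (%.3f s).",
                  max(times), duration))
  }
  out <- tibble(time_s = times)
  class(out) <- c("bci_events", class(out))
  out
}

#' @param path File path: one onset time (seconds) per line.
#' @rdname events
#' @export
read_events <- function(path, duration = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(events(numeric(), duration))
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) {
    abort(sprintf("non-numeric event time on line %d of %s.",
                  which(is.na(times))[1], path))
  }
  events(times, duration)
}

#' @param ev A `bci_events`.
#' @rdname events
#' @export
write_events <- function(ev, path) {
  writeLines(formatC(ev$time_s, format = "g", digits = 17), path)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable parameter of the wall/SNR pipeline. Defaults follow
#' the methodology: a 2 s sliding window, a 40% conscious band-power
#' reduction for frequency-domain BCIs, and a 0.05 test level.
#'
#' @param window_s Sliding-window length tau in seconds (default 2).
#' @param stride Samples between window starts (default 1: sample by sample).
#' @param filter_setup One of `"fullband"`, `"delta"`, `"wide"`, `"alpha"`,
#'   `"derivative"`.
#' @param mains_hz Mains frequency, 50 or 60 Hz.
#' @param reduction_fraction Conscious band-power reduction for the
#'   frequency-domain signal power, in (0, 1); default 0.40.
#' @param snr_mode `"time"` (P300 peak power as-is) or `"frequency"`
#'   (reduced by `reduction_fraction`).
#' @param freq_power_convention How the reduction is applied:
#'   `"power_scaled"` multiplies the time-domain power by
#'   `1 - reduction_fraction`; `"amplitude_scaled"` squares the reduced
#'   amplitude, i.e. multiplies by `(1 - reduction_fraction)^2`.
#' @param alpha_level Significance level for group tests (default 0.05).
#' @param discard_startup_s Seconds dropped before any variance scan, to
#'   keep IIR filter startup transients out of the noise extrema (default 2).
#' @param epoch_ms,baseline_ms,search_ms Epoch window, baseline interval and
#'   peak-search interval for P300 averaging, in ms relative to stimulus.
#' @return A list of class `bci_config`.
#' @export
analysis_config <- function(window_s = 2, stride = 1L,
                            filter_setup = "fullband", mains_hz = 50,
                            reduction_fraction = 0.40,
                            snr_mode = c("time", "frequency"),
                            freq_power_convention = c("power_scaled",
                                                      "amplitude_scaled"),
                            alpha_level = 0.05, discard_startup_s = 2,
                            epoch_ms = c(-200, 600),
                            baseline_ms = c(-200, 0),
                            search_ms = c(150, 500)) {
  snr_mode <- arg_match(snr_mode)
  freq_power_convention <- arg_match(freq_power_convention)
  filter_setup <- arg_match(filter_setup, filter_setup_names())
  if (!(mains_hz %in% c(50, 60))) abort("`mains_hz` must be 50 or 60.")
  if (window_s <= 0) abort("`window_s` must be positive.")
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    abort("`reduction_fraction` must lie strictly between 0 and 1.")
  }
  if (discard_startup_s < 0) abort("`discard_startup_s` must be >= 0.")
  structure(list(
    window_s = window_s, stride = as.integer(stride),
    filter_setup = filter_setup, mains_hz = mains_hz,
    reduction_fraction = reduction_fraction, snr_mode = snr_mode,
    freq_power_convention = freq_power_convention,
    alpha_level = alpha_level, discard_startup_s = discard_startup_s,
    epoch_ms = epoch_ms, baseline_ms = baseline_ms, search_ms = search_ms
  ), class = "bci_config")
}

#' Read an analysis configuration from a flat key-value (YAML) file
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path Config file path.
#' @return A `bci_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  exec(analysis_config, !!!vals)
}

#' Write a result bundle as machine-readable JSON
#'
#' Dumps every numeric field with deterministic field order (the column /
#' list order of the object). Tibbles become arrays of row objects.
#'
#' @param results A tibble, list, or list of such.
#' @param path Output path.
#' @export
write_report <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(strip_classes(results), auto_unbox = TRUE,
                              digits = NA, na = "null", null = "null"), con)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}
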