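#' Event-triggered (evoked potential) average
#'
#' Stimulus-locked pointwise mean across epochs: uncorrelated noise
#' attenuates as `1/sqrt(n_events)`, leaving the P300 deflection. Each
#' epoch is baseline-corrected by subtracting its mean over the
#' pre-stimulus interval before averaging; the peak amplitude `c_max` is
#' the signed maximum (positive deflection) of the average within the
#' post-stimulus search interval. Epochs that would run outside the
#' recording are dropped and counted.
#'
#' @param rec A `bci_recording`.
#' @param ev A `bci_events` with at least one usable event.
#' @param epoch_ms Epoch window relative to stimulus, `c(pre, post)` in ms
#'   (default -200..600).
#' @param baseline_ms Baseline interval in ms (default -200..0).
#' @param search_ms Peak-search interval in ms (default 150..500,
#'   bracketing the canonical P300 latency of ~300 ms).
#' @return A list of class `bci_evoked`: `waveform` (tibble `time_ms`, `v`),
#'   `c_max` (V), `latency_ms`, `n_events`, `n_dropped`, plus the window
#'   parameters. `tidy()` returns the waveform, `glance()` the scalars.
#' @export
evoked_average <- function(rec, ev, epoch_ms = c(-200, 600),
                           baseline_ms = c(-200, 0),
                           search_ms = c(150, 500)) {
  check_recording(rec)
  if (!inherits(ev, "bci_events")) abort("`ev` must be a bci_events.")
  if (nrow(ev) == 0L) abort("no events: cannot average an empty series.")
  fs <- rec_fs(rec)
  i_pre <- as.integer(round(epoch_ms[1] / 1000 * fs))
  i_post <- as.integer(round(epoch_ms[2] / 1000 * fs))
  offs <- i_pre:i_post
  centre <- as.integer(round(ev$time_s * fs)) + 1L
  ok <- centre + i_pre >= 1L & centre + i_post <= nrow(rec)
  n_dropped <- sum(!ok)
  centre <- centre[ok]
  if (length(centre) == 0L) abort("no events with a full epoch inside the recording.")
  epochs <- vapply(centre, function(cidx) rec$v[cidx + offs],
                   numeric(length(offs)))
  time_ms <- offs / fs * 1000
  bl <- time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2]
  if (any(bl)) {
    epochs <- sweep(epochs, 2L, colMeans(epochs[bl, , drop = FALSE]))
  }
  avg <- rowMeans(epochs)
  search <- which(time_ms >= search_ms[1] & time_ms <= search_ms[2])
  if (length(search) == 0L) abort("peak-search interval is outside the epoch.")
  ipk <- search[which.max(avg[search])]
  structure(list(
    waveform = tibble(time_ms = time_ms, v = avg),
    c_max = avg[ipk],
    latency_ms = time_ms[ipk],
    n_events = length(centre),
    n_dropped = n_dropped,
    epoch_ms = epoch_ms, baseline_ms = baseline_ms, search_ms = search_ms
  ), class = "bci_evoked")
}

#' @export
print.bci_evoked <- function(x, ...) {
  cat(sprintf(
    "<bci_evoked> %d events (%d dropped): c_max = %.3g uV at %.0f ms\n",
    x$n_events, x$n_dropped, x$c_max * 1e6, x$latency_ms))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bci_evoked <- function(x, ...) x$waveform

#' @exportS3Method generics::glance
glance.bci_evoked <- function(x, ...) {
  tibble(c_max = x$c_max, latency_ms = x$latency_ms,
         n_events = x$n_events, n_dropped = x$n_dropped)
}

#' Conscious signal power, time-domain convention
#'
#' The P300 peak is taken straight as the consciously generated voltage
#' change; its power is the squared peak amplitude `T_t(c) = c_max^2`.
#'
#' @param c_max Peak evoked amplitude in volts (> 0).
#' @return Power in V^2.
#' @examples
#' conscious_power_time(19e-6) # 3.61e-10 V^2
#' @export
conscious_power_time <- function(c_max) {
  if (any(c_max <= 0)) {
    abort("`c_max` must be positive (no positive evoked deflection found).")
  }
  c_max^2
}

#' Conscious signal power, frequency-domain convention
#'
#' Frequency-domain BCIs (e.g. motor imagery) consciously *reduce* the
#' power of a narrow band; only the reduction counts as conscious signal.
#' With a reduction fraction q (default 0.40) two conventions are in use:
#' `power_scaled` takes `T_f = T_t * (1 - q)` (the reduction applied to the
#' power); `amplitude_scaled` takes `T_f = T_t * (1 - q)^2` (the reduction
#' applied to the amplitude, then squared). Both are exposed because the
#' two appear interchangeably in practice; reports carry the convention
#' used.
#'
#' @param t_time Time-domain conscious power `T_t(c)` in V^2.
#' @param reduction Fraction of band power consciously reduced, in (0, 1).
#' @param convention `"power_scaled"` (default) or `"amplitude_scaled"`.
#' @return Power in V^2, strictly less than `t_time`.
#' @export
conscious_power_freq <- function(t_time, reduction = 0.40,
                                 convention = c("power_scaled",
                                                "amplitude_scaled")) {
  convention <- arg_match(convention)
  if (any(t_time <= 0)) abort("`t_time` must be positive.")
  if (reduction <= 0 || reduction >= 1) {
    abort("`reduction` must lie strictly between 0 and 1.")
  }
  switch(convention,
         power_scaled = t_time * (1 - reduction),
         amplitude_scaled = t_time * (1 - reduction)^2)
}

#' Nominal noise power of a recording
#'
#' Whole-recording mean-square power. Because the small evoked potentials
#' are buried in the ongoing EEG, the variance of the recording with and
#' without the conscious component is essentially identical, so the plain
#' recording power stands in for the noise power.
#'
#' @param rec A pre-filtered `bci_recording`.
#' @param discard_startup_s Seconds dropped at the start (default 0; pass
#'   the config value to match the wall scan).
#' @return Power in V^2.
#' @export
nominal_noise_power <- function(rec, discard_startup_s = 0) {
  check_recording(rec)
  rec <- discard_startup(rec, discard_startup_s)
  mean(rec$v^2)
}

#' Signal-to-noise ratio in dB
#'
#' `10 log10(conscious_power / noise_power)`.
#'
#' @param conscious_power Conscious signal power T(c) in V^2 (> 0).
#' @param noise_power Nominal noise power sigma_r^2 in V^2 (> 0).
#' @return SNR in dB.
#' @examples
#' snr_db(3.70e-10, 2.75e-9) # -8.71 dB
#' @export
snr_db <- function(conscious_power, noise_power) {
  if (any(conscious_power <= 0)) abort("`conscious_power` must be positive.")
  if (any(noise_power <= 0)) abort("`noise_power` must be positive.")
  10 * log10(conscious_power / noise_power)
}

#' Estimate the SNR of a recording
#'
#' Combines the conscious signal power (from an evoked average or a given
#' peak amplitude) with the recording's nominal noise power. In
#' `snr_mode = "frequency"` the conscious power is reduced by the
#' configured band-power reduction before the ratio is taken.
#'
#' @param rec A pre-filtered `bci_recording` supplying the noise power.
#' @param ev Optional `bci_events`: when given, `c_max` is estimated by
#'   [evoked_average()] on `rec`.
#' @param c_max Peak conscious amplitude in volts; required when `ev` is
#'   not given (e.g. taken from a separate oddball session).
#' @param config An [analysis_config()].
#' @return A one-row tibble of class `bci_snr`: `snr_db`,
#'   `conscious_power`, `noise_power`, `mode`, `convention`, `c_max`.
#' @export
estimate_snr <- function(rec, ev = NULL, c_max = NULL,
                         config = analysis_config()) {
  check_recording(rec)
  if (is.null(c_max)) {
    if (is.null(ev)) abort("give either `ev` or `c_max`.")
    evk <- evoked_average(rec, ev, epoch_ms = config$epoch_ms,
                          baseline_ms = config$baseline_ms,
                          search_ms = config$search_ms)
    c_max <- evk$c_max
  }
  t_time <- conscious_power_time(c_max)
  t_c <- if (config$snr_mode == "frequency") {
    conscious_power_freq(t_time, config$reduction_fraction,
                         config$freq_power_convention)
  } else {
    t_time
  }
  noise <- nominal_noise_power(rec, config$discard_startup_s)
  out <- tibble(
    snr_db = snr_db(t_c, noise),
    conscious_power = t_c,
    noise_power = noise,
    mode = config$snr_mode,
    convention = if (config$snr_mode == "frequency")
      config$freq_power_convention else NA_character_,
    c_max = c_max
  )
  class(out) <- c("bci_snr", class(out))
  out
}
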