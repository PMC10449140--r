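#' Specification of a synthetic single-channel EEG recording
#'
#' Describes a recording as a sum of labelled components whose ground truth
#' is retained: 1/f^slope background EEG (~20 uV RMS), an optional
#' amplitude-modulated 10 Hz alpha rhythm, broadband (>20 Hz-dominant) EMG
#' bursts up to jaw-clench size (~1 mV peak), tonic EMG, low-frequency
#' eye-blink pulses, saccade/movement steps, and mains interference.
#' Generation is a pure function of (spec, seed).
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 250).
#' @param background_rms Background EEG RMS in volts (default 20e-6).
#' @param background_slope Spectral exponent of the 1/f^slope background
#'   (default 1; 0 gives white noise).
#' @param alpha_amp Peak amplitude (V) of a waxing-waning 10 Hz alpha
#'   rhythm; 0 disables.
#' @param emg_tonic Constant EMG level as a multiple of `background_rms`
#'   (0 disables).
#' @param emg_schedule Tibble/data frame with columns `onset_s`,
#'   `duration_s`, `gain`: broadband bursts, high-passed at 20 Hz, with
#'   0.25 s raised-cosine onset/offset ramps; `gain` is the burst RMS as a
#'   multiple of `background_rms`.
#' @param blink_schedule Numeric vector of blink onset times (s). Each
#'   blink is a biphasic ~400 ms raised-cosine pulse.
#' @param blink_amp Blink peak amplitude in volts (default 150e-6).
#' @param saccade_schedule Tibble/data frame with columns `onset_s`,
#'   `step_v`: smoothed EOG potential steps (also used for movement
#'   artefacts).
#' @param mains_amp Mains amplitude in volts (default 0).
#' @param mains_hz Mains frequency (default 50).
#' @param seed Default RNG seed used by [generate_recording()].
#' @return A list of class `bci_synth_spec`.
#' @export
synthetic_spec <- function(duration_s = 120, fs = 250,
                           background_rms = 20e-6, background_slope = 1,
                           alpha_amp = 0, emg_tonic = 0,
                           emg_schedule = NULL, blink_schedule = numeric(),
                           blink_amp = 150e-6, saccade_schedule = NULL,
                           mains_amp = 0, mains_hz = 50, seed = 1L) {
  if (duration_s <= 0 || fs <= 0) abort("duration and fs must be positive.")
  emg_schedule <- normalise_schedule(emg_schedule,
                                     c("onset_s", "duration_s", "gain"))
  saccade_schedule <- normalise_schedule(saccade_schedule,
                                        c("onset_s", "step_v"))
  if (any(emg_schedule$gain < 0)) abort("EMG gains must be >= 0.")
  check_within <- function(x, what) {
    if (length(x) && (any(x < 0) | any(x >= duration_s))) {
      abort(sprintf("%s onsets must lie within [0, duration).", what))
    }
  }
  check_within(emg_schedule$onset_s, "EMG burst")
  check_within(blink_schedule, "blink")
  check_within(saccade_schedule$onset_s, "saccade")
  structure(list(
    duration_s = duration_s, fs = fs, background_rms = background_rms,
    background_slope = background_slope, alpha_amp = alpha_amp,
    emg_tonic = emg_tonic, emg_schedule = emg_schedule,
    blink_schedule = as.numeric(blink_schedule), blink_amp = blink_amp,
    saccade_schedule = saccade_schedule, mains_amp = mains_amp,
    mains_hz = mains_hz, seed = seed
  ), class = "bci_synth_spec")
}

normalise_schedule <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                       cols))
  }
  x <- as.data.frame(x)
  if (!all(cols %in% names(x))) {
    abort(sprintf("schedule needs columns: %s", paste(cols, collapse = ", ")))
  }
  as_tibble(x[cols])
}

#' Generate a synthetic EEG recording with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed; defaults to `spec$seed`. Same (spec, seed) gives a
#'   bit-identical recording.
#' @param ... Labels (`subject`, `task`, `channel`) forwarded to
#'   [recording()].
#' @return A list with elements
#'   * `recording`: the summed `bci_recording` (exactly the sum of the
#'     components),
#'   * `components`: tibble with one column per component (`background`,
#'     `alpha`, `emg`, `eog`, `mains`), in volts,
#'   * `truth`: list with `std_ratio` (programmed ratio of the largest to
#'     the quietest within-window standard deviation, from the component
#'     amplitudes, ignoring band-limiting by later filters) and the
#'     programmed component RMS values.
#' @export
generate_recording <- function(spec, seed = NULL, ...) {
  if (!inherits(spec, "bci_synth_spec")) {
    abort("`spec` must come from synthetic_spec().")
  }
  if (is.null(seed)) seed <- spec$seed
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  tt <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    background <- shaped_noise(n, fs, spec$background_slope) *
      spec$background_rms
    alpha <- if (spec$alpha_amp > 0) {
      env <- (1 + sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))) / 2
      spec$alpha_amp * env * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
    } else {
      numeric(n)
    }
    emg_gain <- rep(spec$emg_tonic, n)
    if (nrow(spec$emg_schedule)) {
      for (i in seq_len(nrow(spec$emg_schedule))) {
        b <- spec$emg_schedule[i, ]
        emg_gain <- emg_gain +
          b$gain * burst_envelope(tt, b$onset_s, b$duration_s, ramp_s = 0.25)
      }
    }
    emg <- if (any(emg_gain > 0)) {
      emg_unit(n, fs) * emg_gain * spec$background_rms
    } else {
      numeric(n)
    }
    eog <- numeric(n)
    for (on in spec$blink_schedule) {
      eog <- eog + blink_pulse(tt, on, spec$blink_amp)
    }
    if (nrow(spec$saccade_schedule)) {
      for (i in seq_len(nrow(spec$saccade_schedule))) {
        s <- spec$saccade_schedule[i, ]
        eog <- eog + s$step_v * smooth_step(tt, s$onset_s, rise_s = 0.05)
      }
    }
    mains <- if (spec$mains_amp > 0) {
      spec$mains_amp * sin(2 * pi * spec$mains_hz * tt + runif(1, 0, 2 * pi))
    } else {
      numeric(n)
    }
  })
  v <- background + alpha + emg + eog + mains
  quiet_var <- spec$background_rms^2 * (1 + spec$emg_tonic^2) +
    spec$alpha_amp^2 * 3 / 8 + spec$mains_amp^2 / 2
  max_gain <- if (nrow(spec$emg_schedule)) max(spec$emg_schedule$gain) else 0
  loud_var <- quiet_var + (max_gain * spec$background_rms)^2
  truth <- list(
    std_ratio = if (quiet_var > 0) sqrt(loud_var / quiet_var) else NA_real_,
    background_rms = spec$background_rms,
    max_burst_rms = max_gain * spec$background_rms
  )
  list(
    recording = recording(v, fs = fs, ...),
    components = tibble(t = tt, background = background, alpha = alpha,
                        emg = emg, eog = eog, mains = mains),
    truth = truth
  )
}

# unit-RMS Gaussian noise with a 1/f^(slope) power spectrum
shaped_noise <- function(n, fs, slope) {
  x <- rnorm(n)
  if (slope != 0) {
    sp <- fft(x)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2] # two-sided frequency axis
    w <- ifelse(f < 0.1, 0, f^(-slope / 2)) # no DC / sub-0.1 Hz power
    x <- Re(fft(sp * w, inverse = TRUE)) / n
  }
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# unit-RMS broadband EMG carrier: white noise high-passed at 20 Hz
emg_unit <- function(n, fs) {
  hp <- signal::butter(4, 20 / (fs / 2), type = "high")
  x <- as.numeric(signal::filter(hp, rnorm(n)))
  x / sqrt(mean(x^2))
}

# raised-cosine on/off envelope, flat in the middle
burst_envelope <- function(tt, onset, duration, ramp_s = 0.25) {
  u <- (tt - onset) / ramp_s
  d <- (onset + duration - tt) / ramp_s
  env <- pmin(1, pmax(0, u), pmax(0, d))
  # smooth the linear ramps into raised cosines
  ifelse(env > 0 & env < 1, (1 - cos(pi * env)) / 2, env)
}

# biphasic blink: 250 ms positive lobe then 150 ms negative rebound
blink_pulse <- function(tt, onset, amp) {
  p <- numeric(length(tt))
  u1 <- (tt - onset) / 0.25
  in1 <- u1 >= 0 & u1 <= 1
  p[in1] <- amp * (1 - cos(2 * pi * u1[in1])) / 2
  u2 <- (tt - onset - 0.25) / 0.15
  in2 <- u2 >= 0 & u2 <= 1
  p[in2] <- p[in2] - 0.4 * amp * (1 - cos(2 * pi * u2[in2])) / 2
  p
}

# saccade / movement artefact: raised-cosine smoothed potential step
smooth_step <- function(tt, onset, rise_s = 0.05) {
  u <- (tt - onset) / rise_s
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
}

#' Specification of a synthetic oddball (P300) session
#'
#' Oddball stimuli arrive after inter-stimulus intervals drawn uniformly
#' from `isi_range_s` (default 7--13 s); each adds a positive
#' raised-cosine P300 deflection to the ongoing signal, peaking
#' `p300_latency_ms` after the stimulus.
#'
#' @param base A [synthetic_spec()] describing the ongoing signal.
#' @param isi_range_s Inter-stimulus interval range in seconds.
#' @param p300_amp P300 template peak amplitude in volts (e.g. 19e-6).
#' @param p300_latency_ms Latency of the template peak (default 300 ms).
#' @param p300_width_ms Template half-width: support is
#'   `latency +/- width` (default 200 ms).
#' @return A list of class `bci_oddball_spec`.
#' @export
oddball_spec <- function(base = synthetic_spec(duration_s = 300),
                         isi_range_s = c(7, 13), p300_amp = 19e-6,
                         p300_latency_ms = 300, p300_width_ms = 200) {
  if (!inherits(base, "bci_synth_spec")) {
    abort("`base` must come from synthetic_spec().")
  }
  if (p300_amp < 0) abort("`p300_amp` must be >= 0.")
  if (isi_range_s[1] <= 0 || isi_range_s[2] < isi_range_s[1]) {
    abort("`isi_range_s` must be an increasing positive range.")
  }
  structure(list(base = base, isi_range_s = isi_range_s,
                 p300_amp = p300_amp, p300_latency_ms = p300_latency_ms,
                 p300_width_ms = p300_width_ms),
            class = "bci_oddball_spec")
}

#' Generate a synthetic oddball session
#'
#' Event times accumulate Uniform(isi) draws until the session ends; the
#' P300 template is added at each event. The ground-truth template is
#' returned so recovery can be checked.
#'
#' @param spec A [oddball_spec()].
#' @param seed RNG seed; defaults to the base spec's seed.
#' @param ... Labels forwarded to [recording()].
#' @return A list: `recording` (`bci_recording`), `events` (`bci_events`),
#'   `template` (tibble `time_ms`, `v` of the true deflection), and the
#'   base generator's `truth`.
#' @export
generate_oddball_session <- function(spec, seed = NULL, ...) {
  if (!inherits(spec, "bci_oddball_spec")) {
    abort("`spec` must come from oddball_spec().")
  }
  base <- spec$base
  if (is.null(seed)) seed <- base$seed
  dur <- base$duration_s
  gen <- generate_recording(base, seed = seed, ...)
  # epoching needs a complete post-stimulus window: leave 1 s headroom
  ev_times <- withr::with_seed(seed + 104729L, {
    tms <- numeric()
    t_cur <- 0
    repeat {
      t_cur <- t_cur + runif(1, spec$isi_range_s[1], spec$isi_range_s[2])
      if (t_cur >= dur - 1) break
      tms <- c(tms, t_cur)
    }
    tms
  })
  if (length(ev_times) == 0L) {
    abort("session too short to contain a single inter-stimulus interval.")
  }
  fs <- base$fs
  tt <- gen$components$t
  lat <- spec$p300_latency_ms / 1000
  hw <- spec$p300_width_ms / 1000
  template_of <- function(u) {
    # raised cosine on [lat - hw, lat + hw], peak p300_amp at lat
    ifelse(abs(u - lat) <= hw,
           spec$p300_amp * (1 + cos(pi * (u - lat) / hw)) / 2, 0)
  }
  p300 <- numeric(length(tt))
  for (on in ev_times) p300 <- p300 + template_of(tt - on)
  v <- gen$recording$v + p300
  rec <- recording(v, fs = fs, ...)
  tpl_ms <- seq(-200, 600, by = 1000 / fs)
  list(
    recording = rec,
    events = events(ev_times, duration = dur),
    template = tibble(time_ms = tpl_ms, v = template_of(tpl_ms / 1000)),
    truth = gen$truth
  )
}
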