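#' The five causal EEG pre-filtering chains
#'
#' Every chain is applied as a single causal (forward-only) IIR pass, as
#' required for realtime closed-loop BCI use; no zero-phase
#' forward-backward filtering is offered. The setups are:
#'
#' * `fullband`: 0.1 Hz 4th-order Butterworth highpass + mains bandstop.
#'   Worst case: the whole EMG spectrum interferes with detection.
#' * `delta`: 0.1--3 Hz 4th-order Butterworth bandpass + mains bandstop.
#'   Isolates the band where eye blinks, saccades and cable movement live.
#' * `wide`: 8--18 Hz 4th-order Butterworth bandpass + mains bandstop; the
#'   motor-imagery band. The bandpass itself removes DC (0 Hz is in its
#'   stopband), so no extra DC stage is added.
#' * `alpha`: 8--12 Hz 4th-order Butterworth bandpass + mains bandstop;
#'   narrow alpha band around 10 Hz, rejecting most EMG power.
#' * `derivative`: plain first difference `y[n] = x[n] - x[n-1]` (not scaled
#'   by the sampling rate) + mains bandstop.
#'
#' The mains bandstop is a 4th-order Butterworth stop band of half-width
#' 2 Hz (e.g. 49--51 Hz), narrow enough to spare the 20--45 Hz band where
#' EMG contamination is diagnosed.
#'
#' @param setup Chain name, one of `"fullband"`, `"delta"`, `"wide"`,
#'   `"alpha"`, `"derivative"`.
#' @param fs Sampling rate in Hz.
#' @param mains_hz Mains frequency (50 or 60 Hz).
#' @return A list of class `bci_filter_chain` with elements `setup`, `fs`,
#'   and `stages` (each stage: `kind`, `order`, `corners_hz`, and `b`/`a`
#'   transfer-function coefficients).
#' @examples
#' ch <- design_chain("alpha", fs = 250)
#' chain_response(ch, c(10, 50))
#' @export
design_chain <- function(setup, fs, mains_hz = 50) {
  setup <- arg_match(setup, filter_setup_names())
  if (fs <= 0) abort("`fs` must be positive.")
  nyq <- fs / 2
  stages <- switch(setup,
    fullband = list(stage_butter("highpass", 4, 0.1, fs)),
    delta = list(stage_butter("bandpass", 4, c(0.1, 3), fs)),
    wide = list(stage_butter("bandpass", 4, c(8, 18), fs)),
    alpha = list(stage_butter("bandpass", 4, c(8, 12), fs)),
    derivative = list(list(kind = "difference", order = 1L,
                           corners_hz = numeric(),
                           b = c(1, -1), a = 1))
  )
  stages <- c(stages, list(stage_butter("bandstop", 4,
                                        mains_hz + c(-2, 2), fs)))
  for (st in stages) {
    if (length(st$corners_hz) && any(st$corners_hz >= nyq)) {
      abort(sprintf("corner frequency %g Hz is at or above Nyquist (%g Hz).",
                    max(st$corners_hz), nyq))
    }
  }
  structure(list(setup = setup, fs = fs, mains_hz = mains_hz,
                 stages = stages),
            class = "bci_filter_chain")
}

filter_setup_names <- function() {
  c("fullband", "delta", "wide", "alpha", "derivative")
}

# Butterworth stage via signal::butter. `order` is the overall filter order;
# band filters take order/2 pole pairs.
stage_butter <- function(kind, order, corners_hz, fs) {
  if (any(corners_hz >= fs / 2)) {
    abort(sprintf("corner frequency %g Hz is at or above Nyquist (%g Hz).",
                  max(corners_hz), fs / 2))
  }
  w <- corners_hz / (fs / 2)
  flt <- switch(kind,
    highpass = signal::butter(order, w, type = "high"),
    lowpass = signal::butter(order, w, type = "low"),
    bandpass = signal::butter(order / 2, w, type = "pass"),
    bandstop = signal::butter(order / 2, w, type = "stop")
  )
  list(kind = kind, order = as.integer(order), corners_hz = corners_hz,
       b = as.numeric(flt$b), a = as.numeric(flt$a))
}

#' @export
print.bci_filter_chain <- function(x, ...) {
  cat(sprintf("<bci_filter_chain> setup '%s' @ %g Hz\n", x$setup, x$fs))
  for (st in x$stages) {
    cat(sprintf("  %s order %d %s\n", st$kind, st$order,
                if (length(st$corners_hz))
                  paste0("[", paste(st$corners_hz, collapse = "-"), " Hz]")
                else ""))
  }
  invisible(x)
}

#' Apply a pre-filter chain to a recording
#'
#' Single causal pass through every stage, zero initial conditions. Output
#' has the same length as the input and the recording's provenance flag is
#' set to the chain's setup name.
#'
#' @param rec A `bci_recording`.
#' @param chain A `bci_filter_chain` from [design_chain()], or a setup name
#'   (then the chain is designed at the recording's sampling rate).
#' @param mains_hz Mains frequency, used only when `chain` is a name.
#' @return The filtered `bci_recording`.
#' @export
apply_chain <- function(rec, chain, mains_hz = 50) {
  check_recording(rec)
  if (is.character(chain)) {
    chain <- design_chain(chain, fs = rec_fs(rec), mains_hz = mains_hz)
  }
  if (!inherits(chain, "bci_filter_chain")) {
    abort("`chain` must be a bci_filter_chain or a setup name.")
  }
  if (!isTRUE(all.equal(chain$fs, rec_fs(rec)))) {
    abort(sprintf("chain designed for fs = %g Hz, recording is %g Hz.",
                  chain$fs, rec_fs(rec)))
  }
  v <- rec$v
  for (st in chain$stages) {
    v <- as.numeric(signal::filter(st$b, st$a, v))
  }
  out <- rec
  out$v <- v
  attr(out, "filter_setup") <- chain$setup
  out
}

#' Frequency response of a filter chain
#'
#' Evaluates the combined transfer function of all stages on the unit
#' circle.
#'
#' @param chain A `bci_filter_chain`.
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @return A tibble with columns `freq_hz`, `gain` (linear magnitude) and
#'   `gain_db`.
#' @export
chain_response <- function(chain, freq_hz) {
  if (!inherits(chain, "bci_filter_chain")) {
    abort("`chain` must be a bci_filter_chain.")
  }
  gain <- vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / chain$fs)
    g <- 1 + 0i
    for (st in chain$stages) {
      g <- g * sum(st$b * z^(seq_along(st$b) - 1)) /
        sum(st$a * z^(seq_along(st$a) - 1))
    }
    Mod(g)
  }, numeric(1))
  tibble(freq_hz = freq_hz, gain = gain, gain_db = 20 * log10(gain))
}

#' @exportS3Method generics::tidy
tidy.bci_filter_chain <- function(x, ...) {
  list_rbind(map(x$stages, function(st) {
    tibble(kind = st$kind, order = st$order,
           corner_lo_hz = if (length(st$corners_hz)) min(st$corners_hz) else NA_real_,
           corner_hi_hz = if (length(st$corners_hz)) max(st$corners_hz) else NA_real_)
  }))
}
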