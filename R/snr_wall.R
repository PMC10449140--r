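#' Sliding-window noise power scan
#'
#' Mean-square power (no mean subtraction) over a window slid across the
#' recording, by default sample by sample. This is the test statistic
#' `T(x) = (1/N) sum x[n]^2` evaluated on every chunk of length
#' `window_s` seconds; its extrema over the recording define the noise
#' uncertainty.
#'
#' @param rec A `bci_recording` (normally already pre-filtered and with the
#'   startup transient discarded -- [profile_recording()] handles both).
#' @param window_s Window length tau in seconds (default 2).
#' @param stride Samples between consecutive window starts (default 1).
#' @return A tibble of class `bci_sliding_power` with columns `start_s`
#'   (window start time) and `power` (V^2), and attributes `window_s`,
#'   `stride`, `fs`.
#' @export
sliding_power <- function(rec, window_s = 2, stride = 1L) {
  check_recording(rec)
  fs <- rec_fs(rec)
  w <- as.integer(round(window_s * fs))
  if (w < 1L) abort("`window_s` is shorter than one sample.")
  stride <- as.integer(stride)
  if (stride < 1L) abort("`stride` must be >= 1 sample.")
  x <- rec$v
  n <- length(x)
  if (n < w) {
    abort(sprintf(
      "recording (%d samples) is shorter than one window (%d samples).",
      n, w))
  }
  # cumulative-sum evaluation of all window mean squares
  cs <- cumsum(c(0, x^2))
  starts <- seq.int(1L, n - w + 1L, by = stride)
  powers <- (cs[starts + w] - cs[starts]) / w
  powers[powers < 0] <- 0 # guard against roundoff on tiny signals
  out <- tibble(start_s = (starts - 1L) / fs, power = powers)
  class(out) <- c("bci_sliding_power", class(out))
  attr(out, "window_s") <- window_s
  attr(out, "stride") <- stride
  attr(out, "fs") <- fs
  out
}

#' Noise-power extrema of a sliding scan
#'
#' @param sps A `bci_sliding_power` from [sliding_power()].
#' @return A named list with `sigma2_min` and `sigma2_max` (V^2).
#' @details A zero minimum (dead channel / flatline window) is refused
#'   explicitly, since the noise-uncertainty ratio would be infinite.
#' @export
noise_extrema <- function(sps) {
  if (!inherits(sps, "bci_sliding_power")) {
    abort("`sps` must come from sliding_power().")
  }
  if (nrow(sps) == 0L) abort("empty sliding-power series.")
  s2min <- min(sps$power)
  s2max <- max(sps$power)
  if (s2min <= 0) {
    abort(paste0("minimum window power is zero (flatline / dead channel): ",
                 "the noise uncertainty would be infinite."))
  }
  list(sigma2_min = s2min, sigma2_max = s2max)
}

#' Noise uncertainty factor rho
#'
#' The ratio of the largest to the smallest noise *standard deviation*
#' observed across sliding windows: `rho = sqrt(sigma2_max / sigma2_min)`.
#'
#' @param sigma2_min,sigma2_max Window-power extrema in V^2,
#'   `0 < sigma2_min <= sigma2_max`.
#' @return Dimensionless `rho >= 1`.
#' @examples
#' noise_rho(1.15e-10, 2.00e-8) # about 13.2
#' @export
noise_rho <- function(sigma2_min, sigma2_max) {
  if (any(sigma2_min <= 0)) abort("`sigma2_min` must be positive.")
  if (any(sigma2_max < sigma2_min)) {
    abort("`sigma2_max` must be >= `sigma2_min`.")
  }
  sqrt(sigma2_max / sigma2_min)
}

#' SNR-wall in dB
#'
#' The SNR below which no averaging length achieves the target error
#' probabilities under noise uncertainty `rho`: on a linear scale the wall
#' is `rho - 1/rho`, reported as `10 log10(rho - 1/rho)` dB. At `rho = 1`
#' (perfectly known noise) the linear wall is 0 and the dB value is `-Inf`:
#' any positive SNR is detectable.
#'
#' @param rho Noise uncertainty, `>= 1`.
#' @return SNR-wall in dB (`-Inf` when `rho == 1`).
#' @examples
#' snr_wall_db(13.21) # 11.18 dB
#' @export
snr_wall_db <- function(rho) {
  if (any(rho < 1)) abort("`rho` must be >= 1.")
  ifelse(rho == 1, -Inf, 10 * log10(rho - 1 / rho))
}

#' Noise profile of a recording: extrema, rho, nominal power, SNR-wall
#'
#' Composes [sliding_power()] -> [noise_extrema()] -> [noise_rho()] ->
#' [snr_wall_db()]. The nominal noise power `sigma2_nominal` is the
#' whole-recording mean square (the direct route); the alternative
#' `rho * sigma2_min` route is also reported as `sigma2_nominal_rho` for
#' comparison. The first `discard_startup_s` seconds are excluded from all
#' power computations so that IIR startup transients cannot masquerade as
#' the maximum noise variance.
#'
#' @param rec A pre-filtered `bci_recording`.
#' @param config A [analysis_config()]; `window_s`, `stride` and
#'   `discard_startup_s` are used.
#' @return A one-row tibble of class `bci_noise_profile` with columns
#'   `sigma2_min`, `sigma2_max`, `rho`, `sigma2_nominal`,
#'   `sigma2_nominal_rho`, `snr_wall_db`, `window_s`, `n_windows`.
#' @export
profile_recording <- function(rec, config = analysis_config()) {
  check_recording(rec)
  rec <- discard_startup(rec, config$discard_startup_s)
  sps <- sliding_power(rec, window_s = config$window_s,
                       stride = config$stride)
  ex <- noise_extrema(sps)
  rho <- noise_rho(ex$sigma2_min, ex$sigma2_max)
  out <- tibble(
    sigma2_min = ex$sigma2_min,
    sigma2_max = ex$sigma2_max,
    rho = rho,
    sigma2_nominal = mean(rec$v^2),
    sigma2_nominal_rho = rho * ex$sigma2_min,
    snr_wall_db = snr_wall_db(rho),
    window_s = config$window_s,
    n_windows = nrow(sps)
  )
  class(out) <- c("bci_noise_profile", class(out))
  attr(out, "filter_setup") <- rec_filter_setup(rec)
  out
}

discard_startup <- function(rec, discard_s) {
  if (discard_s <= 0) return(rec)
  fs <- rec_fs(rec)
  drop <- as.integer(round(discard_s * fs))
  if (drop >= nrow(rec)) {
    abort("`discard_startup_s` removes the entire recording.")
  }
  out <- rec[-seq_len(drop), , drop = FALSE]
  for (a in c("fs", "subject", "task", "channel", "filter_setup")) {
    attr(out, a) <- attr(rec, a)
  }
  class(out) <- class(rec)
  out
}
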