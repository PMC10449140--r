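#' Standard normal upper-tail probability and its inverse
#'
#' `q_function(x) = P(Z > x)` for standard normal Z; `q_inverse` is its
#' inverse. These are the Q and Q^-1 of classical detection theory.
#'
#' @param x Real number(s).
#' @param p Probability(ies) in (0, 1).
#' @return `q_function()`: probabilities; `q_inverse()`: real numbers.
#' @export
q_function <- function(x) pnorm(x, lower.tail = FALSE)

#' @rdname q_function
#' @export
q_inverse <- function(p) qnorm(p, lower.tail = FALSE)

#' False-alarm probability of the energy detector
#'
#' Asymptotic (large-N Gaussian) false-alarm probability of comparing the
#' mean-square of `n` real Gaussian noise samples against threshold
#' `gamma`, under worst-case noise uncertainty: the noise sits at its
#' largest admissible variance `rho * sigma2`. `rho = 1` recovers the
#' stationary-noise expression.
#'
#' @param gamma Detection threshold in V^2.
#' @param sigma2 Nominal noise power in V^2.
#' @param n Number of averaged samples (>= 1).
#' @param rho Noise uncertainty factor (>= 1, default 1).
#' @return Probability of false alarm.
#' @export
p_false_alarm <- function(gamma, sigma2, n, rho = 1) {
  check_detector_args(sigma2 = sigma2, n = n, rho = rho)
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  q_function((gamma - rho * sigma2) / (sqrt(2 / n) * rho * sigma2))
}

#' Detection probability of the energy detector
#'
#' Asymptotic detection probability with signal power `t_c` present, under
#' worst-case noise uncertainty for detection: the signal rides on the
#' *smallest* admissible noise variance `sigma2 / rho`.
#'
#' @param gamma Detection threshold in V^2.
#' @param t_c Conscious signal power T(c) in V^2 (>= 0).
#' @param sigma2 Nominal noise power in V^2.
#' @param n Number of averaged samples.
#' @param rho Noise uncertainty factor (>= 1, default 1).
#' @return Probability of detection.
#' @export
p_detection <- function(gamma, t_c, sigma2, n, rho = 1) {
  check_detector_args(sigma2 = sigma2, n = n, rho = rho)
  if (any(t_c < 0)) abort("`t_c` must be >= 0.")
  mu <- t_c + sigma2 / rho
  q_function((gamma - mu) / (sqrt(2 / n) * mu))
}

check_detector_args <- function(sigma2, n, rho) {
  if (any(sigma2 <= 0)) abort("`sigma2` must be positive.")
  if (any(n < 1)) abort("`n` must be >= 1.")
  if (any(rho < 1)) abort("`rho` must be >= 1.")
}

#' Samples required for robust detection, stationary noise
#'
#' Number of averaged samples N at which an energy detector meets the
#' target false-alarm and detection probabilities when the noise variance
#' is known exactly:
#' `N = 2 [Qinv(P_FA) - Qinv(P_D) (1 + SNR)]^2 / SNR^2`.
#' With stationary noise this is always finite: a longer averaging time
#' always buys reliability.
#'
#' @param p_fa Target false-alarm probability, `0 < p_fa < p_d`.
#' @param p_d Target detection probability, `p_d < 1`.
#' @param snr_linear Linear SNR `T(c)/sigma2` (> 0).
#' @return A one-row tibble with `n_raw` (exact real value) and `n_samples`
#'   (ceiling-rounded integer count).
#' @export
samples_required_stationary <- function(p_fa, p_d, snr_linear) {
  check_targets(p_fa, p_d)
  if (snr_linear <= 0) abort("`snr_linear` must be positive.")
  if (p_fa == p_d) {
    warn("p_fa == p_d: the requirement is degenerate (N = 0).")
  }
  n_raw <- 2 * (q_inverse(p_fa) - q_inverse(p_d) * (1 + snr_linear))^2 /
    snr_linear^2
  tibble(n_raw = n_raw, n_samples = ceiling(n_raw))
}

check_targets <- function(p_fa, p_d) {
  if (p_fa <= 0 || p_fa >= 1 || p_d <= 0 || p_d >= 1) {
    abort("`p_fa` and `p_d` must lie strictly between 0 and 1.")
  }
  if (p_fa > p_d) abort("`p_fa` must not exceed `p_d`.")
}

#' Samples required for robust detection under noise uncertainty
#'
#' Low-SNR sample complexity with noise variance only known within a
#' factor `rho`:
#' `N = 2 [Qinv(P_FA) - Qinv(P_D)]^2 / [SNR - (rho - 1/rho)]^2`.
#' When the SNR does not exceed the linear SNR-wall `rho - 1/rho`, the
#' required averaging length diverges: `Inf` is returned as a value, not an
#' error -- detection is impossible no matter how long one averages.
#'
#' @inheritParams samples_required_stationary
#' @param rho Noise uncertainty factor (>= 1).
#' @return A one-row tibble with `n_raw` and `n_samples` (both `Inf` at or
#'   below the wall) and `wall_linear`.
#' @export
samples_required_uncertain <- function(p_fa, p_d, snr_linear, rho) {
  check_targets(p_fa, p_d)
  if (snr_linear <= 0) abort("`snr_linear` must be positive.")
  if (rho < 1) abort("`rho` must be >= 1.")
  wall <- rho - 1 / rho
  if (snr_linear <= wall) {
    n_raw <- Inf
  } else {
    n_raw <- 2 * (q_inverse(p_fa) - q_inverse(p_d))^2 /
      (snr_linear - wall)^2
  }
  tibble(n_raw = n_raw, n_samples = ceiling(n_raw), wall_linear = wall)
}

#' Is a conscious EEG change detectable?
#'
#' The decision rule of the whole methodology: detectable if and only if
#' the SNR is *strictly* above the SNR-wall. Equality counts as not
#' detectable (the required averaging length is already infinite there).
#'
#' @param snr_db SNR in dB.
#' @param wall_db SNR-wall in dB (may be `-Inf`).
#' @return Logical.
#' @examples
#' detectable(-8.71, 11.18) # jaw clench, fullband: FALSE
#' detectable(7, 5) # jaw clench, alpha band: TRUE
#' @export
detectable <- function(snr_db, wall_db) {
  snr_db > wall_db
}

#' Monte-Carlo simulation of the energy detector
#'
#' Draws `trials` independent realisations of `n` real Gaussian samples,
#' under H0 (noise only) and H1 (noise plus a constant-amplitude signal of
#' power `t_c`), computes the mean-square statistic for each and thresholds
#' it at `gamma`. Per-trial noise variances follow `sigma2_schedule`
#' (recycled across trials), so non-stationary schedules -- e.g. the
#' adversarial worst case with noise at `rho*sigma2` under H0 and
#' `sigma2/rho` under H1 -- can be simulated by two calls.
#'
#' `method = "gaussian"` simulates every sample; `method = "chisq"` draws
#' the sufficient statistic `n*T/sigma2` directly from its exact
#' (noncentral) chi-square distribution -- identical in law, and practical
#' for the very large `n` of the low-SNR regime.
#'
#' @param t_c Signal power in V^2 under H1 (the signal is the constant
#'   `sqrt(t_c)`).
#' @param sigma2_schedule Per-trial noise variances (V^2), recycled to
#'   `trials`.
#' @param n Samples averaged per trial.
#' @param gamma Threshold in V^2.
#' @param trials Number of Monte-Carlo trials.
#' @param seed RNG seed; the result is a pure function of the arguments.
#' @param method `"gaussian"` (per-sample simulation) or `"chisq"` (exact
#'   sufficient-statistic sampling).
#' @return A one-row tibble: `p_fa` (empirical, H0), `p_d` (empirical,
#'   H1), `trials`, `n`.
#' @export
simulate_energy_detector <- function(t_c, sigma2_schedule, n, gamma, trials,
                                     seed = 1L,
                                     method = c("gaussian", "chisq")) {
  method <- arg_match(method)
  if (trials < 1) abort("`trials` must be >= 1.")
  if (any(sigma2_schedule <= 0)) abort("noise variances must be positive.")
  if (t_c < 0) abort("`t_c` must be >= 0.")
  s2 <- rep_len(sigma2_schedule, trials)
  amp <- sqrt(t_c)
  withr::with_seed(seed, {
    if (method == "gaussian") {
      t0 <- numeric(trials)
      t1 <- numeric(trials)
      # chunked so the sample matrix stays modest
      chunk <- max(1L, as.integer(floor(5e6 / n)))
      i <- 1L
      while (i <= trials) {
        j <- min(trials, i + chunk - 1L)
        idx <- i:j
        noise <- matrix(rnorm(n * length(idx), sd = rep(sqrt(s2[idx]),
                                                        each = n)),
                        nrow = n)
        t0[idx] <- colMeans(noise^2)
        t1[idx] <- colMeans((noise + amp)^2)
        i <- j + 1L
      }
    } else {
      # n*T/sigma2 ~ chi-square(n) under H0, noncentral with
      # ncp = n*t_c/sigma2 under H1 (constant signal in Gaussian noise)
      t0 <- s2 * rchisq(trials, df = n) / n
      t1 <- s2 * rchisq(trials, df = n, ncp = n * t_c / s2) / n
    }
    tibble(p_fa = mean(t0 > gamma), p_d = mean(t1 > gamma),
           trials = trials, n = n)
  })
}

#' Design an energy detector under noise uncertainty
#'
#' Bundles the theory: given target error probabilities, an SNR and a
#' noise uncertainty, reports the required averaging length (possibly
#' `Inf`), the linear and dB SNR-wall, whether the operating point is
#' detectable, and the worst-case threshold `gamma` that meets `p_fa` at
#' that length.
#'
#' @inheritParams samples_required_uncertain
#' @param sigma2 Nominal noise power (V^2), default 1 (gamma scales with it).
#' @return A one-row tibble of class `bci_detector_design`.
#' @export
design_detector <- function(p_fa, p_d, snr_linear, rho = 1, sigma2 = 1) {
  req <- samples_required_uncertain(p_fa, p_d, snr_linear, rho)
  gamma <- if (is.finite(req$n_samples)) {
    rho * sigma2 * (1 + sqrt(2 / req$n_samples) * q_inverse(p_fa))
  } else {
    NA_real_
  }
  out <- tibble(
    p_fa = p_fa, p_d = p_d, snr_linear = snr_linear, rho = rho,
    sigma2 = sigma2, n_raw = req$n_raw, n_samples = req$n_samples,
    gamma = gamma, wall_linear = req$wall_linear,
    wall_db = snr_wall_db(rho),
    detectable = detectable(10 * log10(snr_linear), snr_wall_db(rho))
  )
  class(out) <- c("bci_detector_design", class(out))
  out
}
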