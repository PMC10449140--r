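test_that("Q and its inverse form an exact pair", {
  expect_identical(q_function(0), 0.5)
  expect_equal(q_function(1.6449), 0.05, tolerance = 1e-3)
  expect_identical(q_inverse(0.5), 0)
  xs <- seq(-6, 6, by = 0.25)
  expect_equal(q_inverse(q_function(xs)), xs, tolerance = 1e-9)
  ps <- c(1e-9, 1e-6, 0.01, 0.3, 0.5, 0.7, 0.99, 1 - 1e-6, 1 - 1e-9)
  expect_equal(q_function(q_inverse(ps)), ps, tolerance = 1e-9)
})

test_that("false-alarm probability behaves at its anchors", {
  expect_equal(p_false_alarm(gamma = 1.3, sigma2 = 1, n = 50, rho = 1.3),
               0.5)
  gammas <- seq(0.5, 3, by = 0.1)
  pfa <- p_false_alarm(gammas, sigma2 = 1, n = 100)
  expect_true(all(diff(pfa) < 0))
})

test_that("detection probability reduces to the stationary case at rho = 1", {
  expect_equal(p_detection(gamma = 1.5, t_c = 0.5, sigma2 = 1, n = 80,
                           rho = 1), 0.5)
  # explicit stationary form
  g <- 1.3; tc <- 0.4; s2 <- 1; n <- 64
  expect_equal(p_detection(g, tc, s2, n, rho = 1),
               q_function((g - (tc + s2)) / (sqrt(2 / n) * (tc + s2))))
})

test_that("empirical detector rates match the exact chi-square law", {
  # per-sample Gaussian simulation against the exact distribution of the
  # mean-square statistic: n*T/sigma2 ~ (noncentral) chi-square
  n <- 50; gamma <- 1.4; s2 <- 1; tc <- 0.5; trials <- 2e4
  sim <- simulate_energy_detector(tc, s2, n, gamma, trials, seed = 41,
                                  method = "gaussian")
  p_fa_true <- pchisq(n * gamma / s2, df = n, lower.tail = FALSE)
  p_d_true <- pchisq(n * gamma / s2, df = n, ncp = n * tc / s2,
                     lower.tail = FALSE)
  se <- function(p) sqrt(p * (1 - p) / trials)
  expect_lt(abs(sim$p_fa - p_fa_true), 3 * se(p_fa_true))
  expect_lt(abs(sim$p_d - p_d_true), 3 * se(p_d_true))
})

test_that("gaussian and chi-square simulation paths agree in law", {
  n <- 40; gamma <- 1.25; trials <- 2e4
  a <- simulate_energy_detector(0.3, 1, n, gamma, trials, seed = 42,
                                method = "gaussian")
  b <- simulate_energy_detector(0.3, 1, n, gamma, trials, seed = 43,
                                method = "chisq")
  tol <- 4 * sqrt(0.25 / trials) * sqrt(2) # two independent MC estimates
  expect_lt(abs(a$p_fa - b$p_fa), tol)
  expect_lt(abs(a$p_d - b$p_d), tol)
})

test_that("simulation is a pure function of its seed and degenerates sanely", {
  a <- simulate_energy_detector(0.2, 1, 30, 1.2, 5000, seed = 44)
  b <- simulate_energy_detector(0.2, 1, 30, 1.2, 5000, seed = 44)
  expect_identical(a, b)
  # no signal: detection rate equals false-alarm rate within binomial error
  z <- simulate_energy_detector(0, 1, 50, 1.1, 2e4, seed = 45)
  expect_lt(abs(z$p_d - z$p_fa), 4 * sqrt(0.25 / 2e4) * sqrt(2))
})

test_that("stationary sample count matches a numeric threshold-elimination oracle", {
  p_fa <- 0.05; p_d <- 0.95
  for (snr in c(0.05, 0.1, 0.5)) {
    req <- samples_required_stationary(p_fa, p_d, snr)
    # oracle: find N where the gamma meeting P_FA equals the gamma meeting
    # P_D, searching on a continuous N grid
    mismatch <- function(nn) {
      g_fa <- 1 + sqrt(2 / nn) * q_inverse(p_fa)
      g_d <- (1 + snr) * (1 + sqrt(2 / nn) * q_inverse(p_d))
      g_fa - g_d
    }
    n_oracle <- uniroot(mismatch, c(1, 1e7), tol = 1e-9)$root
    expect_equal(req$n_raw, n_oracle, tolerance = 1e-6)
    expect_identical(req$n_samples, ceiling(req$n_raw))
  }
  # N scales as 1/snr^2 at small snr
  n1 <- samples_required_stationary(0.05, 0.95, 1e-3)$n_raw
  n2 <- samples_required_stationary(0.05, 0.95, 2e-3)$n_raw
  expect_equal(n1 / n2, 4, tolerance = 0.01)
  expect_warning(samples_required_stationary(0.2, 0.2, 0.1), "degenerate")
})

test_that("sample count under uncertainty diverges exactly at the wall", {
  rho <- 1.5
  wall <- rho - 1 / rho
  at_wall <- samples_required_uncertain(0.05, 0.95, wall, rho)
  expect_identical(at_wall$n_raw, Inf)
  expect_identical(at_wall$n_samples, Inf)
  below <- samples_required_uncertain(0.05, 0.95, wall / 2, rho)
  expect_identical(below$n_raw, Inf)
  # strictly decreasing in snr above the wall, diverging towards it
  snrs <- wall * (1 + c(0.01, 0.05, 0.2, 1, 5))
  ns <- vapply(snrs,
               function(s) samples_required_uncertain(0.05, 0.95, s,
                                                      rho)$n_raw,
               numeric(1))
  expect_true(all(is.finite(ns)))
  expect_true(all(diff(ns) < 0))
  # rho = 1 recovers the low-SNR limit of the stationary count
  snr <- 1e-4
  n_unc <- samples_required_uncertain(0.05, 0.95, snr, rho = 1)$n_raw
  n_sta <- samples_required_stationary(0.05, 0.95, snr)$n_raw
  expect_equal(n_unc / n_sta, 1, tolerance = 1e-3)
})

test_that("finite sample count and detectability agree (wall consistency)", {
  grid <- expand.grid(snr = c(0.01, 0.1, 0.5, 1, 3),
                      rho = c(1, 1.05, 1.3, 2))
  for (i in seq_len(nrow(grid))) {
    snr <- grid$snr[i]; rho <- grid$rho[i]
    fin <- is.finite(samples_required_uncertain(0.05, 0.95, snr,
                                                rho)$n_raw)
    expect_identical(fin, detectable(10 * log10(snr), snr_wall_db(rho)))
  }
})

test_that("the decision rule is a strict inequality", {
  expect_false(detectable(-8.71, 11.18)) # jaw clench, fullband
  expect_true(detectable(7, 5)) # jaw clench, alpha band
  expect_false(detectable(3.3, 3.3))
  expect_true(detectable(0.1, -Inf))
})

test_that("design_detector bundles threshold, count and decision", {
  d <- design_detector(0.05, 0.95, snr_linear = 0.5, rho = 1.1)
  expect_true(d$detectable)
  expect_true(is.finite(d$n_samples))
  # the reported gamma meets the false-alarm target at the reported n
  expect_equal(p_false_alarm(d$gamma, 1, d$n_samples, rho = 1.1), 0.05,
               tolerance = 0.005)
  d2 <- design_detector(0.05, 0.95, snr_linear = 0.1, rho = 1.5)
  expect_false(d2$detectable)
  expect_identical(d2$n_samples, Inf)
  expect_true(is.na(d2$gamma))
})
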