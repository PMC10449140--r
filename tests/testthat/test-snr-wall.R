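test_that("sliding power of simple deterministic signals", {
  rec <- recording(rep(3, 1000), fs = 250)
  sps <- sliding_power(rec, window_s = 2)
  expect_true(all(sps$power == 9))
  expect_equal(nrow(sps), 1000 - 500 + 1)

  alt <- recording(rep(c(1, -1), 500), fs = 250)
  expect_true(all(sliding_power(alt, window_s = 0.1)$power == 1))
})

test_that("sliding power matches the brute-force double loop", {
  withr::with_seed(21, x <- rnorm(1000))
  rec <- recording(x, fs = 100)
  for (st in c(1L, 7L)) {
    sps <- sliding_power(rec, window_s = 0.5, stride = st)
    expect_equal(sps$power, oracle_sliding_power(x, 50L, st),
                 tolerance = 1e-12)
  }
})

test_that("recordings shorter than one window are refused", {
  expect_error(sliding_power(white_recording(100, fs = 250), window_s = 2),
               "shorter than one window")
})

test_that("noise extrema: trivial series, flatline refusal", {
  rec <- recording(rep(1, 30), fs = 10)
  sps <- sliding_power(rec, window_s = 1)
  sps$power <- c(4e-10, 1e-10, 9e-10, rep(4e-10, nrow(sps) - 3))
  ex <- noise_extrema(sps)
  expect_equal(ex$sigma2_min, 1e-10)
  expect_equal(ex$sigma2_max, 9e-10)

  all_equal <- sliding_power(recording(rep(2, 50), fs = 10), window_s = 1)
  ex2 <- noise_extrema(all_equal)
  expect_identical(ex2$sigma2_min, ex2$sigma2_max)

  flat <- recording(c(rep(0, 20), rnorm(30)), fs = 10)
  expect_error(noise_extrema(sliding_power(flat, window_s = 1)),
               "flatline|dead")
})

test_that("two-segment noise recovers the programmed variance step", {
  withr::with_seed(22, x <- c(rnorm(5000, sd = 1), rnorm(5000, sd = 10)))
  sps <- sliding_power(recording(x, fs = 250), window_s = 2)
  # windows fully inside each segment
  inside1 <- sps$power[sps$start_s <= 16]
  inside2 <- sps$power[sps$start_s >= 20.5]
  expect_equal(min(sps$power), min(inside1), tolerance = 1e-12)
  expect_lt(abs(mean(inside1) - 1), 0.15)
  expect_lt(abs(mean(inside2) - 100) / 100, 0.15)
})

test_that("rho is the ratio of standard deviations, not variances", {
  expect_equal(noise_rho(1.15e-10, 2.00e-8), 13.1876, tolerance = 1e-4)
  expect_identical(noise_rho(3e-9, 3e-9), 1)
  expect_equal(noise_rho(1e-10, 4e-10), 2)
  expect_error(noise_rho(0, 1e-10), "positive")
  expect_error(noise_rho(2e-10, 1e-10), ">=")
})

test_that("SNR-wall in dB follows 10 log10(rho - 1/rho)", {
  expect_equal(round(snr_wall_db(13.21), 2), 11.18)
  expect_identical(snr_wall_db(1), -Inf)
  expect_equal(snr_wall_db(2), 10 * log10(1.5), tolerance = 1e-12)
  expect_error(snr_wall_db(0.9), ">= 1")
  # strictly increasing in rho above 1
  rhos <- seq(1.001, 20, length.out = 200)
  expect_true(all(diff(snr_wall_db(rhos)) > 0))
})

test_that("stationary white noise yields a near-degenerate wall", {
  rec <- white_recording(120 * 250, sd = 20e-6, seed = 23)
  prof <- profile_recording(rec, analysis_config(discard_startup_s = 0))
  expect_lt(prof$rho, 1.6)
  expect_lt(prof$snr_wall_db, 1)
})

test_that("a recording of exactly one window is its own nominal power", {
  rec <- white_recording(500, fs = 250, seed = 24)
  prof <- profile_recording(rec, analysis_config(discard_startup_s = 0))
  expect_identical(prof$rho, 1)
  expect_equal(prof$sigma2_min, prof$sigma2_nominal, tolerance = 1e-12)
  expect_identical(prof$snr_wall_db, -Inf)
})

test_that("tiled window powers average to the whole-recording power", {
  withr::with_seed(25, x <- rnorm(6000, sd = 5e-6))
  rec <- recording(x, fs = 250)
  sps <- sliding_power(rec, window_s = 2, stride = 500L)
  expect_equal(mean(sps$power), mean(x^2), tolerance = 1e-12)
  prof <- profile_recording(rec, analysis_config(discard_startup_s = 0,
                                                 stride = 500L))
  expect_lte(prof$sigma2_min, prof$sigma2_nominal)
  expect_gte(prof$sigma2_max, prof$sigma2_nominal)
})

test_that("rho is robust to the scan stride", {
  cfg1 <- analysis_config(stride = 1L)
  cfg25 <- analysis_config(stride = 25L) # fs / 10
  for (task in c("lying_eo", "sudoku", "reading")) {
    gen <- generate_recording(task_preset(task, seed = 26))
    filt <- apply_chain(gen$recording, "fullband")
    r1 <- profile_recording(filt, cfg1)$rho
    r25 <- profile_recording(filt, cfg25)$rho
    expect_lt(abs(r25 - r1) / r1, 0.02)
  }
  # steep jaw-clench burst ramps quantize the extremum more strongly
  gen <- generate_recording(task_preset("jaw_clench", seed = 26))
  filt <- apply_chain(gen$recording, "fullband")
  r1 <- profile_recording(filt, cfg1)$rho
  r25 <- profile_recording(filt, cfg25)$rho
  expect_lt(abs(r25 - r1) / r1, 0.03)
})

test_that("startup discard keeps filter transients out of the extrema", {
  # a large step decaying through the delta filter would fake sigma2_max
  v <- c(rep(500e-6, 10), rnorm(30000, sd = 20e-6))
  rec <- recording(v, fs = 250)
  filt <- apply_chain(rec, "delta")
  with_discard <- profile_recording(filt, analysis_config())
  without <- profile_recording(filt, analysis_config(discard_startup_s = 0))
  expect_lt(with_discard$rho, without$rho)
})
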