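test_that("zero-amplitude spec generates an all-zero recording", {
  spec <- synthetic_spec(duration_s = 10, background_rms = 0,
                         mains_amp = 0, seed = 51)
  gen <- generate_recording(spec)
  expect_identical(unique(gen$recording$v), 0)
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- task_preset("reading", seed = 52)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$v, b$recording$v)
  c <- generate_recording(spec, seed = 53)
  expect_false(identical(a$recording$v, c$recording$v))
})

test_that("the recording is exactly the sum of its components", {
  gen <- generate_recording(task_preset("jaw_clench", seed = 54))
  comp <- gen$components
  expect_identical(gen$recording$v,
                   comp$background + comp$alpha + comp$emg + comp$eog +
                     comp$mains)
})

test_that("jaw-clench bursts are broadband and >20 Hz dominant", {
  spec <- task_preset("jaw_clench", seed = 55)
  gen <- generate_recording(spec)
  # peak amplitudes reach the sub-mV range during clenches
  expect_gt(max(abs(gen$recording$v)), 500e-6)
  expect_lt(max(abs(gen$recording$v)), 2e-3)
  # band power above 20 Hz: burst vs quiet windows at least 20 dB apart
  hp <- signal::butter(4, 20 / 125, type = "high")
  v_hp <- as.numeric(signal::filter(hp, gen$recording$v))
  tt <- gen$recording$t
  on <- spec$emg_schedule$onset_s[2]
  burst <- v_hp[tt >= on + 0.3 & tt <= on + 1.7]
  quiet <- v_hp[tt >= on + 5 & tt <= on + 9]
  expect_gt(10 * log10(mean(burst^2) / mean(quiet^2)), 20)
  # EMG component carries little sub-20 Hz power
  lp <- signal::butter(4, 15 / 125, type = "low")
  emg_lp <- as.numeric(signal::filter(lp, gen$components$emg))
  expect_lt(mean(emg_lp^2) / mean(gen$components$emg^2), 0.05)
})

test_that("schedules outside the recording are rejected", {
  expect_error(synthetic_spec(duration_s = 10,
                              blink_schedule = c(2, 11)), "within")
  expect_error(synthetic_spec(
    duration_s = 10,
    emg_schedule = data.frame(onset_s = 2, duration_s = 1, gain = -1)),
    ">= 0")
})

test_that("oddball sessions have uniform 7-13 s inter-stimulus intervals", {
  sess <- generate_oddball_session(
    oddball_spec(synthetic_spec(duration_s = 300, seed = 56)))
  n_ev <- nrow(sess$events)
  expect_gte(n_ev, 23)
  expect_lte(n_ev, 43)
  isis <- diff(sess$events$time_s)
  expect_true(all(isis >= 7 & isis <= 13))
  # mean ISI over 10 sessions is close to 10 s
  all_isis <- unlist(lapply(1:10, function(i) {
    s <- generate_oddball_session(
      oddball_spec(synthetic_spec(duration_s = 300, seed = 56 + i)))
    diff(s$events$time_s)
  }))
  se <- sqrt(3) / sqrt(length(all_isis)) # Var U(7,13) = 3
  expect_lt(abs(mean(all_isis) - 10), 3 * se)
})

test_that("a zero-amplitude P300 is not hallucinated by averaging", {
  sess <- generate_oddball_session(
    oddball_spec(synthetic_spec(duration_s = 300, seed = 57), p300_amp = 0))
  filt <- apply_chain(sess$recording, "fullband")
  evk <- evoked_average(filt, sess$events)
  # noise floor of the average: background RMS / sqrt(n), with headroom
  # for taking a maximum over the correlated search window
  floor_v <- 20e-6 / sqrt(evk$n_events)
  expect_lt(abs(evk$c_max), 3 * floor_v)
})

test_that("the programmed P300 template is returned and embedded", {
  osp <- oddball_spec(synthetic_spec(duration_s = 120, background_rms = 0,
                                     seed = 58), p300_amp = 19e-6)
  sess <- generate_oddball_session(osp)
  evk <- evoked_average(sess$recording, sess$events)
  # events land at continuous times, so each epoch samples the template
  # slightly off its peak: agreement to ~1%
  expect_equal(evk$c_max, 19e-6, tolerance = 0.01)
  expect_equal(evk$latency_ms, 300, tolerance = 4)
  expect_equal(max(sess$template$v), 19e-6, tolerance = 1e-8)
})

test_that("task presets cover the eight tasks with plausible phenomenology", {
  expect_length(task_names(), 8L)
  for (task in task_names()) {
    spec <- task_preset(task, seed = 59)
    expect_s3_class(spec, "bci_synth_spec")
    gen <- generate_recording(spec)
    expect_identical(nrow(gen$recording), 30000L)
  }
  # eyes-closed rest has an alpha rhythm and no blinks
  ec <- task_preset("lying_ec", seed = 59)
  expect_gt(ec$alpha_amp, 0)
  expect_length(ec$blink_schedule, 0L)
  # reading blinks far more often than lying with eyes open
  expect_gt(length(task_preset("reading", seed = 59)$blink_schedule),
            2 * length(task_preset("lying_eo", seed = 59)$blink_schedule))
})

test_that("programmed noise std ratio is recovered through the pipeline", {
  # controlled two-level design: white background, flat-topped bursts
  spec <- synthetic_spec(
    duration_s = 120, background_rms = 20e-6, background_slope = 0,
    emg_schedule = data.frame(onset_s = c(30, 70), duration_s = 4,
                              gain = 50),
    seed = 60)
  gen <- generate_recording(spec)
  filt <- apply_chain(gen$recording, "fullband")
  prof <- profile_recording(filt, analysis_config())
  expect_lt(abs(prof$rho - gen$truth$std_ratio) / gen$truth$std_ratio,
            0.15)
})
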