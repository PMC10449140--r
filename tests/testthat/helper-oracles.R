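# Brute-force double-loop window power: the independent oracle for
# sliding_power().
oracle_sliding_power <- function(x, w, stride) {
  starts <- seq.int(1L, length(x) - w + 1L, by = stride)
  vapply(starts, function(s) {
    acc <- 0
    for (k in s:(s + w - 1L)) acc <- acc + x[k]^2
    acc / w
  }, numeric(1))
}

# White-noise recording helper (volts).
white_recording <- function(n, fs = 250, sd = 1, seed = 1) {
  withr::with_seed(seed, recording(rnorm(n, sd = sd), fs = fs))
}

# Recording containing a known template at given event times plus white
# noise; used for evoked-average recovery tests.
template_session <- function(event_times, duration_s, fs = 250,
                             amp = 19e-6, latency_s = 0.3, width_s = 0.2,
                             noise_sd = 20e-6, seed = 1) {
  n <- as.integer(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  v <- withr::with_seed(seed, rnorm(n, sd = noise_sd))
  tpl <- function(u) ifelse(abs(u - latency_s) <= width_s,
                            amp * (1 + cos(pi * (u - latency_s) / width_s)) / 2,
                            0)
  for (on in event_times) v <- v + tpl(tt - on)
  list(recording = recording(v, fs = fs),
       events = events(event_times, duration = duration_s),
       template = tpl)
}
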