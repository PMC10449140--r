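#' Task presets for the synthetic generator
#'
#' Maps the eight study tasks to artefact schedule densities with the
#' phenomenology each task exhibits in real recordings:
#'
#' * `jaw_clench`: a clench every 15 s -- 2 s broadband EMG bursts at 15x
#'   the background RMS (peaks near 1 mV) with a low-frequency movement
#'   transient at each onset, plus a few blinks early in the recording.
#' * `lying_ec`: eyes closed -- a waxing-waning 10 Hz alpha rhythm, no
#'   blinks, two swallows (EMG burst + small movement transient).
#' * `lying_eo`: eyes open -- regular blinks and occasional gaze shifts,
#'   light tonic EMG.
#' * `word_search`, `sudoku`, `phone_app`: moderate tonic EMG (tense
#'   muscles) with frequent small saccades and blinks.
#' * `colouring`: tonic EMG, rhythmic movement artefacts and pen-switch
#'   bursts.
#' * `reading`: dense blinks, line-scanning saccades, speech EMG bursts
#'   and page-turn movement artefacts.
#'
#' Schedule jitter is drawn deterministically from `seed`, so a preset is
#' a pure function of `(task, duration_s, fs, seed)`.
#'
#' @param task One of the eight task names (see above).
#' @param duration_s Recording length (default 120 s, the study's task
#'   duration).
#' @param fs Sampling rate (default 250 Hz).
#' @param seed RNG seed for schedule jitter, stored in the spec.
#' @return A [synthetic_spec()].
#' @export
task_preset <- function(task = task_names(), duration_s = 120, fs = 250,
                        seed = 1L) {
  task <- arg_match(task)
  base <- list(duration_s = duration_s, fs = fs, background_rms = 20e-6,
               background_slope = 1, mains_amp = 10e-6, seed = seed)
  withr::with_seed(seed + 7919L, {
    pars <- switch(task,
      jaw_clench = {
        onsets <- jitter_grid(duration_s, every = 15, jitter = 1)
        list(emg_schedule = tibble(onset_s = onsets, duration_s = 2,
                                   gain = 15),
             saccade_schedule = tibble(onset_s = onsets,
                                       step_v = alt_sign(length(onsets)) *
                                         200e-6),
             blink_schedule = sort(runif(3, 1, 10)))
      },
      lying_ec = {
        swallows <- jitter_grid(duration_s, every = 50, jitter = 8)
        list(alpha_amp = 6e-6,
             emg_schedule = tibble(onset_s = swallows, duration_s = 1.5,
                                   gain = 5),
             saccade_schedule = tibble(onset_s = swallows,
                                       step_v = alt_sign(length(swallows)) *
                                         80e-6))
      },
      lying_eo = list(
        emg_tonic = 0.5,
        blink_schedule = jitter_grid(duration_s, every = 6, jitter = 2),
        saccade_schedule = sacc_sched(duration_s, every = 8, jitter = 3,
                                      step = 60e-6)
      ),
      word_search = list(
        emg_tonic = 1,
        blink_schedule = jitter_grid(duration_s, every = 6, jitter = 2),
        saccade_schedule = sacc_sched(duration_s, every = 3, jitter = 1,
                                      step = 40e-6)
      ),
      sudoku = list(
        emg_tonic = 0.5,
        blink_schedule = jitter_grid(duration_s, every = 6, jitter = 2),
        saccade_schedule = sacc_sched(duration_s, every = 3, jitter = 1,
                                      step = 60e-6)
      ),
      phone_app = list(
        emg_tonic = 1,
        blink_schedule = jitter_grid(duration_s, every = 5, jitter = 2),
        saccade_schedule = sacc_sched(duration_s, every = 2, jitter = 0.8,
                                      step = 50e-6)
      ),
      colouring = {
        switches <- jitter_grid(duration_s, every = 15, jitter = 3)
        list(emg_tonic = 1,
             emg_schedule = tibble(onset_s = switches, duration_s = 1,
                                   gain = 3),
             blink_schedule = jitter_grid(duration_s, every = 5, jitter = 2),
             saccade_schedule = sacc_sched(duration_s, every = 8, jitter = 2,
                                           step = 150e-6))
      },
      reading = {
        turns <- jitter_grid(duration_s, every = 40, jitter = 5)
        sacc <- sacc_sched(duration_s, every = 1.5, jitter = 0.5,
                           step = 50e-6)
        sacc <- bind_rows(sacc,
                          tibble(onset_s = turns,
                                 step_v = alt_sign(length(turns)) * 250e-6))
        list(emg_tonic = 1,
             emg_schedule = tibble(
               onset_s = jitter_grid(duration_s, every = 20, jitter = 4),
               duration_s = 2, gain = 4),
             blink_schedule = jitter_grid(duration_s, every = 3, jitter = 1),
             saccade_schedule = arrange(sacc, .data$onset_s))
      }
    )
  })
  exec(synthetic_spec, !!!utils::modifyList(base, pars))
}

#' @rdname task_preset
#' @export
task_names <- function() {
  c("jaw_clench", "lying_ec", "lying_eo", "word_search", "sudoku",
    "phone_app", "colouring", "reading")
}

# evenly spaced onsets with uniform jitter, kept inside (1, duration - 3)
jitter_grid <- function(duration_s, every, jitter) {
  g <- seq(every, duration_s - 3, by = every)
  if (length(g) == 0L) return(numeric())
  g <- g + runif(length(g), -jitter, jitter)
  sort(pmin(pmax(g, 1), duration_s - 3))
}

sacc_sched <- function(duration_s, every, jitter, step) {
  on <- jitter_grid(duration_s, every, jitter)
  tibble(onset_s = on, step_v = alt_sign(length(on)) * step)
}

# alternate signs so EOG steps do not accumulate into a drift
alt_sign <- function(n) rep_len(c(1, -1), n)
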