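# bciwall

Can a consciously generated EEG change be detected *at all* in a
single-channel scalp recording, given that the recording is contaminated
by **non-stationary** noise — facial-muscle (EMG) bursts, eye blinks,
saccades, movement artefacts? `bciwall` answers that question with a hard,
measurable criterion for BCI researchers and experiment designers: it
computes a recording's **SNR-wall** and its **SNR** and compares them.

## The criterion

With stationary noise, an energy detector (compare the mean-square
`T(x) = (1/N) Σ x[n]²` of `N` samples against a threshold γ) can reach any
target false-alarm probability `P_FA` and detection probability `P_D` by
averaging longer:

```
N = 2 [Q⁻¹(P_FA) − Q⁻¹(P_D)(1 + SNR)]² / SNR²
```

With non-stationary noise, the noise standard deviation wanders between a
smallest and a largest value. Their ratio, measured with a 2 s sliding
window over the whole recording,

```
ρ = sqrt(σ²_r,max / σ²_r,min)  ≥ 1,
```

sets a floor below which the required averaging length diverges:

```
N = 2 [Q⁻¹(P_FA) − Q⁻¹(P_D)]² / [SNR − (ρ − 1/ρ)]²   →  ∞
SNR_wall = 10 log10(ρ − 1/ρ)  dB
```

The recording's SNR is `10 log10(T(c)/σ²_r)`, where the conscious signal
power `T(c)` is estimated from the P300 evoked potential (`T_t(c) =
c²_max`, or the fraction of band power a subject can consciously
desynchronise for frequency-domain BCIs) and `σ²_r` is the whole-recording
mean-square power. Conscious EEG changes are detectable **iff
SNR > SNR_wall**.

The package implements the full pipeline: plain-text recording/event I/O,
the five causal pre-filter chains used in BCI practice (0.1 Hz highpass,
0.1–3 Hz, 8–18 Hz, 8–12 Hz, first difference; each + mains bandstop), the
sliding-window wall estimator, P300 averaging, the energy-detector theory
with a Monte-Carlo verifier, a seeded synthetic-EEG generator with eight
task presets (jaw clench … lying down with eyes closed), and group-level
paired t-tests with a star table of detectable task × filter cells.

## Worked example

```r
library(bciwall)

# synthetic 2-minute jaw-clench recording + 5-minute oddball session
gen  <- generate_recording(task_preset("jaw_clench", seed = 1))
sess <- generate_oddball_session(
  oddball_spec(synthetic_spec(duration_s = 300, seed = 1)))

# conscious amplitude from the P300 average
evk <- evoked_average(apply_chain(sess$recording, "fullband"), sess$events)
evk
#> <bci_evoked> 30 events (0 dropped): c_max = 16.3 uV at 200 ms

# minimal filtering: the wall towers over the SNR
cfg  <- analysis_config(filter_setup = "fullband")
filt <- apply_chain(gen$recording, cfg$filter_setup)
prof <- profile_recording(filt, cfg)
snr  <- estimate_snr(filt, c_max = evk$c_max, config = cfg)
c(wall = prof$snr_wall_db, snr = snr$snr_db)
#>      wall       snr
#>  12.45293 -15.97560
detectable(snr$snr_db, prof$snr_wall_db)
#> [1] FALSE

# narrow 8-12 Hz filtering rejects the EMG bursts: detection possible
cfg  <- analysis_config(filter_setup = "alpha", snr_mode = "frequency")
filt <- apply_chain(gen$recording, cfg$filter_setup)
prof <- profile_recording(filt, cfg)
snr  <- estimate_snr(filt, c_max = evk$c_max, config = cfg)
c(wall = prof$snr_wall_db, snr = snr$snr_db)
#>     wall      snr
#> 5.519864 6.234218
detectable(snr$snr_db, prof$snr_wall_db)
#> [1] TRUE
```

Reading the numbers: fullband, the jaw-clench bursts drive the
window-power ratio to ρ ≈ 18, a wall of ≈ 12 dB that the ≈ −16 dB SNR
cannot clear — no averaging length will make detection reliable. Filtering
to the 8–12 Hz alpha band suppresses the >20 Hz EMG, the wall drops to
≈ 5.5 dB and the SNR (a 40% conscious band-power reduction of the P300
power) rises just above it. Group-level versions of this comparison
(`group_test()`, `detectability_table()`) star the task × filter cells
where the SNR is significantly above the wall across subjects.

A thin CLI covering the same operations ships in `inst/exec/bciwall`
(subcommands `wall`, `snr`, `decide`, `simulate`, `theory`, `groupstats`).

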