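---
title: "SNR-walls: deciding whether conscious EEG changes are detectable at all"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNR-walls: deciding whether conscious EEG changes are detectable at all}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bciwall)
```

## The problem

A brain--computer interface (BCI) must decide, in real time, whether a
consciously generated EEG change is present in a single scalp channel. The
channel also carries facial-muscle (EMG) activity, eye blinks, saccades,
movement artefacts and mains interference, and -- crucially -- the *power*
of that noise fluctuates over time: a jaw clench raises the signal from
~20 uV to nearly 1 mV for a couple of seconds and then subsides.

Classical energy detection says that with *stationary* noise any positive
SNR becomes detectable if one averages long enough. With non-stationary
noise this is false. If the noise standard deviation wanders between a
smallest and a largest value, their ratio

$$\rho = \sqrt{\sigma^2_{r,\max} / \sigma^2_{r,\min}} \ge 1$$

defines a hard floor, the **SNR-wall**,

$$\mathrm{SNR}_{\mathrm{wall}} = 10\log_{10}(\rho - 1/\rho)\ \mathrm{dB},$$

below which the number of samples needed to reach any fixed false-alarm and
detection probabilities diverges: an ambiguous power excursion can always
be either noise at its loud extreme or signal on top of noise at its quiet
extreme. A conscious EEG change is detectable if and only if

$$\mathrm{SNR} > \mathrm{SNR}_{\mathrm{wall}}.$$

This package computes both sides of that inequality for any single-channel
recording and verifies the detection theory behind it by Monte Carlo.

## The model and its assumptions

The electrode signal is modelled as `d[n] = (a[n] + b[n] + c[n]) * f[n]`:
artefacts `a`, background EEG `b` (together the noise `r = a + b`), the
consciously controlled component `c`, all passed through a causal
pre-filter chain `f`. The detector is the mean-square energy statistic
`T(x) = (1/N) sum x[n]^2` compared against a threshold. Asymptotic
(Gaussian) expressions for the false-alarm and detection probabilities,
and the resulting sample-complexity formulas with and without noise
uncertainty, are implemented in `p_false_alarm()`, `p_detection()`,
`samples_required_stationary()` and `samples_required_uncertain()`.
Assumptions worth stating:

* Real-valued Gaussian samples, so `Var[T] = 2 sigma^4 / N`. The
  complex-baseband variant used in telecommunications (`sigma^4/N`) is out
  of scope.
* The closed forms are central-limit asymptotics. The exact law of `N
  T/sigma^2` is (noncentral) chi-square; at small `N` the Gaussian tail is
  off by up to a few percent, which is why the Monte-Carlo verification
  tests run in the low-SNR / large-`N` regime where the methodology
  actually operates. `simulate_energy_detector()` offers both a literal
  per-sample Gaussian simulation and an exact chi-square sampler of the
  same statistic (`method = "chisq"`) for large `N`.
* The low-SNR simplification `SNR + 1 ~ 1` is inherited by the
  uncertain-noise sample count as printed in the underlying theory; no
  attempt is made to "improve" that formula.

## Measuring the two sides of the inequality

**SNR-wall.** `sliding_power()` scans the filtered recording with a
`window_s = 2` s window, by default sample by sample (`stride = 1`; a
larger stride is available for long recordings and changes `rho` by well
under a percent for strides up to fs/10 on ordinary recordings --
recordings whose power landscape has very steep ramps, such as strong
isolated EMG bursts, show up to ~3% quantisation at fs/10). The extrema of
the scan give `rho` and the wall. `T` is mean-square power *without* mean
subtraction; every chain removes DC, so the mean is ~0 anyway. The first
`discard_startup_s = 2` s are excluded from every power computation: a
causal IIR chain's startup transient would otherwise masquerade as
`sigma2_max` and inflate the wall.

**SNR.** The conscious signal power cannot be measured directly (one
cannot ethically paralyse a subject), so it is estimated from the P300
oddball response: `evoked_average()` forms the stimulus-locked mean,
baseline-corrects each epoch over the pre-stimulus interval, and takes the
signed positive peak `c_max` in a 150--500 ms search window (epoch
-200..600 ms; these bounds bracket canonical P300 latency and are
config-overridable). Whether epochs should be baseline-corrected before
averaging is a genuinely open choice; this package corrects, and flags the
choice in its reports. Time-domain BCIs use `T_t(c) = c_max^2`
(`conscious_power_time()`). Frequency-domain BCIs consciously *reduce* a
narrow band's power ("desynchronisation") by a fraction, default 40%, and
only the reduction is signal. Two conventions circulate for applying it:
`power_scaled` (`T_f = 0.6 T_t`) and `amplitude_scaled`
(`T_f = (0.6 c_max)^2 = 0.36 T_t`). Both appear in practice -- even within
single write-ups -- so both are implemented behind
`freq_power_convention`, defaulting to `power_scaled`; results carry the
convention used. The noise power is the whole-recording mean square
(`nominal_noise_power()`), computed directly rather than via
`rho * sigma2_min`; both routes are reported by `profile_recording()` and
the direct route is the default because it does not compound the sampling
error of the extrema.

## The five pre-filter chains

`design_chain()` builds, at any sampling rate: `fullband` (0.1 Hz 4th-order
Butterworth highpass), `delta` (0.1--3 Hz bandpass), `wide` (8--18 Hz),
`alpha` (8--12 Hz), and `derivative` (plain first difference, not scaled by
fs), each followed by a mains bandstop. All filtering is a single causal
pass -- realtime BCI cannot look ahead -- so no zero-phase
forward-backward filtering is offered. Two details were open and decided
here: the mains stop is a 4th-order Butterworth bandstop of +/-2 Hz
half-width (narrow enough to spare the 20--45 Hz EMG-diagnostic band), and
the DC-removal of the band-limited setups is supplied by the bandpass
itself (0 Hz lies in its stopband), with no extra stage. The stop-band
implementation choice is recorded in the chain object so results are
auditable.

## What the synthetic generator emulates

Real recordings from the eight study tasks are emulated by
`synthetic_spec()` / `task_preset()`:

* background EEG: 1/f-shaped Gaussian noise at 20 uV RMS (levels seen at a
  central electrode), with an optional waxing-waning 10 Hz alpha rhythm
  for eyes-closed rest;
* EMG: white noise high-passed at 20 Hz -- burst spectra in real data are
  flat or elevated above ~20 Hz -- with raised-cosine on/off ramps.
  The jaw-clench preset fires a 2 s, 15x-background burst every ~15 s,
  peaking near 1 mV;
* EOG: biphasic ~400 ms blink pulses (150 uV) and raised-cosine-smoothed
  saccade/movement potential steps. These amplitudes are
  order-of-magnitude choices (the tasks constrain densities, not
  voltages) and are configuration, not constants;
* mains at 10 uV.

Each clench onset also injects a low-frequency movement transient: a
purely >20 Hz EMG model cannot reproduce the large delta-band variance
excursions that jaw clenches cause in practice (head and electrode-lead
movement), and those excursions are what drives the delta-band wall up.
Schedule jitter is drawn deterministically from the seed, components are
returned separately (the recording is exactly their sum), and the
programmed quiet/loud standard-deviation ratio is exposed for recovery
tests. What the generator does *not* emulate: EEG topography (one channel
only), physiologically detailed neural dynamics, heteroscedastic
electrode drift, or real P300 latency/shape variability -- so passing
tests demonstrate the pipeline's statistical behaviour under controlled
non-stationarity, not clinical validity on any particular dataset.

Oddball sessions (`generate_oddball_session()`) draw inter-stimulus
intervals uniformly from 7--13 s and add a positive raised-cosine P300
template (default 19 uV peak, 300 ms latency, 200 ms half-width; the
morphology is a qualitative stand-in -- only amplitude and latency
recovery are asserted, never shape).

## Group-level testing

For every task x filter cell, each subject contributes a matched
(SNR, wall) pair; `task_test()` runs a one-sided **paired** t-test on the
differences (H1: mean SNR - wall > 0). Whether the original analysis was
paired or two-sample, one- or two-sided, is not specified anywhere;
pairing within subject is the natural choice for matched pairs and the
directional hypothesis follows from the question asked. The
independent-samples variant sits behind `paired = FALSE`, and the choice
is recorded in the result. Per-cell decisions are made at plain
`p < alpha` with no multiple-testing correction (matching per-cell
reporting conventions); a Holm-adjusted column is emitted alongside for
transparency. Infinite walls (`rho = 1`) are excluded with a count rather
than propagated.

## Numerical choices and degenerate inputs

* Sliding powers are computed from a cumulative sum of squares (exact to
  ~1e-12 relative against a brute-force double loop; negative roundoff is
  clamped at zero).
* A flatline window (`sigma2_min = 0`) is a hard error: `rho` would be
  infinite and the recording is unusable, not "very noisy".
* `rho = 1` yields a wall of `-Inf` dB (any positive SNR detectable);
  `detectable()` is a strict inequality, so equality with the wall is
  "not detectable" -- the required averaging length is already infinite
  there.
* `samples_required_uncertain()` returns `Inf` as a value, never an
  exception, and reports both the raw and ceiling-rounded counts.
* Recordings are held in volts; microvolt inputs are converted once at the
  reading boundary. Both SNR and wall are pure power ratios, so a global
  gain change (e.g. an amplifier recalibration) leaves them untouched --
  this invariance is tested end to end.

## Problem sizes used in the test-suite simulations

The packaged simulations mirror the study protocol at sizes chosen for
statistical resolution: 120 s task recordings and 300 s oddball sessions
at 250 Hz (the sampling rate is never assumed silently; 250 Hz is typical
for the portable amplifier class involved and is explicit everywhere), 6
synthetic subjects per task for the qualitative filter-band pattern, 300
stimulus repetitions for amplitude-recovery checks, 1e5 Monte-Carlo trials
per operating point for the detector-rate comparisons (on a 3x3 grid with
N between 4e4 and 1.6e5, where the Gaussian asymptotics are accurate to
well inside binomial error), and 2000 replicates for the type-I-error
check of the group test.

## A worked example

```{r example, eval = FALSE}
library(bciwall)

# a synthetic jaw-clench recording and an oddball session
gen <- generate_recording(task_preset("jaw_clench", seed = 7))
sess <- generate_oddball_session(
  oddball_spec(synthetic_spec(duration_s = 300, seed = 7)))

# conscious amplitude from the P300 average (fullband-filtered session)
evk <- evoked_average(apply_chain(sess$recording, "fullband"), sess$events)

# wall and SNR of the fullband-filtered task recording
cfg <- analysis_config(filter_setup = "fullband")
filt <- apply_chain(gen$recording, cfg$filter_setup)
prof <- profile_recording(filt, cfg)
snr <- estimate_snr(filt, c_max = evk$c_max, config = cfg)

detectable(snr$snr_db, prof$snr_wall_db)
```

## Known limitations

* Single channel only: no montages, no ICA-based separation (a
  multi-electrode alternative for estimating both SNR and wall).
* The P300 proxy assumes the oddball response power is representative of
  the conscious power available to the BCI task at hand.
* The energy-detector theory assumes Gaussian noise; EMG bursts are
  heavy-tailed in practice, which the wall formalism absorbs into the
  variance extrema but the error-probability formulas do not model.
* The generator's artefact amplitudes are plausible orders of magnitude,
  not fitted to any dataset; conclusions about a *specific* recording
  setup require running the pipeline on its own data (plain-text sample
  tables are read directly).
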