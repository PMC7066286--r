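---
title: "Individualized phase-locked tACS for the oddball P300: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized phase-locked tACS for the oddball P300: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddlock)
```

## The problem

The P300 (P3b) is a positive event-related potential peaking roughly
300–600 ms after task-relevant stimuli, maximal at the parietal midline
electrode Pz. Viewed in the time–frequency domain it is a transient
delta/theta event-related oscillation (ERO). Transcranial alternating
current stimulation (tACS) can entrain brain oscillations at the applied
frequency — but only if the stimulation's phase and frequency match the
targeted oscillation. `oddlock` implements the full experimental pipeline
for studies that attempt exactly that: estimate each subject's P300 latency
and ERO frequency from a pre-stimulation oddball block, schedule stimulus
presentation so that the P300 peak coincides with a stimulation peak, and
quantify outcomes and group effects afterwards.

Because no patient EEG is shipped with such studies, the package's first
module is a synthetic oddball-EEG generator with the statistical structure
the analysis assumes, so every downstream stage is exercisable and testable
end to end.

## The synthetic oddball session

`sim_config()` describes a session: 400 trials by default, 25% targets,
1000 ms stimuli, ISI uniform on 1000–2000 ms (so a block averages
400 × 2.5 s ≈ 16.7 min), a 32-channel 10-10 montage at 1000 Hz.

On each target trial the generator adds, at Pz, the burst

$$s(t) = A \exp\!\left(-\frac{(t-L)^2}{2\sigma^2}\right)
  \cos\!\big(2\pi f_0 (t-L)\big),$$

whose maximum $A$ falls exactly at onset $+\,L$. Other channels receive the
burst scaled by a cosine falloff over 10-10 great-circle distance from Pz,
giving a parietal topography without a head model. Defaults: $A$ = 8 µV
(the scale of published pre-condition P300 amplitudes), $L$ = 440 ms (the
typical oddball P300 latency reported in pilot work), $f_0$ = 3 Hz
(delta/theta), envelope SD $\sigma$ = 200 ms.

Two generator choices deserve explanation:

* **Envelope width.** With $\sigma$ = 200 ms the burst's spectral
  full-width at half maximum is about 1.9 Hz, comfortably narrower than the
  delta + theta span. A much narrower envelope (e.g. $\sigma \approx$
  100 ms) would smear the burst's spectrum over more than 3 Hz, at which
  point "the frequency of the ERO" stops being meaningfully defined at the
  0.5 Hz resolution of the online analysis grid — the estimand itself
  dissolves. 200 ms corresponds to a ~470 ms-wide P300, within the
  physiological range for a slow P3b.
* **Blink model.** Blinks are a fixed ~400 ms biphasic template (two
  opposed half-Gaussians) inserted on 10% of trials within 0–1 s
  post-onset — matching the ~8.5% of EEG trials such studies reject. The
  template time course is identical on every channel (this shared waveform
  is what "uniform on all channels" means operationally; inter-channel
  correlation is the detection cue), while its amplitude decays towards
  posterior sites with a 20% floor, the typical parietal residue of an
  ocular potential. A flatter profile (say, half the frontal amplitude
  everywhere) would put ~75 µV of blink residue on Pz — physiologically
  wrong, and enough to contaminate the ERSP baseline broadband through the
  overlapping −3–0 s baselines of neighboring trials.

Background noise is pink (power ∝ 1/f), 10 µV RMS per channel: broadband
EEG is closer to 1/f than to white noise, and a 1/f baseline genuinely
stresses the ERSP normalization (see "Known biases" below). Behavior is a
truncated-normal reaction time (mean 450 ms, SD 100 ms, truncated to the
trial's response window) with configurable omission (5%) and commission
(1%) probabilities; an optional switch couples RT to the ERO latency to
emulate the P300-latency/RT relationship.

What the generator does **not** emulate: forward-modeled scalp potentials,
saccades, alpha rhythms and other structured background, non-stationary
noise, latency jitter of the P300 across trials, and the tACS artifact in
during-condition EEG. Passing tests therefore show that the pipeline's
logic and statistics behave as specified under a clean, controlled model of
the data — not that the estimators would reach the same accuracy on
clinical recordings.

## Preprocessing chains

Two named presets mirror the two analysis stages:

| preset | filters | reference | cleanup |
|---|---|---|---|
| `online` | HP 0.5 Hz, LP 20 Hz | as recorded | blink-trial rejection |
| `offline` | HP 0.5 Hz, LP 8 Hz | common average | rejection + optional ICA |

All filtering is zero-phase (forward–backward Butterworth, order 4 per
pass, reflection-padded): causal filtering would delay the P300 peak and
bias the latency that drives stimulation timing. Epochs span −3 to +4 s
around stimulus onset (7001 samples at 1 kHz, closed window) with the
−50–0 ms baseline mean removed.

A trial is rejected as blink-contaminated when its 0–1 s window exceeds
100 µV on any channel *and* the median pairwise inter-channel correlation
of that window exceeds 0.8 — the operational form of "a large deflection,
uniform on all channels". Both thresholds are configurable; the qualitative
criterion fixes neither.

The ICA step replaces manual component inspection with a reproducible
heuristic: FastICA components whose time course correlates with a frontal
ocular proxy channel (default Fp1) above 0.7 are removed — unless their
trial-averaged time course peaks within 300–600 ms post-onset, the guard
that protects P300-carrying sources. A compact symmetric FastICA (tanh
contrast, eigenvalue whitening, unmixing estimated on a 4× time-decimated
copy) is implemented inside the package. In the default study driver the
ICA step is off: with blink-trial rejection already removing contaminated
trials, it adds runtime but little accuracy on the synthetic data; set
`use_ica = TRUE` in `study_config()` to enable it.

## ERSP and parameter estimation

`wavelet_ersp()` computes a complex Morlet transform with a constant 3
cycles at every frequency (the wavelet's temporal SD is
$\sigma_t = n_{cyc}/(2\pi f)$), averages power over retained trials, and
normalizes per frequency to the −3–0 s baseline in dB:
$10\log_{10} P(f,t) / \bar P_{base}(f)$. Grids follow the two presets:
online 1.5–20 Hz in 0.5 Hz steps at 24 ms; offline 0.8–10 Hz in 0.25 Hz
steps at 14 ms. Cells closer to an epoch edge than $3\sigma_t$ are marked
invalid and excluded from maxima. A `decim` argument subsamples the time
axis before the transform; it is safe once the signal is low-pass filtered
well below the decimated Nyquist (the online chain's 20 Hz low-pass allows
`decim = 4` at 1000 Hz) and makes the 100-subject simulations tractable.

The individual protocol then falls out of three small steps:

1. **P300 latency** $L$: argmax of the average target ERP at Pz in the
   closed 300–600 ms window (the corrected estimation window; `c(0, 900)`
   reproduces the initial wide one). Ties go to the earliest sample;
   boundary maxima are flagged.
2. **Stimulation frequency** $f$: frequency of the ERSP maximum within
   ±150 ms of $L$, over the whole frequency axis. "Maximum in time of the
   per-frequency maxima" and "global window maximum" coincide for a global
   maximum; the package computes the global maximum, with ties broken
   toward earlier times, then lower frequencies.
3. **Wait duration**: the stimulation sine starts at a rising zero-crossing
   at the trigger, so peaks sit at $T/4 + kT$ ($T = 1000/f$ ms). Presenting
   the stimulus $w = (T/4 - L) \bmod T$ after a trigger puts the P300 peak
   on a stimulation peak; the shortest non-negative wait is used, which
   maximizes the trial count in the fixed 20 min block.

All phase arithmetic flows from the single convention
$\text{phase}(t) = 2\pi f (w + t)/1000 \bmod 2\pi$, which equals $\pi/2$ at
$t = L$ by construction. The *phase miss* between online and offline
parameter estimates is the circular distance of the two phases at P300
latency, in $[0, \pi]$, keeping the online wait actually delivered; the
signed difference is retained as a secondary field.

`schedule_during_block()` replays the presentation loop — stimulus, jittered
ISI, wait for the next rising zero-crossing trigger, add $w$, present —
until the 20 min stimulation block ends, so higher stimulation frequencies
fit more trials. The waveform generator produces the 1 mA peak-to-peak,
DC-free sinusoid with linear 10 s ramps, and the sham variant that fades in
for 10 s and immediately out again.

### Known biases, numerical choices

* The frequency estimator maximizes a *ratio* with a 1/f-shaped
  denominator, so its expectation sits slightly above the true burst
  frequency (about +0.2–0.4 Hz here: the 3-cycle wavelet's bandwidth grows
  with $f$ while the baseline falls with $f$). This is faithful to the
  method as practiced — the original protocol itself needed an offline
  re-estimation precisely because online estimates were imperfect — and is
  one reason the phase-miss diagnostic exists.
* Overlapping epochs (trial spacing ~2.5 s vs a 3 s baseline) put the
  previous trial's P300 into the baseline window. With realistic noise
  levels this inflates the baseline at $f_0$ by under 10% and is accepted;
  the alternative (shortening the baseline) would depart from the stated
  −3–0 s convention.
* dB (10·log10 ratio) is used for ERSP values; published ERSP magnitudes in
  this design carry no stated unit, so no attempt is made to match them
  numerically.
* Sample quantization: during-block onsets land on the 1 kHz grid, so the
  phase at P3Lat deviates from $\pi/2$ by at most $2\pi f \cdot 1\,$ms.

## Outcomes and statistics

Per subject and condition: P300 amplitude (window maximum of the average
target ERP at Pz, 300–600 ms, in µV) and its latency; reaction-time mean
and SD over valid responses (closed 200–1000 ms validity interval, sample
SD with $n-1$); omission and commission counts; and the ERSP maximum in the
±3 Hz × ±150 ms window around the delivered stimulation parameters.
Omission trials stay in the ERP averages (they only leave the RT analysis),
mirroring the dual trial bookkeeping of such studies. The during condition
is behavior-only: EEG under stimulation carries the tACS artifact and is
not analyzed.

Group inference on change scores, with two groups of nine by default:

* amplitude hypothesis: right-tailed exact rank-sum test (stim > sham) on
  the relative pre-to-post amplitude change, uncorrected;
* behavioral hypotheses: left-tailed tests on pre-to-post and pre-to-during
  change (a hypothesized decrease), two-sided on during-to-post,
  Benjamini–Hochberg-corrected within each measure's three time
  comparisons (not across measures);
* ERSP hypothesis: right-tailed test on the relative change of the
  windowed ERSP maximum.

The test reports both the rank-sum $W$ of the first sample and the
Mann–Whitney $U = W - n_1(n_1+1)/2$: published values in this literature
sometimes exceed the maximum possible $U$, indicating rank-sum reporting,
and the dual report keeps results comparable either way. Exact p-values are
used whenever $n_1 + n_2 \le 20$ without ties — two groups of nine sit
squarely in the exact regime; ties fall back to the tie-corrected normal
approximation. Commission errors are excluded from inference when no
condition exceeds 4 presses (rare false alarms carry no rankable signal;
threshold configurable). Spearman correlations (mid-ranks, two-sided) link
pre-to-post change scores across measures and to the phase miss.

Relative change is $(x_{later} - x_{pre})/x_{pre} \times 100$; error
counts, whose baselines can legitimately be zero, are compared as absolute
differences instead — the guarded division is an error, not a silent `Inf`.

## The study driver

`run_study()` wires everything together for a synthetic cohort:
per-subject ERO frequency drawn from a truncated normal matching the
observed stimulation-frequency spread (mean 3.0 Hz, SD 1.24 Hz, clipped to
2–7 Hz) and latency from N(440, 50) clipped to 350–550 ms; pre block →
online chain → protocol estimation → phase-locked during schedule
(behavior only) → post block → offline chain → outcomes → statistics. The
simulated tACS effect is an ERO amplitude multiplier on post-condition
target trials of the stim group (default 1.3) — the minimal mechanism
consistent with tACS raising oscillation amplitude in the stimulated band;
a latency-entrainment alternative can be emulated through the RT-coupling
switch. Every stage is a pure function of (inputs, config, seed); rerunning
with the same seed reproduces the output bundle byte for byte.

## Problem sizes used in the shipped checks

The package's own verification runs are sized to keep a complete check
tractable on a single CPU, as a deliberate design choice: parameter
recovery uses 100 synthetic subjects with 300-trial sessions on a
4-channel montage (Pz plus the frontal channels needed for blink
rejection) at unchanged SNR; the type-I-error simulation of the amplitude
test uses 10⁴ replicates of two groups of nine; end-to-end study runs in
the test suite use 40-trial blocks and 2–3 subjects per group. Estimation
accuracy depends on trial count and SNR, not on the montage size, so the
channel reduction does not change what is being verified.

## Limitations

The generator's P300 has no single-trial latency jitter, so ERP averages
are sharper than clinical data; the ICA heuristic is validated against the
generator's blink model only; EDF+ support covers the continuous
uniform-rate layout this pipeline writes, not the full zoo of EDF variants;
and the group-level simulations say nothing about whether tACS works in
patients — they verify the pipeline, not the physiology.
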