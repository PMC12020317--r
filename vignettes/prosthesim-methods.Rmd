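---
title: "Methods: simulating and analyzing bidirectional neuroprosthesis data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing bidirectional neuroprosthesis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosthesim)
```

## Scope

`prosthesim` implements the analysis pipeline of an implanted bidirectional
sensorimotor interface — intramuscular EMG sensing for myoelectric control
plus peripheral nerve stimulation for somatosensory feedback — as a tested,
reusable package. Because no subject data are deposited for systems of this
kind, the package pairs every analysis stage with a synthetic-data generator
whose ground truth the stage must recover. A green test therefore
establishes that the *rules* of the pipeline are implemented correctly and
are mutually consistent, not that any clinical claim holds.

## The synthetic EMG model

`generate_emg()` produces interference EMG at the "filtered stochastic"
level: each channel is band-limited (15–350 Hz) Gaussian noise,
amplitude-modulated by a posture envelope with 200 ms raised-cosine
rise/fall ramps, plus an independent band-limited baseline noise floor.
Rest blocks of 2 s separate postures so that baseline statistics are
estimable from labeled rest. Because activation and baseline components are
independent, the RMS during posture $p$ on channel $c$ approaches
$\sqrt{A_{cp}^2 + \sigma_0^2}$, which the tests verify empirically.

Deliberately *not* modeled: motor-unit recruitment and firing statistics,
volume conduction, electrode geometry, and amplitude non-stationarity
within a posture. These do not affect the downstream rules (windowed
features, variance/peak/MAV criteria, spectral ratios), which is all the
generator exists to exercise. Default amplitudes (50 µV activation RMS,
1–5 µV baseline) are plausible for bipolar intramuscular recordings but are
not fitted to any participant; no published amplitude distributions exist
for this system.

Stimulation artifacts are injected as a sum of sinusoids at the stimulation
frequency and its harmonics rather than as a pulse train. This choice makes
the per-harmonic spectral power an explicit dial, which is exactly what the
artifact statistics measure; a pulse train would couple all harmonic
amplitudes through its shape. Broadband contamination is a multiplicative
power gain. Both are idealizations of the narrowband/broadband dichotomy
the categorization rules encode.

## Features and channel quality

Waveform length (WFL) is the sum of absolute sample-to-sample changes
within a window divided by the *number of samples* in the window, and MAV
is the windowed mean of the rectified signal. The per-sample (not
per-second) denominator keeps both features in µV, which is what the
published decision thresholds (0.02 variance, 17 µV MAV) imply. Windows
are half-open, advance by the step, and trailing partial windows are
dropped — streaming semantics, no padding.

The bandpass is a 4th-order Butterworth highpass at 15 Hz cascaded with a
4th-order lowpass at 350 Hz, each applied forward–backward (zero phase) so
posture labels stay aligned. Only the band is published; the
order/family/phase choices are ours, and with band edges a factor of 23
apart the cascade is indistinguishable from a direct bandpass design at the
tested tolerances. No DSP package ships in this toolchain, so the design
(prototype poles, prewarping, bilinear transform) is implemented here and
validated against the attenuation contract (≥ 20 dB one octave outside the
band, < 1 dB ripple in band).

A channel is *noise-only* when all three published criteria hold: WFL
variance below 0.02, at most three WFL peaks exceeding 3× baseline, and at
least 90% of MAV windows below 17 µV. Three choices the source does not
pin down:

* **Units of the 0.02 threshold.** Printed as µV, but the variance of a µV
  quantity is in µV²; we apply it to the variance in µV².
* **Baseline noise level**: the median WFL over rest-labeled windows —
  robust to stray bursts during rest.
* **What a "peak" is**: a threshold excursion; excursions closer than 3
  windows merge into one so a single burst is never double-counted.

Crosstalk is the zero-lag Pearson correlation of two channels' WFL series
over the entire signal. The source does not state whether raw EMG or
features were correlated; the feature-domain reading matches the magnitudes
it discusses (most pairs below 0.10, problem pairs above 0.4) and is the
quantity that matters for a WFL-driven controller. Zero-variance channels
get correlation 0 with a warning rather than NaN.

## Artifact spectral statistics

Spectrograms use 500 ms windows (published) with Hann tapers at 50%
overlap (our choice), giving 2 Hz resolution so a 70 Hz stimulation tone
falls exactly on a bin. The PSD scaling is one-sided and
Parseval-consistent, which the tests check to 1%.

The ratio-of-frequency-power-increased at frequency $f$ is

$$\phi_f = \frac{\mathrm{med}_t P_\text{stim}(f) - \mathrm{med}_{t,f'} P_\text{stim}(f')}
                {\mathrm{med}_t P_\text{nostim}(f) - \mathrm{med}_{t,f'} P_\text{nostim}(f')}$$

with $f'$ ranging over the neighbor bands $[f-10, f-5] \cup [f+5, f+10]$ Hz
(the published 60–65/75–80 Hz at $f = 70$, generalized so one rule covers
all harmonics). Two numerical choices: the neighbor median pools frames and
bins, and the denominator is floored at the no-stimulation neighbor-band
level, so the ratio stays finite and conservative when the no-stimulation
excess is ≈ 0 — which is the typical case, since without an artifact there
is nothing special about the bin at $f$. A nonpositive stimulation excess
reports $\phi_f = 0$ (unambiguously "no artifact"). $\phi_\text{overall}$
is the pooled median power ratio over 10–500 Hz excluding ±5 Hz around the
stimulation frequency and each harmonic (70–490 Hz).

Categorization applies the published threshold of 15 with the precedence:
unresponsive → increased overall power (any trial) → consistent artifact
(every trial) → intermittent artifact (some trial) → unaffected.
"High WFL variance during attempted movements" is operationalized as *not*
noise-only, reusing the package's own responsiveness criteria.

## Psychophysics and electrode health

Charge per phase is $Q = I \, t$ (mA × µs = nC). The Shannon safety
criterion $\log_{10}(Q/A) = k - \log_{10} Q$ solves to
$Q = 10^{(k + \log_{10} A)/2}$ µC; with $k = 1.1$ and a 0.5 mm² contact
this is the 250 nC limit used as the search ceiling.

`measure_threshold()` reproduces the two-phase protocol: ramp amplitude in
0.01 mA steps at a fixed 250 µs width until detection (censoring at the
safety limit), then binary-search the width until the bracket is within
10 µs. The ramp starts at zero (the source does not say; starting at a
floor could only skip sub-floor thresholds) and the width search runs on
[10, 250] µs — the lower bound is the package's choice, bounded by the
published 10 µs resolution. For a deterministic observer the recovered
charge is guaranteed to lie in
$[\text{latent},\ \text{latent} + \Delta I \cdot t + I \cdot \Delta t]$,
which the tests assert over 1,000 random latent thresholds. Censored
measurements are excluded from trend regressions (handling unstated in the
source; exclusion is conservative).

Tissue resistance is Ohm's law per probe pulse (0.2 mA, 70 µs, 1000 Hz)
averaged over eight trials; any single trial above 15 kΩ flags the contact
as a loose connection and excludes it. Percept stability is the mean
Jaccard similarity over all session pairs, excluding proprioception-only
reports; "on the hand" means any drawn pixel distal to the template's
wrist line, so split percepts still count. The descriptor→category lexicon
ships as an editable TSV (`extdata/descriptor_categories.tsv`) because the
full published lexicon lives in supplementary material; unknown terms
default to tactile with a warning.

## Trend statistics

Linear trends are OLS with an F-test against the intercept-only model
(identical to the slope t-test for simple regression — property-tested);
logistic trends are binomial GLMs with a likelihood-ratio χ² against the
constant model. Complete separation is detected and handled by a
Haldane–Anscombe 0.5 continuity-corrected refit, flagged in the result (no
Firth-penalty package ships in this toolchain). The published pairing of
Kruskal–Wallis with "Tukey's multiple comparison adjustment" is
nonstandard; we implement the Nemenyi form — studentized-range test on
mean ranks — as the closest rank-based Tukey analogue, and the choice is
isolated behind `group_compare()` so it can be swapped. Degenerate inputs
are defined rather than errored: constant responses give $F = 0, p = 1$;
all-zero paired differences give $p = 1$.

Monte-Carlo calibration (2,000 null replicates per test, fixed seeds)
checks that all three tests reject at 5% ± 1.5% at $\alpha = 0.05$; the
signed-rank simulation uses $n = 10$ pairs, where the exact test's
attainable size is 4.9%.

## Controller

Training targets are effort vectors $e(t) = d \cdot \overline{\mathrm{WFL}}(t)$:
the posture's direction vector in $\{-1,0,+1\}^3$ scaled by the mean WFL
across channels. The 18 postures are all single and paired DOF
combinations. Of 10 repetitions per posture, the 3 least similar (Pearson
correlation of the per-channel mean-WFL pattern against the median
pattern) are excluded, the 4 most similar train, and the remaining 3
validate — the 4-vs-3 split by similarity rank is our reading of an
unspecified detail, and ties exclude the lowest repetition indices.

The network is the published architecture (14 tanh hidden units, 3 linear
outputs) with choices the source leaves open documented as configuration:
per-channel input standardization, target scaling to unit magnitude, MSE
loss, full-batch Adam, early stopping on a validation-RMSE plateau
(patience 10 evaluations at 25-iteration spacing), best-weights restore,
seeded initialization for bitwise reproducibility. No neural-network
package ships in this toolchain, so the ~60-line network is implemented
here.

Decoding applies a per-direction deadband and gain:
$v = \mathrm{sign}(r)\, g\, (|r| - \theta)$ for $|r| > \theta$, else 0.
Subtracting the threshold keeps velocity continuous at the deadband edge.
Thresholds are auto-calibrated so an all-zero (rest) input decodes to zero
velocity; gains so a 95th-percentile training effort drives about one
joint range per second. Both remain user-configurable, as they were for
the participant.

## Virtual environment

Trials integrate decoded velocities in 50 ms steps (the feature update
rate) with angles clipped to the normalized range $[-1, 1]$. Success
requires every DOF error ≤ 15% of range continuously for 1 s within the
30 s limit; time-to-target is the time at the end of the dwell.
Stimulation feedback is a three-level step — 0 Hz outside 22.5%, 50 Hz
inside 22.5%, 100 Hz inside 15% — reading the published "increased from 0
to 50 Hz … and from 50 to 100 Hz" as discrete levels rather than a
continuous ramp; the mapping is one small function if a ramp is preferred.
Random targets are uniform in $[-0.8, 0.8]$ per DOF so the success band
never leaves the joint range. Path efficiency is start-to-end displacement
over distance traveled in joint-angle space, ≤ 1 by the triangle
inequality.

The closed-loop tests use a scripted "user" that encodes an intent
proportional to the remaining error through the same channel map the
controller was trained on. This validates the control loop's internal
consistency; it says nothing about a human learner, visual feedback, or
attention — the factors that dominate real performance differences between
feedback conditions.

## Known limitations

* The EMG generator's spectral shape is flat within the passband;
  real interference EMG has a mid-band power concentration.
* The detection observer is stationary; real thresholds drift within and
  across sessions beyond the linear trends modeled here.
* Percept drawings are square masks; Jaccard behavior under realistic
  free-form drawings is exercised only through translation and area
  jitter.
* Wilcoxon/Kruskal–Wallis p-values use the normal/χ² approximations when
  ties are present, as base R does.
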