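---
title: "Methods: models, parameters and design choices in trapcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in trapcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcode)
```

# Overview

`trapcode` implements the analysis chain of activity-dependent tagging
(TRAP) experiments in auditory cortex: stimulus schedule construction, spike
detection from loose-patch traces, PSTH-based response metrics, d′
discriminability, pseudo-population SVM decoding, and automated counting of
labeled nuclei. This vignette documents the underlying models, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

# Stimulus protocols

Schedules tile a session with identical presentations at a fixed period of
`duration + ISI`, where ISI is always **offset-to-onset**. A partial final
period is dropped (`floor`), which reproduces the standard protocol
arithmetic: 3600 repetitions of a 100-ms tone with 900-ms ISI in one hour,
900 repetitions of a 3-s call with 1-s ISI, 1440 FRA trials (30 log-spaced
frequencies × 4 levels × 12 repetitions), and 60 call trials (20 at each of
3 attenuation levels). FRA and call orderings are a single seeded shuffle of
the full trial list — the minimal reading of "pseudo-random" that keeps the
design exactly balanced. Attenuation is stored in dB below the maximum
playback level; absolute SPL is metadata (playback hardware is out of
scope).

Syllable windows are half-open `[onset, onset + duration)` in samples, so a
boundary sample belongs to the earlier window. `flip_syllables` reverses the
waveform inside each window in place; it is an involution and permutes
samples, hence preserves energy.

# Synthetic data generator

The generator provides the *minimal* statistical structure the downstream
estimators assume, not a biophysical model:

- **Spike trains** are inhomogeneous Poisson: a constant spontaneous rate
  over the trial window plus, per syllable, an *additive* evoked rate over a
  rectangular window of `response_duration_ms` starting `latency_ms` after
  syllable onset. The per-trial latency is Gaussian with SD
  `latency_jitter_sd_ms`, truncated at zero. During a response window the
  total rate is therefore `spont + evoked`, which is what a window-rate
  estimator should recover.
- **Voltage traces** are sums of a biphasic 1-ms spike template (peak
  aligned to the spike time within one sample) on white Gaussian noise, with
  optional 1-Hz sinusoidal drift standing in for movement artifacts; the
  default sampling rate is 10 kHz, the acquisition standard for this kind of
  recording.
- **Micrographs** are 8-bit images of disc-shaped nuclei on a uniform
  background, with a linear multiplicative illumination gradient along the
  diagonal (corner-to-corner ratio `1 + g`) and per-pixel Poisson noise. A
  configurable fraction of cells is placed with centers 1.7 radii apart
  (discs overlapping by ~30% of a radius) to exercise watershed splitting.

Defaults (spontaneous 5 ± 2 sp/s, evoked 20–40 ± 8 sp/s per syllable,
latency 10 ms ± 2 ms, response 80 ms, 20 trials per stimulus, nucleus radius
6 px at intensity 160 on background 30) are chosen as round, physiologically
plausible values for anesthetized auditory cortex and 10× micrographs; no
rate numerals are printed in the source study's text, so these are
documented as illustrative, not fitted. All randomness flows from one
explicit seed per call; sub-streams are derived deterministically
(`derive_seed`), so identical seeds give identical artifacts.

What the generator does **not** emulate: bursting and refractoriness,
adaptation across trials, correlated noise between neurons, realistic
vocalization audio, irregular nucleus morphology, or 3-D image stacks.
Passing tests therefore demonstrate correctness of the *estimators and
protocol logic* under the assumed statistical model, not robustness to every
property of real recordings.

# Spike detection

Traces are high-pass filtered at 100 Hz with a 2nd-order Butterworth applied
forward and backward (zero phase, 4th-order magnitude). The trace is
reflect-padded before filtering so start-up transients fall outside the
data. Zero phase matters: spike times must not shift, and the test suite
asserts an impulse's argmax is unmoved.

Detection thresholds the polarity-corrected trace and assigns one spike per
contiguous suprathreshold segment at its extremum, rounded to the nearest
millisecond; segments separated by less than 1 ms of sub-threshold samples
are merged (a refractory floor that prevents double-counting multi-peaked
waveforms), and duplicate milliseconds after rounding collapse to one spike.
The automatic threshold is

    median(|x|) + 5 · median(|x|) / 0.6745

on the rectified filtered trace. `median(|x|)/0.6745` is the standard robust
estimate of the noise SD in extracellular work (insensitive to the spikes
themselves); the total level is ≈ 5.7 σ on Gaussian noise, giving of the
order of one false event per hour at 10 kHz while detecting 10 σ spikes with
essentially unit probability. Polarity is auto-selected as the sign whose
half-rectified trace has the larger kurtosis (spikes make one tail heavy),
which makes detection invariant to the amplifier's sign convention; both
threshold and polarity are overridable.

# Response metrics

PSTHs are spike counts in fixed 1-ms bins aligned to stimulus onset, summed
over trials; bin sums always equal the number of in-range spikes.

**Smoothing.** FWHM windows and latencies are extracted from a
Gaussian-smoothed PSTH (default kernel SD 5 ms, recorded in the output).
Raw 1-ms bins are far too noisy for half-maximum crossings at realistic
trial counts; 5 ms preserves onset-response structure while stabilizing the
crossings. Exact worked examples in the tests use SD 0 so expectations can
be derived by hand.

**FWHM convention.** On the smoothed PSTH restricted to post-onset bins, the
window runs from the first bin reaching `baseline + (peak − baseline)/2` to
just past the last such bin (half-open in ms). The baseline is the mean
pre-stimulus smoothed bin height — the natural reference when the trace has
nonzero spontaneous activity. Multi-peaked PSTHs yield a single spanning
window. A flat PSTH (peak ≤ baseline) is a no-response error, and the window
is scale-invariant by construction.

**Windows and rates.** Spontaneous rates come from the −1000 to −200 ms
window (natural calls) or the −100 to 0 ms window (tones). Evoked
per-syllable rates use 100-ms windows (`"fixed"`) or
`max(100 ms, syllable length)` (`"fig7"`); windows that would run into the
next syllable are truncated there with a warning. Per-syllable significance
is a two-sided Mann–Whitney test of per-trial window rates against per-trial
spontaneous rates at α = 0.05, using the syllable's own PSTH-segment FWHM
window where a peak exists and the plain evoked window otherwise (the
segment-level choice; whether the original analyses used per-call or
per-syllable FWHM is not determinable, so both the rule and the smoothing SD
are exposed as configuration).

**Tuning.** FRA entries are mean evoked rates per frequency × level in the
cell's response window, normalized by the cell's maximum (all-zero matrices
are flagged, not divided). BF is the frequency of the global maximum, CF the
frequency maximizing the level-averaged response, latency the smoothed-PSTH
peak time (with a baseline + 2 SD crossing as the documented alternative).
Ties resolve to the lowest frequency / earliest time — deterministic and
order-independent.

**Group statistics.** "Fisher's LSD after Kruskal–Wallis" is implemented as
its closest nonparametric analogue: pairwise two-sided rank-sum tests,
unadjusted, reported only when the omnibus Kruskal–Wallis test is
significant. This diverges from a literal (parametric) LSD but matches the
omnibus-gated, unadjusted logic.

**A note on the significance test's level.** The Mann–Whitney level
statement applies to exchangeable samples. Comparing a 100-ms window rate
against an 800-ms window rate under a *common* firing rate is not a null for
the test — the two rate estimators have very different discrete supports, so
rejection rates are far from nominal even when no response exists. The
calibration simulation in the test suite therefore draws both groups from
equal-length windows (800 ms at 5 sp/s, 60 trials per side), where the type-I
error is confirmed to sit at 0.05 within binomial error over 2000 null
syllables. In practice evoked effects are large relative to this subtlety,
but window-length asymmetry should be kept in mind when interpreting
borderline p-values.

# d′ discriminability

For one neuron and two stimuli, the evoked-rate distribution is the mean and
sample SD (n − 1) of the syllable-wise evoked rates, and

    d′ = (μ₁ − μ₂) / sqrt((σ₁² + σ₂²)/2).

Identical distributions give exactly 0 and the function is antisymmetric.
Matrix pixels average **|d′|** across neurons: the sign of d′ depends only on
the arbitrary order of the stimulus pair, so signed averaging would cancel
real discriminability. Degenerate cases (both SDs zero) give 0 when the
means agree and an undefined marker (excluded from averages, counted in the
output) otherwise. The per-neuron signed tensor is retained so that the
between-group comparison — a per-pixel two-sided Mann–Whitney test on
per-neuron |d′| — uses the raw values rather than the averaged matrix.

# Population decoder

Feature vectors are neuron × syllable spike counts in the first *k*
syllables' windows (100 ms or syllable length). Because neurons are recorded
in separate sessions, pseudo-trials are assembled by assigning each neuron's
20 real trials to the 20 pseudo-trials with an independent seeded
permutation, refreshed on every iteration. Each iteration holds out 2 of the
20 trials per class (an 18/2 split), trains a linear-kernel SVM on the 36
training rows and scores the 4 held-out rows; accuracy is the mean over
iterations (1000 by default). Features are standardized per column with
training-set statistics only, preventing count-scale dominance without
leaking test information; the SVM cost parameter defaults to C = 1. Both are
configurable since the original protocol does not specify them. Iteration
*i* derives its seed from `(base_seed, i)`, so results are exactly
reproducible.

Because every neuron's held-out real trials are disjoint from its training
trials, the expected accuracy under identical class distributions is exactly
0.5. A *single* dataset's repeated-split accuracy nevertheless varies around
0.5 with an SD of about 0.055 — all iterations resample the same 20-trial
pools, so pool-level sampling noise does not average out with more
iterations. The chance-calibration test therefore averages 1000-iteration
accuracies over 12 independently simulated null datasets, which bounds the
standard error near 0.016.

A useful subtlety for constructing positive controls: a "stronger"
population beats a matched control only when its evoked-rate *vectors* are
scaled (e.g. 2×), so that the between-stimulus signal grows faster (2×) than
the Poisson noise (√2×). Drawing two populations independently with a doubled
mean but the same between-syllable SD leaves the signal unchanged while
increasing the noise, and decodes *worse* — the package's positive-control
simulations use matched multiplicative scaling.

# Cell quantification

Sections are corrected with a grayscale white top-hat (disc structuring
element, default radius 25 px — comfortably above the ~6 px nucleus radius,
with a warning when it is not) followed by a 3 × 3 median filter. Top-hat
removes background varying on scales larger than the element, i.e. the
illumination field; under Poisson noise it cannot push the background *floor*
to zero (grayscale erosion is biased low by several noise SDs), but it
flattens corner-to-corner unevenness from tens of intensity units to a few,
which is what matters for a global threshold. Binarization keeps pixels
**strictly greater than** 50 (8-bit scale); components smaller than 20 px are
discarded; touching nuclei are split by watershed on the distance transform.

The watershed height tolerance defaults to **1 px**: for 6-px-radius nuclei
overlapping by ~30% of a radius the saddle depth of the fused distance map
is only ~2.5–2.8 px, and a tolerance of 2 px empirically merges such pairs
while 1 px splits them without over-segmenting single discs (the h-parameter
trades over- against under-segmentation and should be revisited for very
different cell sizes).

Densities pool counts and masked volumes across all of an animal's sections
before dividing (volume = masked area × nominal section thickness, 40 or
60 μm; no shrinkage correction; confocal stacks are maximum-projected before
counting). Per animal, relative density = A1 density / S1 density, and fold
induction divides by the mean relative density of the No-Stim group — whose
group mean is therefore exactly 1 by construction. Animals with zero S1
density are excluded with a warning.

# Pipeline, configuration and problem sizes

`run_pipeline()` executes simulation → metrics → exclusion → d′ → decoding →
histology from one layered configuration (R list or YAML) with a single
top-level seed; unknown keys are rejected, and a manifest (config, seed,
package version) is written beside the CSV outputs. Identical configs and
seeds give byte-identical outputs.

Default problem sizes are picked so a full desktop run takes minutes:
12 + 12 neurons × 3 calls × 20 trials, 100 decoder iterations per point, and
2 sections × 2 regions × 3 animals × 2 conditions of 256 × 256 px images.
The test suite uses the same machinery at sizes chosen per property — e.g.
200 simulated neurons for estimator-bias checks, 2000 null syllables for
test-level calibration, 12 null datasets × 1000 iterations for decoder
calibration, 10 seeds × 6 syllable counts for the population contrast — each
stated in the corresponding test.

# Known limitations

- The Poisson generator omits refractoriness and burst structure; detection
  accuracy on real loose-patch data depends on waveform stability not
  modeled here.
- FWHM windows assume a single dominant response mode per analyzed segment;
  strongly multi-peaked responses yield one spanning window by design.
- The decoder implements only the two-class, linear, repeated-split protocol
  (no multiclass, nonlinear kernels, or time-resolved decoding).
- Region masks are inputs: the package does not delineate A1/S1 boundaries,
  and counting operates on 2-D (projected) sections only.
- Mann–Whitney significance with heavily tied low counts is conservative;
  at very low spontaneous rates the per-syllable flags lose power.
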