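---
title: "Spatiotemporal beamformer decoding of visual brain responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal beamformer decoding of visual brain responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmbci)
```

## The problem

Visual brain-computer interfaces decode which on-screen target a user is
looking at from their brain activity. Two classic paradigms are covered
here, both recorded either with on-scalp magnetometers (OPM-MEG, signals in
fT) or scalp EEG (uV):

* **Motion-onset evoked responses.** Nine crosses expand and contract one
  at a time; only the gazed cross elicits a stereotyped evoked deflection —
  a sharp occipito-parietal component near 190 ms (N200 electrically, M200
  magnetically) followed by a broader centro-parietal component near
  350 ms (P/M300). Detecting which cross's expansions carry the component
  identifies the gazed cross.
* **Steady-state visual evoked potentials (SSVEP).** All nine targets
  flicker simultaneously, each with a unique combination of frequency and
  phase; the visual cortex entrains to the gazed flicker, and the response
  carries both its frequency and its phase. Because all targets stimulate
  at once, selections are fast — the basis of the mind-speller.

Because raw recordings of this kind are not generally available, the
package carries a first-class synthetic-session generator so every stage of
the pipeline — preprocessing, evoked statistics, spectral features, the
decoder, channel selection, the spelling loop — is exercised end to end on
controlled, seeded data.

## The decoder

The core model is a *spatiotemporal linearly-constrained minimum-variance
(LCMV) beamformer*. Let $a \in \mathbb{R}^{1 \times mn}$ be the vectorized
activation pattern of interest over $m$ channels and $n$ samples
(channel-major: channel 1's $n$ samples, then channel 2's, ...), and let
$\Sigma \in \mathbb{R}^{mn \times mn}$ be the covariance of vectorized data
segments, shrunk towards the identity with regularization constant
$\alpha = 0.95$:

$$\hat\Sigma = \alpha \Sigma + (1 - \alpha) I.$$

The beamformer weights are

$$w = \frac{a \hat\Sigma^{-1}}{a \hat\Sigma^{-1} a^\top},$$

with $\hat\Sigma^{-1}$ a symmetric pseudo-inverse (eigenvalues below
$10^{-10}$ of the largest are discarded). $w$ is the unique linear filter
with unit gain on the pattern ($a w^\top = 1$) and minimal output variance,
so it passes the pattern while suppressing everything correlated that is
not the pattern. Applied to new data $x$, the score $w x^\top$ estimates
how strongly the pattern is present. The test suite checks this solution
against an independent brute-force constrained minimizer (BFGS over the
null space of the constraint) on small random problems.

Both paradigms use the same machinery with different patterns:

* **ERP paradigm** (one beamformer). The pattern is the vectorized average
  *target* epoch (stimulated cross = cued cross) over the full epoch; the
  covariance uses all vectorized training epochs. At prediction time the
  epochs of a trial are averaged per candidate cross (`k_reps` repetitions
  each), scored, and the cross with maximal output wins.
* **SSVEP paradigm** (nine beamformers). For target $i$ with flicker
  frequency $f_i$, training epochs cued to $i$ are cut into 50%-overlapping
  segments two periods of $f_i$ long ($n_i = \mathrm{round}(2 f_s / f_i)$
  samples); the pattern is the average segment. The covariance for target
  $i$ uses segments of the same length from *all* epochs, including other
  targets — those are exactly the structured interference the beamformer
  must suppress. A new epoch is scored by all nine beamformers (each with
  its own segmentation) and the maximal output wins, ties to the lowest
  target id.

### Segment alignment

With 50% overlap, segment starts advance by one stimulus period. At a
150 Hz processing rate a 9 Hz period is 16.67 samples: rounding the *step*
to 16 samples and accumulating (start $= 16k$) drifts the segment grid by a
third of a sample per segment, which wraps several times across a 4-s epoch
and scrambles the phase information that separates targets sharing a
frequency. The package therefore rounds each start against the exact
fractional grid, $\mathrm{start}_k = \mathrm{round}(k \cdot 2 (f_s/f)(1 -
\mathrm{overlap}))$, bounding the phase error at half a sample with no
accumulation. In simulation this is the difference between fourfold CV
accuracy capped around 86% (errors confined to the 9 Hz triplet even at
very high SNR) and 100%.

### Real-time rules

During simulated online spelling, epochs are 2 s long and the segments
starting before 150 ms are discarded to skip the entrainment transient. In
the post hoc stimulation-length sweep (truncations from 0.25 s to 2 s),
very short truncations can leave no segment that satisfies the discard
rule; in that case the discard is waived for that epoch, and a target whose
two-period window does not fit in the truncation at all scores $-\infty$
(it cannot be detected). At 0.25 s and the default 8–10 Hz layout this
makes some targets undetectable, so sweep accuracy at the shortest lengths
is expected to be poor and to rise with length.

## Preprocessing

All steps are deterministic, with 0-based sample indexing and half-open
windows $[\mathrm{start}, \mathrm{end})$:

* **Band-pass filtering**: 4th-order Butterworth applied forward and
  backward (zero phase; the net magnitude is the squared single-pass
  response), with odd-reflection padding. Evoked analysis uses 0.5–15 Hz,
  steady-state analysis 4–40 Hz.
* **Epoching**: −200..600 ms around each stimulation (ERP) or 0..4 s per
  trial (SSVEP); events whose window exceeds the recording are skipped and
  counted.
* **Baselining**: per epoch and channel, the mean over the 200 ms
  pre-onset window is subtracted.
* **Downsampling** to 150 Hz by a windowed-sinc polyphase resampler whose
  polyphase branches are normalized to unit DC gain (passband amplitude
  error below 0.1%, DC exact). Output length is
  $\lfloor n \cdot f_\mathrm{new} / f_s \rfloor$.
* **Planar gradiometers**: differences of magnetometer pairs. A tangential
  neural dipole reverses polarity across neighbouring on-scalp sensors, so
  differencing adds signal coherently while averaging independent noise —
  an amplitude-SNR gain of about $\sqrt2$ for an ideal antiphase pair.
  `pairs = "all"` forms all $k(k-1)/2$ pairs.
* **Re-referencing** (EEG only): the mastoid average is subtracted from
  every EEG channel; magnetometers are reference-free and pass through.

## Response statistics

* **Evoked averages** split epochs into target (stimulated = cued) and
  non-target conditions; pointwise 95% confidence bands use the
  bias-corrected and accelerated (BCa) bootstrap over epochs, 1000
  resamples. Peak amplitude and latency of a component are the extreme of
  the evoked mean across channels inside a search window (defaults
  150–250 ms for the N/M200, 280–450 ms for the P/M300), with BCa intervals
  by resampling epochs and re-running the search.
* **Component SNR** is reported in dB as $10\log_{10}(P_w / P_b)$, where
  $P_w$ is the mean squared amplitude of the evoked mean in a 100-ms window
  centred on the component peak and $P_b$ the same quantity in the 200-ms
  pre-onset baseline. Its confidence interval uses the *percentile*
  bootstrap (the BCa/percentile split follows the respective analyses).
  Note that the bootstrap distribution of this statistic is biased downward
  relative to the point estimate (resampling doubles the variance of the
  noise-of-the-mean that dominates $P_b$), so the percentile interval is a
  variability summary rather than an exactly calibrated interval; the
  tests therefore check point-estimate recovery.
* **Spectral SSVEP SNR** of an epoch is the amplitude of the DFT bin at
  the gazed frequency divided by the mean amplitude of the six bins on
  each side (target bin excluded; DC and Nyquist never used). Frequencies
  must lie exactly on a bin — a 4-s epoch has 0.25 Hz resolution, so
  integer frequencies always do; off-bin requests are an explicit error,
  never silently interpolated. Amplitude spectra use the $|X|/N$
  normalization; any consistent choice cancels in the ratio.
* **Phase** is the argument of the DFT coefficient at the gazed frequency,
  cosine-referenced at epoch onset and mapped to $(-\pi, \pi]$; dispersion
  across epochs is the circular standard deviation
  $\sqrt{-2 \ln \bar R}$, with $\bar R$ the mean resultant length.

## The synthetic generator

`generate_erp_session()` and `generate_ssvep_session()` emulate the two
recording types on a configurable sensor layout (default: a 3x3
parieto-occipital magnetometer grid):

* **Schedules** are block-design pseudorandom: every block of nine
  presentations is a permutation of the nine conditions. Defaults are the
  study conditions — 45 ERP trials with each cross stimulated 5 times per
  trial (150-ms expansions, inter-stimulus interval 150 ± 75 ms, uniform
  jitter), a 10-frequency x 10-repetition single-square sweep (4-s
  flickers, 1.75 ± 0.25 s gaps), and 9 x 8 = 72 four-second training
  trials for the speller.
* **Evoked components** are Gaussian-windowed half-sines with compact
  support, peaking exactly at their latency. Defaults: −567.34 fT at
  191 ms (N/M200-like, parieto-occipital) and −1103.38 fT at 347 ms
  (P/M300-like, centro-parietal). Magnetometer field maps are signed
  dipolar, $g(u) = u e^{-u^2/2}$ along the left-right axis, so
  neighbouring sensors show the polarity reversal that makes synthetic
  gradiometers effective; EEG maps are single-signed Gaussians.
* **Steady-state responses** are sinusoids at the target frequency with
  the target phase minus $2\pi f L$, where $L = 50$ ms is the assumed
  latency of the visual system — reproducing the negative phase-vs-
  frequency trend seen in real recordings.
* **Noise** is per-channel white Gaussian plus $1/f^\beta$-shaped Gaussian
  ($\beta = 1$), both 300 fT by default (about 13 fT/$\sqrt{\mathrm{Hz}}$
  over a 500 Hz bandwidth, a realistic broadband magnetometer floor).
  Sensor noise is independent across channels.
* The default sampling rate is 1000 Hz, and the default frequency-phase
  layout crosses {8, 9, 10} Hz with phases {0, 2pi/3, 4pi/3}; both are
  plain configuration values, since neither the acquisition rate of the
  magnetometer system nor the exact on-screen frequency-phase assignment
  is fixed by the paradigm.

**Calibration of the response amplitude.** The steady-state response
amplitude is not a published quantity, and two printed observables pull in
different directions under this simple signal model: matching the per-epoch
spectral SNR ratios (about 2.2–2.6 at the best sensor) requires roughly
30 fT, while the 93–100% spelling accuracies imply a stronger effective
response — unsurprising, since the real decoder drew on 24 sensors plus 45
gradiometers, whereas the default synthetic array has nine. The default of
50 fT was fixed once as the compromise: it yields best-channel spectral SNR
around 2.8–4.0 and spelling-session accuracies of roughly 85–100% across
seeds, both on the scale of the real recordings. Tests that require a
*high-SNR* regime construct it explicitly (amplitude at least five times
the noise sigma) rather than inheriting it from these defaults.

**What the generator does not emulate:** trial-to-trial amplitude/latency
variability, spatially correlated sensor noise, movement or ocular
artifacts, stimulus-evoked harmonics, or any forward head model. Passing
tests therefore demonstrate the correctness and internal consistency of the
pipeline under controlled conditions, not performance on real recordings.

## Evaluation and channel selection

Decoding accuracy is estimated by stratified, seeded k-fold
cross-validation — fivefold for ERP decoding (stratified over trials by
cued cross, so a trial's epochs never straddle folds) and fourfold for the
speller — with all predictions pooled into one confusion matrix
(accuracy = trace/total). Greedy forward channel selection starts from the
empty set and repeatedly adds the candidate channel that maximizes the CV
score (ERP: mean fivefold accuracy over one to five stimulus repetitions;
SSVEP: fourfold accuracy), stopping at 100% or when the score no longer
strictly improves.

## The simulated speller

`run_spelling_session()` reproduces the online loop: the word's characters
(plus seeded random fillers up to eight, plus a backspace icon) are
scattered over the nine targets; for each selection a fresh 2-s stimulation
epoch is synthesized for the gazed target, filtered 4–40 Hz, downsampled,
and classified with the 150-ms discard rule. The simulated user gazes the
next needed character, or the backspace immediately after a decoding error;
a word ends when the working text reaches the word's length (a trailing
error therefore ends the word uncorrected, as in the real protocol). The
20-s habituation period before each word has no signal consequence and is
not modelled. `posthoc_length_sweep()` re-classifies the session's epochs
truncated to 0.25–2 s in 0.25-s steps.

## Numerical choices

* Covariance: mean-centred, $1/(N-1)$ normalization over vectorized
  segments; pseudo-inverse tolerance $10^{-10}$ of the largest eigenvalue.
* Ties in classification break to the lowest target id (determinism).
* Bootstrap: BCa with $z_0$ from the bootstrap distribution (ties counted
  half) and acceleration from jackknife skewness; degenerate all-identical
  resamples collapse to a zero-width interval. Seeded throughout.
* Circular dispersion returns `Inf` when the resultant length is below
  1e-12 (exact antipodal cancellation).
* Zero-phase filtering pads by odd reflection (at least three filter
  lengths, up to 100 samples); epochs shorter than the padding requirement
  are an error rather than a silent degradation.
* The problem sizes used by the test-suite simulations (for example 45-
  trial ERP sessions on a 9-channel grid, 72-trial speller sessions, 900
  noise-only trials for the chance-level check, 800 replicates for
  bootstrap coverage) were chosen to make Monte-Carlo tolerances tight at
  desk scale.

## Limitations

The pipeline decodes in sensor space only; source-space decoding, artifact
rejection, bad-channel handling, harmonic-combination SSVEP features and
alternative classifiers (CCA, TRCA, Riemannian) are out of scope. The
synthetic generator's simplifications listed above mean that absolute
accuracy figures on synthetic sessions should not be read as predictions
for real subjects.
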