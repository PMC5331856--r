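---
title: "Methods: simulating and measuring fast-rate musical-note ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring fast-rate musical-note ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noteERP)
```

## The experimental design being emulated

noteERP models a blocked auditory experiment in which guitar notes are
presented at 4 Hz (one note per 250 ms) over five 5-minute blocks. Two
blocks carry a *patterned* sequence: overlapping three-note sliding windows
climbing through four two-octave major-scale fretboard shapes (E, D, C, A
in that order), the whole cycle repeating one semitone higher each time it
completes. Two blocks present the *same notes* in a fixed random order, so
the pattern/random contrast is purely sequential — the stimulus multisets
are identical. A fifth block is a classic oddball stream: a frequent
standard note (G2, 90%) and a rare deviant (F4, 10%), with an exact 120 /
1080 split over the 1200 events of a block. Block order is counterbalanced
with a 5 × 5 Latin square; with 13 subjects the rows are reused cyclically.

Audio is synthesized with a plucked-string delay-line model (an
additive-harmonic fallback is available), each 250 ms note mean-removed,
linearly ramped over its first and last 10 ms, and normalized to a 0.40
maximum absolute amplitude. The amplitude envelope of a rendered patterned
block is periodic at the presentation rate, so its rectified, low-passed
(4th-order Butterworth at 20 Hz, zero phase) power spectrum peaks at 4 Hz
with harmonics at 8 and 12 Hz — a useful stimulus-side sanity check that
does not depend on timbre.

## The evoked model

Each stimulus evokes a kernel over 0–500 ms built from Gaussian-windowed
peaks (`width_ms` is the FWHM; sigma = width / 2.355) plus a Hann-windowed
8 Hz cosine over the 250 ms note interval. The pattern/random kernel has
four peaks, near 20, 100, 175 (negative) and 200 ms — two periods of an
8 Hz oscillation per note. The oddball standard adds a small late
positivity near 300 ms; the deviant modulates the ~175 ms (mismatch
negativity) and ~300 ms (late positive / P300-like) components. Peak
widths default to 16 ms (24 ms for the late positivity): narrow enough
that the 175 and 200 ms peaks, only 25 ms apart, do not bleed into each
other's half-maximum spans, and smooth enough that a 50 Hz low-pass leaves
them largely intact. Absolute microvolt amplitudes are placeholders (the
literature this design comes from reports figures, not microvolt tables);
every analysed quantity is a relative contrast.

Topography is a fixed per-channel gain in [0, 1] over a 24-channel 10–20
montage, maximal at Fz and ~0 at the two mastoids, so mastoid
re-referencing is approximately signal-neutral while still propagating
mastoid noise, as it does in real recordings. Background activity is
independent per-channel 1/f pink noise (spectral exponent 1, RMS
configurable; 5 µV at the full-scale preset). Optional packet-loss gaps
zero the signal and set a boolean mask, emulating dropouts of a wireless
amplifier.

### Effects are injected on the measurement scale

The headline condition effects are percent modulations of peak amplitude:

* random vs pattern: −56.42% at the ~175 ms negative peak (more negative
  for random), +45.41% at the ~200 ms positive peak;
* rare vs frequent: −300.35% at ~175 ms (mismatch negativity), +759.77%
  at ~300 ms;

all on the signed scale `100 * (a_test − a_ref) / |a_ref|`.

A subtlety makes naive injection unrecoverable: any AC-coupled pipeline
(detrending plus a 0.01 Hz high-pass) removes each block's DC, so
amplitudes are only measurable relative to the block mean, and the 50 Hz
low-pass slightly reshapes narrow peaks. Multiplying a kernel component by
1.4541 therefore does *not* move the measured FWHM-mean amplitude by
45.41%. noteERP instead defines the injected modulation as the percent
change *of the measured quantity*: component gains for the random and
deviant kernels are found by a chord-Newton iteration against a noise-free
forward model of the steady-state epoch — the periodised kernel train,
mean-removed (including the small DC residual that detrending a padded
finite block leaves behind), passed through the same zero-phase Butterworth
cascade as the pipeline, measured with the same peak-window and FWHM code.
With this calibration the zero-noise pipeline recovers injected
modulations to well under one percentage point, which is what makes
bias checks meaningful; the residual solver tolerance is 0.02 points.

### Subject heterogeneity and the latent factor

Each subject draws a standard-normal latent sensitivity `z`. The four
modulation parameters vary between subjects (SDs of 5, 5, 15 and 40
points) with loadings ±sqrt(rho) on `z`, signed so that the observable
pair — the pattern-minus-random amplitude *difference* and the rare-note
amplitude — correlates at the configured target (+0.65 for the ~175 ms
pair, +0.38 for the ~200/~300 ms pair). Familiarity ratings (integers
1–7, mean 4, SD 1.8 before rounding) load on `z` with
`rho_fam / sqrt(rho_n175)`, targeting a −0.45 correlation with the N175
difference; integer rounding and clipping attenuate this slightly, and the
implied familiarity correlation of the ~200 ms channel is a by-product
rather than a controlled target.

## The measurement pipeline

Per recording: linear detrend per channel; zero-phase Butterworth
band-pass 0.01–50 Hz; re-reference to the mastoid mean. The band-pass is a
cascade of an order-4 high-pass and order-4 low-pass, each run forward and
backward: a single band-pass design with a 0.01 Hz edge at 500 Hz places
poles so close to the unit circle that its transfer-function realisation
is numerically unstable (we measured gain errors of three orders of
magnitude), while the cascade is exact to well under 1% in the passband.
Each filter is realised as analytically derived second-order sections
(Butterworth prototype poles through the bilinear transform, unit gain per
biquad at its reference frequency): even as a cascade, a direct-form
order-4 high-pass at 0.01 Hz amplifies input rounding noise by ~1e11,
visible as millivolt-scale-relative artifacts, whereas the biquad form
keeps it near machine precision.

Epochs span [−250, +500) ms around each onset — half-open, the t = 0
sample included, 375 samples at 500 Hz. Epochs overlapping any lost-packet
sample are rejected, as are epochs exceeding 100 µV absolute amplitude on
any non-mastoid channel or a 3.5 SD across-epoch variance z-score. This
threshold rejection is a deliberate, documented stand-in for toolbox
artifact detection and ICA blink removal: simulated data contains no
blinks, and the rejection stage exists so that the exclusion logic
(including packet loss) is exercised, not to reproduce a particular
toolbox. No per-epoch baseline subtraction is applied by default (for a
4 Hz steady-state train the pre-stimulus cycle mean is ~0 anyway).

The analysis electrode is the channel whose across-*condition* average has
the largest absolute amplitude in 0–500 ms (mastoids excluded, ties to the
lower channel index) — averaging across conditions first keeps the choice
unbiased with respect to condition differences. Group peak windows are
then found on that electrode's across-subject, across-condition grand
average: local extrema exceeding 0.5 µV prominence, windows bounded by
zero crossings, or by the midpoint between extrema when two neighbouring
peaks share a sign — a midpoint stays put when noise wiggles the flat
stretch between peaks, which is what keeps window boundaries stable to a
couple of samples under percent-level noise; same-sign extrema within
20 ms merge. Windows are computed jointly over
both conditions of a stage; for the pattern/random stage only windows
peaking inside 0–250 ms are kept (later windows repeat the next note's
early peaks), and for the oddball stage the windows nearest 175 and
300 ms.

Within each group window, each subject's per-condition amplitude is the
FWHM mean: the extremum of the window's polarity — preferring an interior
local extremum over a window-edge maximum, so that activity leaking across
a boundary from the neighbouring note's response is never mistaken for
the peak — a half-maximum level of
half the peak value relative to the 0 µV baseline of the mean-free
filtered signal, the contiguous same-sign span around the peak above
half-maximum in magnitude, and the mean amplitude over that span. A span
collapsing below two samples falls back to the peak sample and is flagged.
For an isolated Gaussian peak this estimator has a closed-form value
(mean of the Gaussian over ±1.1775 sigma ≈ 0.81 × peak), which the test
suite uses as an oracle; it is exactly homogeneous (scaling the waveform
by c scales every amplitude by c), which underpins the percent-modulation
logic.

## Statistics

Ten planned comparisons: paired t-tests pattern vs random at the four
note-interval peaks; paired t-tests rare vs frequent at the two oddball
peaks; Pearson correlations of the pattern-minus-random differences
(N175, P200) with the rare-note amplitudes (~175, ~300 ms); and Pearson
correlations of those two differences with the familiarity rating. All
tests are two-sided; group-level percent modulations accompany each
amplitude contrast. The ten p-values pass through Holm–Bonferroni
step-down: ordered p-values compared to alpha/(m−k+1) — 0.005, 0.00556, …
at alpha = 0.05 — rejection stopping at the first failure. Degenerate
zero-variance paired differences are flagged rather than silently dropped
(all-zero differences give t = 0, p = 1).

## Problem sizes, presets, and what the tests show

Three presets set the scale. `"full"` is the complete design (13 subjects,
five 5-minute blocks, 5 µV noise). `"recovery"` is the effect-recovery
protocol: 13 subjects, one block per condition at 120 s, 0.1 µV RMS noise
(5% of the 2 µV reference peaks). Its geometry follows an error budget:
per-subject averaged-waveform noise is ~0.1/sqrt(480) ≈ 0.005 µV, keeping
the jitter of noisy FWHM span edges — the dominant small-sample bias of
this estimator, since a span that stochastically includes near-threshold
samples pulls the mean toward half-maximum — far below the injected
contrasts. At this scale recovered group modulations sit within ~1–2
points of the injected means across seeds. `"smoke"` (4 subjects, 30 s)
exists for fast end-to-end tests. The latent-correlation check uses 500
subjects with 20 s blocks: between-subject effect spread dominates
measurement noise there, so the empirical r is attenuated by well under
2% relative to the construction target, and the Monte-Carlo SD of r at
n = 500 is about 0.026.

Passing tests demonstrate internal consistency on synthetic data — correct
arithmetic, calibrated injection, unbiased recovery, type-I control of the
roster under the null (rejection rates within binomial bounds of alpha
over 500 measure-level replicates), and bit-level reproducibility from
one master seed through named substreams. They do not certify behaviour on
real EEG: real data have non-Gaussian artifacts, spatially correlated
noise, drifting topographies and genuinely unknown kernel shapes, and the
stand-in rejection stage is far cruder than toolbox pipelines.

## Known limitations

* No volume-conduction or forward head model — topography is a fixed gain
  vector, so re-referencing effects beyond the mastoid case are not
  modelled.
* No blink/EMG/line-noise taxonomy; the optional packet-loss generator and
  amplitude transients are the only acquisition artifacts.
* The FWHM estimator measures relative to the 0 µV filtered baseline; for
  peaks riding on strong slow activity a different reference (e.g. local
  trough-to-peak) would behave differently. The zero-crossing window rule
  is one defensible reading of "onset and offset times of each peak".
* Percent modulations of near-zero reference amplitudes are intrinsically
  unstable; the oddball ~300 ms reference is kept finite by the standard's
  small late positivity.
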