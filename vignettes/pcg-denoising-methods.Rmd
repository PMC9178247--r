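---
title: "Denoising pediatric phonocardiograms: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising pediatric phonocardiograms: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgdenoise)
```

## The problem

A pediatric phonocardiogram is a weak signal in a hostile environment.
The heart sounds S1 and S2 concentrate their energy roughly between 30 and
200 Hz; pathological murmurs from septal defects add quasi-stationary
energy up to ~300 Hz during systole. On top of this sit ambient broadband
noise, impulsive sensor/contact artifacts, and — uniquely troublesome in
infants — crying, whose energy lies above ~155 Hz and can dominate the
waveform for seconds at a time. Classical wavelet soft-threshold denoising
(WST) handles stationary broadband noise but has no mechanism to reject a
burst that towers over its threshold; decomposition methods can isolate the
burst but leave broadband residue inside the heart-sound bands. The package
combines the two: variational mode decomposition (VMD) to separate noise
into rejectable modes, entropy/correlation screening to decide which modes
to keep, and WST to polish what remains.

## The model and its stages

### Variational mode decomposition

VMD represents the record as K band-limited AM/FM modes and finds them by
minimizing total mode bandwidth subject to reconstruction, via alternating
frequency-domain updates (a Wiener-style mode update and a power-centroid
frequency update) with an optional dual-ascent step of rate `tau`.
Working defaults, chosen for 2 kHz heart sounds:

| parameter | default | meaning |
|---|---|---|
| `K` | 6 | number of modes; set from the count of distinct spectral peaks of quiet pediatric PCG, with near-coincident peaks merged |
| `alpha` | 2500 | bandwidth penalty; larger = narrower modes |
| `tau` | 0 | multiplier (dual ascent) rate; 0 relaxes exact reconstruction, appropriate when the input contains noise that should *not* be reproduced |
| `tol` | 1e-7 | relative spectral-change stopping threshold |
| `init` | uniform | centers start at (k − ½)(f_s/2)/K |

Numerical choices: the signal is mirror-extended by half its length on each
side before the FFT and cropped after inversion, suppressing edge artifacts
of the periodic transform; the iteration works on the one-sided spectrum
with Hermitian symmetrization on return; modes are sorted by ascending
center frequency after convergence so "the last mode" is well-defined; a
mode whose previous spectrum is identically zero is treated as unconverged
if it acquires energy (this matters: the first sweep starts from all-zero
modes). Convergence failure is reported through `converged = FALSE`, not an
error. A zero input returns zero modes with the initialization's center
frequencies.

### Mode screening

Noise-bearing modes are recognized by two complementary statistics:
normalized permutation entropy `pec` (pattern randomness, 0 for monotone,
→1 for i.i.d. noise; order m = 5, delay 1, normalized by log m! so the
index is a true [0,1] quantity) and the absolute Pearson correlation `rsig`
between mode and the *noisy* input — the only reference available at run
time. The screening index `rsp = 0.3 (1 − rsig) + 0.7 pec` weights entropy
more (β = 0.3 is a propensity toward the entropy term). Rejection requires
the conjunction `rsp > 0.6` **and** `rsig < 0.5`: a high-entropy mode that
still correlates with the record (e.g. a murmur-bearing band) is kept.
Ordinal-pattern ties are broken by position (earlier sample ranks lower),
which makes the entropy deterministic on quantized audio. If the rule
rejects all modes — possible on noise-only input, which the clinical
procedure never meets — the best-correlated mode is retained so the
pipeline stays total, with a warning.

Known limitation, inherited from the method itself: continuous
low-frequency noise correlates with the input and can defeat screening;
the thresholds are exposed in `run_config()` but no adaptive remedy is
implemented.

### Wavelet soft-threshold stage

Daubechies-6, 6 levels, soft thresholding of all detail bands with the
universal threshold σ̂√(2 ln N), σ̂ = MAD of the finest details / 0.6745,
N the full signal length; approximation coefficients (≤ ~15.6 Hz at 2 kHz)
are never thresholded, preserving the lowest heart-sound content. The
transform uses **periodized** boundary handling rather than symmetric
extension: with orthogonal filters, periodization keeps the analysis
operator exactly orthogonal at every even length, so the inverse is exact
to machine precision — a property the test suite asserts directly (t = 0
reconstructs to 1e−10) and which symmetric extension cannot provide without
redundancy. Odd lengths at any level are handled by repeating the final
sample and cropping on inversion. A per-level σ̂ was considered and
rejected as the default: the global finest-band estimate is the classical
recipe and is what makes the method's characteristic behavior on crying
records reproducible (see below).

### Pipeline orders

VWG shrinks each retained mode separately and then sums (rejected modes are
discarded *before* shrinkage); VGW sums first and shrinks once. On Gaussian
noise the two differ little — each mode's finest-detail band estimates the
same noise floor that the summed signal's does. The practical difference
appears with structured noise, where per-mode thresholds adapt to each
band. The `vmd_last` baseline keeps only the highest-frequency mode; it
reproduces the known failure of that approach on heart sounds, whose
content spans the last *two* modes — `test-denoise.R` asserts the resulting
quality ordering.

## The synthetic generator: what it emulates and what it does not

No clinical recordings ship with the package, so every claim is exercised
on synthetic data built from the field's standard phenomenology:

* **S1/S2** as Gaussian-enveloped sinusoids at 50 Hz (25 ms envelope SD)
  and 75 Hz (20 ms), amplitudes 1 and 0.8, S2 at 35% of the cycle.
  The two frequencies straddle the 62.5 Hz boundary between the d4 and d5
  wavelet bands, as real S1 (dominant 30–60 Hz) and S2 (50–100 Hz) spectra
  do — which is precisely what the Hadamard-product envelope exploits.
* **Murmurs** as band-passed white noise (100–300 Hz) gated to systole with
  10 ms ramps, amplitude relative to the S1 peak.
* **Gaussian ambient noise** rescaled post hoc so the realized SNR equals
  the request exactly, not just in expectation.
* **Impulsive interference** as periodic Hann-windowed broadband clicks.
* **Crying** as band-limited noise bursts with 20 ms cosine ramps. The
  default band is 155–950 Hz: 155 Hz is where crying interference begins
  to overlap heart-sound analysis, and the upper edge deliberately exceeds
  the stethoscope's nominal 500 Hz corner because a loud cry's harmonics
  pass the gradual hardware roll-off. This out-of-band energy is what
  inflates a MAD-based noise estimate during severe crying — the mechanism
  behind WST's characteristic over-smoothing of crying records, which the
  package reproduces. `severe_crying_pcg()` freezes the package's
  reference condition: five 1.3 s bursts in 10 s (65% duty) at 2.5× the
  signal peak.

What the generator does **not** model: valve-motion dynamics, respiratory
modulation, split S2, heart-rate variability within a record, multi-site
auscultation, and — importantly — the tonal, formant-structured character
of real crying. Passing tests therefore demonstrate that the pipeline's
mechanisms work as designed on signals with the right spectral geometry;
they do not certify clinical performance.

A note on what synthetic murmurs imply: because the murmur model *is*
band-limited noise, the screening stage scores murmur-dominated modes much
like noise and may reject them — unlike real murmurs, whose resonant
structure keeps them correlated with the record. Claims about murmur
preservation through VWG/VGW are therefore outside what these simulations
can establish; the screening-stage evaluation instead derives its features
from recordings that are not VMD-denoised first.

## Evaluation metrics

* `snr_db(clean, est)` — 10 log10 of clean power over error power; equal
  signals return a 300 dB capped sentinel (flagged) rather than infinity.
* `rmse` — amplitude-domain error.
* `dn_snr(noisy, denoised)` — 10 log10(P_noisy / P_denoised), reference-free.
  By construction it *increases* as more energy is removed, whether that
  energy was noise or signal; the package reports the value and leaves
  interpretation to the experiment's design (on crying records, wavelet
  shrinkage with an inflated threshold removes nearly everything and scores
  high; the mode-screening pipelines remove the crying and keep the heart
  sounds, scoring low).
* `mel_energies` — 24 triangular filters uniform in Mel between 30 and
  500 Hz (the stethoscope's hardware band), 25 ms Hann frames, 10 ms hop.
  24 filters places the 9th filter's lower edge at ≈156 Hz, so "filters 9
  and up" is exactly the crying-affected band. Band-energy comparisons use
  the linear scale (`log = FALSE`): summed linear filter energies are
  additive, whereas log differences against a near-floor reference would
  magnify physically negligible leakage.
* `confusion_metrics` — Acc/Se/Sp in percent, rounded to 2 decimals,
  positive class = abnormal.

The shipped clinical benchmark tables (`clinical_benchmark()`) hold the
published per-recording SNR/RMSE results of the four denoisers on eight
pediatric recordings at 5 and 10 dB added noise; `benchmark_summary()`
reproduces their aggregate figures (e.g. VGW 12.39 dB vs WST 7.56 dB mean
output SNR at 5 dB input).

## Segmentation and features

The envelope is the moving-average-smoothed (50 ms) absolute Hadamard
product of the full-length d4 and d5 detail reconstructions, normalized to
max 1. Peaks are picked greedily (loudest first) above 0.2 of the maximum
with ≥120 ms separation; alternate-interval logic labels the shorter
interval of each adjacent pair (≤0.5 s) as systole, fixing S1/S2 identity;
trailing incomplete cycles are dropped and fewer than three qualified peaks
is an error, not a guess. The window defaults (50 ms smoothing, 0.2
threshold, 120 ms gap, 0.5 s systole cap) are physiological bounds for
pediatric rates of 60–160 bpm.

Features 1–10 are, per cycle and then averaged: max, (signed) min and mean
absolute amplitude in the systolic S1→S2 window (CAV) and diastolic
S2→next-S1 window (CSV), plus max and mean Hann-periodogram PSD of each
window. Peak-to-peak windows include the transient tails; "min" is read as
the signed minimum, the literal counterpart of "max". Murmurs raise the
systolic amplitude and PSD features, which is the discriminative signal.

## Classifier

A 10-10-1 sigmoid network trained by full-batch gradient descent on MSE
(lr 0.05, 500 epochs, momentum 0.9, uniform ±0.5 init, all seeded and
deterministic). Features are z-scored with statistics from the training
fold only, stored in the model and applied at prediction — leave-one-out
evaluation therefore cannot leak hold-out information. The output is
thresholded at 0.5 (a tie maps to abnormal, the safe screening direction).
Jackknife evaluation aggregates the n held-out predictions into one
confusion matrix; with 103 subjects this matches the convention that
produced the published error-count arithmetic.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments use 10 s records at 2 kHz:
the Gaussian experiment pairs 4 generator specs (75–130 bpm) with 5 noise
seeds per level (20 records at 5 and at 10 dB), the crying comparison runs
the frozen severe-crying scenario over several seeds, and the screening
chain uses a 37 + 66 cohort, mirroring the demographic split of the
clinical study design. These sizes keep a full run in the minutes range on
one CPU while leaving the medians stable across seeds.

## Known limitations

* Screening assumes noise and heart sounds separate in frequency; broadband
  noise below 100 Hz lands in retained modes and reaches the wavelet stage
  unscreened.
* `K` is fixed, not selected per record; severe under- or over-decomposition
  changes which modes are rejectable.
* The dnSNR convention rewards aggressive energy removal; it is only
  meaningful alongside a reference-based metric or a band-energy analysis.
* The classifier is a deliberately small screening network; it saturates on
  cleanly separable synthetic cohorts and says nothing about calibration.
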