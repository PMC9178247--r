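# pcgdenoise

Denoising and automated screening of children's heart-sound recordings
(phonocardiograms, PCG).

Pediatric PCG acquired in clinic is contaminated by ambient noise, sensor
friction and — for infants — crying, which buries the murmurs that signal
congenital heart disease (ventricular/atrial septal defects and related
lesions). This package implements a combined denoiser for such recordings,
the evaluation metrics to judge it, and the downstream segmentation /
feature / neural-network stage that turns a denoised recording into a
normal-vs-murmur screening decision. A synthetic PCG generator with ground
truth makes the entire chain testable without clinical data.

## Method

**Variational mode decomposition (VMD).** The recording x(t) is decomposed
into K band-limited modes u_k(t) = A_k(t) cos(φ_k(t)) by minimizing the
summed mode bandwidth subject to Σ_k u_k = x, solved in the frequency domain
by alternating updates:

    û_k(ω) ← ( x̂(ω) − Σ_{i≠k} û_i(ω) + λ̂(ω)/2 ) / ( 1 + 2α (ω − ω_k)² )
    ω_k    ← ∫₀^∞ ω |û_k(ω)|² dω / ∫₀^∞ |û_k(ω)|² dω

with K = 6, penalty α = 2500 and multiplier rate τ = 0 as the working
defaults for heart sounds at 2 kHz.

**Mode screening.** Each mode is scored by its normalized permutation
entropy pec_k and its absolute correlation RSig_k with the (noisy) input,
combined as

    RSp_k = β (1 − RSig_k) + (1 − β) pec_k ,  β = 0.3.

A mode is rejected as noise iff RSp_k > 0.6 **and** RSig_k < 0.5.

**Wavelet soft-threshold shrinkage (WST).** Daubechies-6, 6 levels,
universal threshold T = σ̂ √(2 ln N) with σ̂ = median(|d₁|)/0.6745; detail
coefficients are soft-thresholded, the approximation band is untouched.

Two pipeline orders are provided: **VWG** (shrink each retained mode, then
sum) and **VGW** (sum retained modes, then one shrinkage pass), alongside
WST-only and a keep-last-mode VMD baseline.

**Screening stage.** Cycles are segmented from the Hadamard product of the
level-4 and level-5 wavelet detail reconstructions (double-qualified peak
picking), 10 amplitude/PSD features are extracted from the systolic (CAV)
and diastolic (CSV) windows, and a 10-10-1 sigmoid back-propagation network
with a 0.5 output threshold is evaluated by leave-one-out jackknife,
reporting accuracy, sensitivity and specificity.

## Worked example

```r
library(pcgdenoise)

spec  <- pcg_spec(duration = 10, heart_rate = 90, seed = 3)
clean <- generate_clean_pcg(spec)$signal
noisy <- add_gaussian_noise(clean, snr_db = 5, seed = 42)

out <- denoise(noisy, "vgw")
out$scores
#> <mode_scores> beta = 0.3, reject if rsp > 0.6 & rsig < 0.5
#>  mode   pec  rsig   rsp decision
#>     1 0.369 0.737 0.337 retained
#>     2 0.397 0.554 0.412 retained
#>     3 0.631 0.188 0.685 rejected
#>     4 0.699 0.188 0.733 rejected
#>     5 0.677 0.190 0.717 rejected
#>     6 0.566 0.175 0.644 rejected

snr_db(clean, noisy)                 # 5.00  (by construction)
snr_db(clean, out$denoised)          # 16.21
snr_db(clean, denoise(noisy, "wst")$denoised)   # 8.37
```

The decomposition isolates the broadband noise into the high-frequency
modes (high entropy, low correlation — rejected); the wavelet pass then
cleans the retained heart-sound modes. On this record VGW recovers ~16 dB
output SNR from a 5 dB input, roughly double the gain of wavelet shrinkage
alone — the same ordering the clinical benchmark table shows
(`benchmark_summary("snr")`).

The screening chain:

```r
coh   <- generate_cohort(n_normal = 37, n_abnormal = 66, seed = 11)
feats <- t(sapply(coh$signals, function(s) segment_pcg(s)$features))
jackknife_eval(feats, coh$labels, seed = 3)
#> <pcg_eval> n = 103 | TP 65  TN 37  FP 0  FN 1
#>   Acc 99.03%  Se 98.48%  Sp 100.00%
```

A command-line front end (`inst/cli/pcgdenoise`) exposes `denoise`,
`simulate`, `evaluate`, `segment` and `classify` subcommands over WAV/JSON/CSV
files; see `?pcg_cli`.

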