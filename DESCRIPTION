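Package: pcgdenoise
Title: Variational Mode Decomposition and Wavelet Denoising of Pediatric Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoising of children's heart-sound recordings (phonocardiograms, PCG)
    by variational mode decomposition (VMD) combined with wavelet soft-threshold
    shrinkage (WST). Modes are screened by a permutation-entropy/correlation index
    before reconstruction; two pipeline orders (per-mode shrinkage then sum, VWG;
    sum then one shrinkage pass, VGW) are provided alongside WST-only and a
    last-mode VMD baseline. Includes a synthetic pediatric PCG generator with
    Gaussian, impulsive and crying-burst noise injection, SNR/RMSE/dnSNR and Mel
    filterbank evaluation metrics, Hadamard-product heart-sound segmentation with
    systolic/diastolic feature extraction, and a small back-propagation network
    with leave-one-out evaluation for murmur screening.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
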