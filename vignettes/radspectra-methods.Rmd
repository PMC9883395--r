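---
title: "Methods: radiation-response classification of Raman tissue spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiation-response classification of Raman tissue spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radspectra)
```

# The problem

Ionizing radiation alters the biochemistry of tumour tissue: lipid,
collagen, phenylalanine and tyrosine Raman bands rise after dose delivery
while nucleic-acid bands (790, 812 cm^-1) fall. `radspectra` implements an
end-to-end pipeline for deciding, from a single preprocessed Raman spectrum
of xenograft tumour tissue, whether the tissue was irradiated:

1. a **synthetic-data generator** emulating the hierarchical design of an
   irradiated-xenograft study (dose arms of mice, three consecutive tumour
   sections per mouse, two Raman maps per section);
2. a **preprocessing chain** (cosmic-ray removal, Savitzky-Golay smoothing,
   polynomial baseline subtraction, total-area normalization);
3. a **one-dimensional CNN** classifier;
4. a **group/basis-restricted NMF** (GBR-NMF) feeding a **random forest**,
   the interpretable baseline;
5. a **validation harness**: random splits, leave-one-mouse/section/map-out
   validation, confusion metrics, multi-run aggregation and a Wilcoxon
   comparison of the two models.

Every stage is testable without any external download: the generator is a
first-class, tested module, not a fixture.

# The synthetic world

Each spectrum is built on a 582-point uniform wavenumber grid. The grid
range is configurable and defaults to 600–1800 cm^-1, the fingerprint
region that contains every band the generator uses (the true instrument
range behind a 582-point spectrum is not public; only the length matters
downstream).

A spectrum of a mouse at dose $d$ (Gy) is

$$ y(\nu) \;=\; \sum_j a_j\,(1 + c_j d)\; g^{mouse}_j g^{sec}_j g^{map}_j\,
   L(\nu; \nu_j, w_j) \;+\; b(\nu) \;+\; \varepsilon(\nu), $$

clipped at zero and normalized to unit trapezoidal area, where
$L(\nu;\nu_j,w_j)$ is a Lorentzian line (the typical Raman lineshape) with
half-width $w_j$ (default 8 cm^-1), $a_j \ge 0$ the base band amplitude,
and $c_j$ the signed fractional amplitude change per Gy. Defaults place
bands at the wavenumbers reported for MDA-MB-231 xenografts, with
$c_j = +0.02$/Gy for the lipid/collagen/phenylalanine/tyrosine bands,
$-0.02$/Gy for the 790/812 cm^-1 nucleic-acid bands, and 0 for the
remaining prominent bands — a ±30 % band change at 15 Gy, a moderate,
clearly resolvable effect chosen once and not revisited.

Key choices where the design was genuinely open:

* **Dose-effect form.** Linear multiplicative scaling $(1 + c_j d)$ — the
  simplest form consistent with "increased / decreased band content";
  amplitudes are floored at zero so large negative coefficients cannot
  produce unphysical bands.
* **Random effects.** Independent log-normal factors per *band* at the
  mouse (sdlog 0.10), section (0.05) and map (0.05) levels. Drawing them
  per band (rather than one scalar per unit) changes relative band
  intensities between animals, which is what makes subject-wise validation
  genuinely harder than a random split — a single scalar would be removed
  entirely by area normalization.
* **Baseline.** A broad random cubic bump (non-negative, unit height,
  scaled by `baseline_amplitude`, default 2) drawn **per spectrum**:
  fluorescence varies point to point within a map. Drawing it per map
  would hand a classifier a map-specific fingerprint (see *Null-effect
  calibration* below).
* **Counts.** Defaults of 5 mice/arm × 3 sections × 2 maps reproduce the
  5-mouse / 15-section / 30-map day-3 hierarchy used for subject-wise
  validation; `spectra_per_map = 80` puts an arm at 2400 spectra, the
  order of the real day-3 arms (2200 and 2505). The per-map spectrum count
  of the real study is not public; 80 was chosen once for scale realism.
* **Basis library.** Stand-ins for the 31 pure-biochemical spectra (whose
  identities are not public): sparse random Lorentzian combinations,
  area-normalized, rejection-sampled so pairwise cosine similarity stays
  below 0.90 (the library must be well-conditioned for constrained NMF).
  These are synthetic surrogates and are labelled as such.

What the generator does **not** emulate: instrument physics (CCD noise,
cosmic-ray statistics beyond an additive impulse), spatial correlation
within a map, realistic biochemical concentrations, or wavenumber
calibration drift (the grid is exact by construction, so the drift
correction step in preprocessing is a documented no-op). A green test
therefore establishes correctness of the *algorithms* under the stated
world, not the reproduction of any real-tissue accuracy.

# Preprocessing

The chain applies, in configurable order: despiking (points whose
second-difference robust z-score exceeds 8 are replaced by the median of
their nearest *unflagged* neighbours — a spike corrupts the second
difference of its neighbours too, so flagged points must not serve as
replacements; passes repeat until clean), Savitzky-Golay smoothing (window
11, polyorder 3; asymmetric edge fits so polynomials are reproduced
exactly everywhere), baseline subtraction by iterative polynomial fitting
from below (order 5: fit, clip the spectrum to the fit, refit to
convergence), and total-area normalization (trapezoidal; exact and
idempotent). These are common Raman defaults; all are configurable so
sensitivity can be tested.

# The CNN

The published architecture is followed exactly where it is specified:
input 582 × 1; conv(32 filters, 20 × 1, stride 1, no padding) → batch norm
→ ReLU; conv(64, 20 × 1, 1) → BN → ReLU; flatten; fully-connected layers;
dropout 0.10; 2-neuron output; softmax. The convolution output length obeys
$O = (I - K + 2P)/S + 1$, giving the 563 × 32 and 544 × 64 feature maps;
the implementation refuses non-divisible configurations rather than
flooring silently. Training minimizes cross-entropy plus an L2 penalty
($\lambda = 10^{-4}$, applied to conv/FC weights as $\tfrac{\lambda}{2}
\lVert w\rVert^2$) with Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) in mini-batches of 175.

Decisions where the published description is silent:

* **Hidden widths.** "Fully connected layers" without sizes: default one
  hidden layer of width 100 with ReLU, then dropout, then the 2-neuron
  output. Width and count are configurable.
* **Early stopping.** "Stops once validation accuracy stops improving" is
  unquantified: patience 10 epochs, improvement threshold 0, cap 200
  epochs; validation is evaluated once per epoch (deterministic). The
  returned model carries the weights *and* batch-norm running statistics
  of the best validation epoch (first occurrence on ties), so reloading
  reproduces the recorded best accuracy exactly.
* **Batch-norm statistics at inference.** Running averages (momentum 0.1)
  accumulated during training, but *seeded from the first mini-batch's
  statistics* rather than the conventional mean 0 / variance 1:
  area-normalized spectra have intensities of order $10^{-3}$, so
  activations sit orders of magnitude away from unit variance and a
  conventionally initialized running variance takes hundreds of updates to
  forget — during which validation accuracy is stuck at prevalence and
  patience-based stopping would fire on an untrained model.
* **Class imbalance.** No reweighting, matching the published silence.
* **Seeding.** One integer seed drives weight init, shuffling and dropout;
  training accuracy per epoch is the sample-weighted mini-batch accuracy.
* **Ties at prediction.** Exactly equal probabilities classify as
  `nonirradiated` (documented, tested).

# GBR-NMF and the random forest

GBR-NMF minimizes $\lVert V - WH\rVert_F^2$ with $W \ge 0$, the first 31
rows of $H$ frozen to the library and one free non-negative row absorbing
unmodelled signal. The multiplicative solver uses Lee–Seung-type updates
restricted so frozen rows are never touched (the auxiliary-function
argument is element-separable, so updating only the free rows still never
increases the objective — the per-iteration Frobenius residual is recorded
and asserted non-increasing). Denominators are floored at $10^{-12}$;
convergence is a $10^{-6}$ relative error change or 2000 iterations. $W$
is initialized from seeded uniforms scaled to the data magnitude; the free
row from the clipped residual of the mean spectrum after NNLS projection
onto the library. With no free factor an exact per-spectrum Lawson–Hanson
NNLS solver is available, and `gbr_nmf_transform()` always scores new
spectra by NNLS against the full fixed basis set, so held-out units can be
projected onto training-fitted bases. Scores are used raw (no per-spectrum
normalization) by default.

The forest: 2000 trees, 5 candidate variables per split, CART/Gini grown
to purity on bootstrap samples. Feature importance is **explicit test-set
permutation MDA** (accuracy drop averaged over 10 seeded permutations per
feature, with its standard error), not the out-of-bag variant — the
evaluation set is explicit and the difference is documented. Because no
random-forest package is available in the target environment, the forest
is implemented in compiled code inside the package and drawn from R's RNG
so `set.seed()` governs it.

# Validation harness

Random splits use largest-remainder rounding of $N \cdot$ ratios
(70/20/10 for the CNN; 75/25 train/test for GBR-NMF-RF). Remainder ties go
to the smaller quota — e.g. $N = 4705$ at 70/20/10 gives (3293, 941, 471).
Subject-wise validation holds out one mouse / section / map at a time
(irradiated units by default; control spectra always remain in training,
matching the published workflow, with an option to hold out controls
symmetrically), trains on the remainder (85/15 train/validation for the
CNN, all-train for the RF) and reports the fraction of held-out spectra
classified correctly. A runtime leakage guard
(`assert_no_leakage()`) refuses any assignment in which a held-out unit's
identifier appears in training, with a dedicated error class mapped to CLI
exit code 3. Multi-run summaries report mean ± sample (n−1) SD; a
single-run SD is 0 by convention and flagged. Model comparison is a
two-sided Wilcoxon rank-sum test, exact when the combined sample is ≤ 25
without ties (a paired signed-rank option exists; unpaired is the
default). Per-run seeds are `base_seed + run`, recorded in the output.

## Null-effect calibration and the memorization trap

With dose coefficients set to zero *and* hierarchy variation switched off,
both models sit at chance (50 ± 5–6 % over 3 seeds) — this is the
package's null-calibration test. The hierarchy must be off for this oracle
to be valid: with per-mouse random effects left on, a random-split
classifier beats chance on "null" data by memorizing each mouse's band
fingerprint (every mouse appears in both training and test with a fixed
label). That is not a bug in the classifier but the within-subject leakage
that motivates subject-wise validation; it is the reason random-split and
leave-one-mouse-out accuracies differ on hierarchical data.

# Numerical and scale notes

* **The learning rate matters more than usual.** The flatten layer feeds
  the first FC layer ~35 000 *all-positive* (post-ReLU) activations. Adam
  moves every weight coordinate by roughly the learning rate per step, so
  a coherent gradient phase shifts the FC pre-activations by
  (rate × fan-in × mean activation) per step: at a rate of $10^{-3}$ a
  single epoch can drive every hidden unit's pre-activation below zero for
  all inputs, after which the ReLU layer is dead and training is
  irrecoverably stuck at the ln 2 loss plateau (observed, and verified
  against finite-difference gradients to rule out a backward-pass defect).
  The published rate of $10^{-4}$ keeps the drift an order of magnitude
  below the activation scale and trains stably; it is the default and is
  also used in the reduced test configurations.

* All deliberate randomness flows through explicit integer seeds; library
  calls restore the caller's RNG state.
* The test suite runs the model-level criteria at reduced scale (smaller
  nets, hundreds-to-~1400 spectra, 300-tree forests) to stay inside the
  test-time budget; architecture shape checks always use the full
  published configuration.
* A full-scale end-to-end run (≈4800 spectra through the default
  582→32→64/FC-100 CNN at mini-batch 175) measures ≈200 s per epoch
  (training plus validation) on one CPU in this implementation, so the
  ≥11 epochs forced by patience-10 early stopping alone exceed a
  15-minute budget (the constrained NMF at 2000 iterations adds ≈150 s
  and the 2000-tree forest ≈50 s). The published wall-clock is only
  reachable with an optimized GPU/SIMD deep-learning runtime, which is
  unavailable here; the pipeline is mechanically identical at both
  scales.
* The acceptance report (`scripts/acceptance.R`) recomputes the two
  architecture shape quantities (563 and 544) by the output-size formula
  and independently by reading observed shapes from a real forward pass.

# Known limitations

* Synthetic spectra are far cleaner than tissue maps: no spatial
  structure, no instrument drift, no cell-type heterogeneity. Green tests
  validate algorithmic correctness, not clinical performance.
* The CNN is CPU-bound R + BLAS; it is suitable for method study at
  reduced scale, not for large hyperparameter searches.
* The 31 basis spectra are synthetic surrogates; score rankings over them
  carry no biochemical meaning.
* MDA here is test-set permutation importance; values are not numerically
  comparable to out-of-bag MDA from other implementations.
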