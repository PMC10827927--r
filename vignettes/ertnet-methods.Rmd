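---
title: "ERTNet: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERTNet: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Emotion recognition from scalp EEG asks a classifier to map a short
multichannel voltage segment (an *epoch*, here 4 s) to an emotional state —
either a quadrant of the valence/arousal plane (HAHV, LAHV, HALV, LALV) or a
discrete category.  The signal properties that carry this information are
oscillatory power in canonical frequency bands (delta < 4 Hz, theta 4–8,
alpha 8–13, beta 13–30, gamma 30–50 Hz) and its distribution over the scalp,
with the beta and gamma bands over temporal and prefrontal sites carrying
the most emotion-related information.

ERTNet is a compact hybrid of a convolutional feature extractor (in the
EEGNet lineage) and a transformer encoder:

1. **Temporal convolution** — `F1` kernels of length `T` samples slide along
   time, one learnable FIR filter bank per kernel, with same-padding and *no
   activation*, so each kernel remains interpretable as a linear filter
   whose discrete-time Fourier transform tells us exactly which band it
   extracts.  Batch normalisation follows.
2. **Depthwise spatial convolution** — for each temporal kernel, `D`
   kernels spanning all `C` electrodes collapse the channel axis, learning
   scalp weighting patterns that can be read as topographies.  Batch
   normalisation, then ELU.
3. **Average pooling** (length `pool1 = 4`) and dropout.
4. **Separable convolution** — a depthwise temporal filter (length 16) per
   feature map followed by a pointwise (1×1) mix into `F2` features, with
   the structural constraint `F2 = F1 × D` enforced at construction.
   Batch normalisation, ELU, a second average pool (`pool2 = 8`), dropout.
5. **Transformer encoder** — the pooled maps become a token sequence
   `X ∈ R^{d×F2}` (`d = S / pool1 / pool2`), fixed sinusoidal positional
   encodings are added, and one encoder block applies multi-head
   self-attention with **full-width heads**: every projection `W_i^Q, W_i^K,
   W_i^V` is `F2 × F2` (so `d_k = F2`) and the concatenated heads are
   projected back by `W^O ∈ R^{nF2×F2}`.  This follows the printed weight
   shapes of the architecture rather than the split-head convention of the
   original transformer; with `n = 8` heads the attention layer is
   correspondingly wider.  Residual connections and layer normalisation
   wrap both the attention and the single-layer, ELU-activated feed-forward
   map (`F2 → F2`, chosen to keep the parameter count small).
6. **Head** — global average pooling over tokens (in place of a flatten) and
   a dense softmax over the classes.

The scaling divisor inside attention is `sqrt(F2)`; since heads are full
width, `d_k = F2` is the only consistent reading.  Dropout defaults to 0.5
for subject-dependent work and 0.25 for subject-independent (LOSOCV) work.
A companion *flatten-head* variant (same extraction stack, flatten + dense
head, no transformer) serves as the EEGNet-style baseline and as the source
model for `transfer_init()`, which copies the extraction stack — temporal,
spatial and separable kernels plus all batch-norm parameters — bit-exactly
into a transformer-headed model.

A useful analytic property connects kernel length to frequency content: a
kernel of length `T` at sampling rate `Sr` cannot represent a full cycle of
anything slower than `Fmin = Sr / T` Hz.  `min_detectable_frequency()`
exposes this, and the sweep experiment below demonstrates its training
consequence.

## Training engine

No deep-learning framework is involved: the forward and backward passes are
implemented directly (R orchestration over BLAS matrix products, with the
fused temporal-convolution / batch-norm / spatial-convolution front in
compiled code under `src/`).  The optimizer is Adam (default learning rate
1e-3, batch 64, categorical cross-entropy, up to 100 passes with patience-10
early stopping on a 10% validation slice) — the training protocol itself is
a design choice of this package, since only the architecture and evaluation
protocols are prescribed by the method.  Batch normalisation uses batch
statistics during training and exponentially smoothed running statistics
(momentum 0.9) at inference; the momentum is deliberately lower than the
framework-default 0.99 so the running statistics converge within the short
training runs used here.  Every gradient in the engine is verified against
central finite differences in the test suite, and the complete forward pass
is verified against a dependency-free straight-loop reimplementation.

Convolution biases are omitted wherever batch normalisation immediately
follows (they would be redundant); weights are Glorot-uniform with a seeded
RNG; no max-norm constraints are applied (the EEGNet lineage sometimes uses
them, but they are not part of this architecture's description).  A seeded,
single-threaded run is exactly reproducible: data order, dropout masks,
initialisation and splits all derive from the configured seeds.

## Preprocessing

`bandpass_filter()` and `notch_filter()` design linear-phase windowed-sinc
(Hamming) FIR filters targeting a 0.5 Hz transition band (1 Hz for the
notch) and apply them with zero phase by centred convolution after even
reflection padding.  Even reflection is used because odd (point-mirrored)
reflection shifts the padded segment's mean by twice the edge value,
injecting a step whose broadband transient leaks into the passband.
`resample_recording()` resamples in the Fourier domain (`round(n × target /
source)` samples, new Nyquist bin zeroed on downsampling).
`segment_epochs()` cuts half-open, 0-based windows `[t, t + 4 s)` and drops
the trailing remainder.  Ratings at the threshold (default 5 on the 1–9
scale) count as "high" in all dimensional labelling modes.  Two preset
pipelines mirror the common dataset conventions: band-pass 4–45 Hz →
resample 128 Hz → 4-s segments (dimensional-style, no re-normalisation),
and notch 50 Hz → band-pass 1–50 Hz → 4-s segments → resample 200 Hz →
per-channel per-epoch z-scoring (discrete-style).  The z-scoring
interpretation of "normalization" is per (epoch, channel) trace; constant
traces map to zeros.  Artifact removal (EOG regression, ICA) is out of
scope: inputs are assumed artifact-reduced, as dataset-provided cleaned
channels usually are.

## The synthetic-EEG generator

`generate_synth()` builds labelled epochs whose class structure matches the
assumptions the interpretability claims rest on: each class may plant a
narrow-band oscillation on a named subset of electrodes, added to a
background of pink noise (power ∝ 1/f, spectral synthesis, unit variance)
plus white noise (SD 0.5), with optional 50 Hz line interference and
broadband high-frequency bursts (both off by default, so the filters are
exercised separately).  The oscillation's centre frequency is re-drawn
uniformly within the class band for every epoch and its phase is random —
a correct model must therefore learn a *band-pass*, not a single tone.
The generator's manifest records the true band and channels per class, so
recovery can be judged without touching the model.

What it does **not** emulate: volume conduction (a real source projects to
many electrodes with a dipolar pattern, not to a channel subset), inter-
subject variability (all subjects share one generative process), nonstation-
arity, and realistic artifacts.  Passing the recovery experiment therefore
shows that the architecture and interpretability pipeline work *when the
class code is band- and channel-localised*, which is the premise of the
interpretability claims — it does not certify performance on real EEG.

## Validation experiments and problem sizes

**Recovery experiment** (`recovery_experiment()`): 32 channels at 128 Hz,
4-s epochs, 800 epochs (4 subjects × 100 per class × 2 classes); class
"excited" adds an 18–22 Hz oscillation on T7/T8 at amplitude 2.5 µV against
a background SD of ~1.12 (amplitude-to-noise ratio ≈ 2.2); model F1 = 4,
T = 32, D = 2, 4 heads, one block; stratified 8:2 split; 10 training
passes with Adam at learning rate 1e-2 (the compact model on this clean
task trains reliably at this higher rate; at 1e-3 some initialisations sit
on a long plateau).  Dropout is disabled for this experiment: dropout
explicitly optimises a network to keep working when units are deleted —
the very perturbation a kernel-ablation study applies — so training with
it biases the model towards redundant kernels whose individual removal is
uninformative.  Success per seed requires
(a) test accuracy > 85%, (b) at least one temporal kernel with dominant
DTFT frequency in 13–30 Hz, (c) the single-kernel ablation that most
reduces macro AUC belonging to such a beta kernel, and (d) the top-4
absolute-weight channels of that kernel's spatial maps intersecting
{T7, T8}.  The package's own bar is ≥ 80% of seeds; the test suite runs 5
seeds and the acceptance script 6, a scale chosen so the full validation
completes on a single CPU in minutes while keeping the multi-seed
character of the check.

**Fmin sweep** (`fmin_sweep_experiment()`): two classes with
equal-amplitude (1 µV) signatures on the same channels at 28–30 Hz (high
beta) and 34–36 Hz (low gamma), 400 epochs; 2-fold CV per kernel length,
15 training passes.  The band pair is engineered so that only the
full-rate first layer can tell the classes apart: after the first average
pool (pooled rate 32 Hz) both bands alias onto the same ~3 Hz residue,
and both sit near the pool's spectral null with nearly equal gains, so
the post-pool stages see almost identical signals.  A T = 32 kernel
(frequency resolution Sr/T = 4 Hz) separates 29 from 35 Hz; a T = 4
kernel (resolution 32 Hz) cannot, so its accuracy falls toward chance —
demonstrating the `Fmin = Sr/T` rule as a training phenomenon rather
than only an identity.  Worth knowing when extending this experiment: a
deep network is resourceful about side channels — on easier variants
(higher amplitude, non-colliding bands) the short-kernel model recovered
the class from post-pool aliasing or from second-order (ELU-harmonic)
residues, and those routes scale with amplitude squared, which is why
the experiment runs at a deliberately low amplitude.  The remaining
variability is optimisation-side: at this SNR the T = 32 model
occasionally under-converges within the short budget, which narrows (and
in rare seeds inverts) the gap; the acceptance script therefore averages
the sweep over two seeds.

**Statistical machinery**: `wilcoxon_signed_rank()` drops zero differences,
uses exact sign-flip enumeration for n ≤ 12 (valid under tied ranks),
the exact signed-rank distribution for untied n ≤ 25, and the normal
approximation with continuity correction beyond; `delong_test()` implements
the fast DeLong construction (midrank placements; one-vs-rest with
Bonferroni for K > 2) and is cross-checked in the tests against an O(n²)
pairwise oracle and against an independent reference implementation
(pROC), plus a 1000-replicate null calibration of its rejection rate.

## Interpretability conventions

* Kernel spectra are the DTFT magnitude on a 512-point grid up to Nyquist;
  the dominant frequency is the argmax above 0.5 Hz.  Band edges are fixed
  at delta [0,4), theta [4,8), alpha [8,13), beta [13,30), gamma [30,50);
  a kernel is "broadband" when the spectral flatness of its power response
  exceeds 0.5 (or its dominant frequency exceeds 50 Hz).  Frequencies below
  1 Hz fall into the delta label.
* "Removing" a temporal kernel means zeroing its weights *and* the matching
  first-stage batch-norm scale and shift, so the branch is exactly silent
  downstream; evaluation is retraining-free and the input model object is
  never mutated.  Removing every kernel leaves logits constant, hence
  one-vs-rest AUC exactly 0.5 — a useful chance-floor identity.  The
  ablation table's "Average" column is the row-wise mean of per-class AUCs.
  Ablation tables are conventionally computed on the full provided epoch
  set.
* Gaussian similarity is a bounded nonlinear least-squares fit of
  `a·exp(−(t−t0)²/(2σ²))` (t0 initialised at the kernel's centre of
  absolute mass, σ at T/6), reporting σ, the magnitude reduction `1/|a|`
  relative to a unit-peak Gaussian, and the Pearson correlation between
  kernel and fit.  Gaussian-like low-pass kernels emerging in the first
  layer act as learned noise-suppression filters.
* Montage coordinates (for topography reports) are idealised 2-D positions
  computed from each 10-10 label's row and lateral index on a unit disc;
  they are adequate for numeric reports and channel ranking, not for source
  analysis.

## Numerical choices and degenerate inputs

Batch-norm and layer-norm use eps = 1e-5.  Softmax rows are max-shifted
before exponentiation.  Cross-entropy clamps probabilities at 1e-12; a
non-finite loss aborts training with diagnostics rather than continuing
silently.  Pooling truncates a trailing remainder that does not fill a
window (and the positions lost this way receive zero gradient).  Constant
traces z-score to zeros; zero kernels get a "broadband" spectrum label with
a warning and an undefined dominant frequency; a degenerate DeLong variance
(identical scores) reports z = 0, p = 1; an all-zero set of paired
differences reports p = 1.  Epoch labels are 0-based integer codes into an
ordered class-name vector; epoch windows are half-open.

A structural caveat discovered by this experiment and worth stating: when
the synthetic task is easy enough that held-out AUC saturates at 1.0, the
network sometimes learns *several* kernels tuned to the planted band, and
removing any single one leaves AUC unchanged — the per-kernel ablation
ordering is then uninformative (ties at zero), even though the band and
channels are plainly recovered in the kernel spectra and topographies and
a *group* ablation of all band-matched kernels collapses AUC to chance.
The per-seed success flags report this honestly rather than paper over it;
the group-level drops are part of the experiment's output.

## Protocol caveats and known limitations

Segment-level stratified k-fold on subject-dependent data lets epochs of
one subject appear on both sides of a fold — the conventional protocol for
these benchmarks, mirrored here deliberately; `losocv()` is the protocol
without that leakage and is the one that measures generalisation to unseen
people.  `hyperparameter_search()` uses uniform random search over the
integer ranges (a stand-in for tree-structured Parzen estimation; with
tens of trials on these small spaces random search is a close substitute).
The multiclass "average AUC" is macro one-vs-rest.  The training engine is
single-threaded and CPU-bound; it is sized for compact configurations
(tens of thousands of parameters), not for large-scale model development.
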