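---
title: "Models and methods behind fvepnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fvepnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fvepnet` classifies flash visual evoked potential (FVEP) sweeps as normal
or retinitis-pigmentosa (RP) and simultaneously decides whether a sweep
belongs to either class at all. This vignette documents the models, the
assumptions behind them, the tunable parameters, and the design choices
that were genuinely open — in enough detail that a maintainer can judge
what the test suite does and does not establish.

## The sweep and its synthetic model

A sweep is 320 samples at 1000 Hz: 20 ms pre-trigger baseline plus 300 ms
post-trigger response, in microvolts. The canonical adult waveform is a
sequence of deflections N1, P1, N2, P2, N3, P3; clinical RP reading keys on
the P2 wave, whose **amplitude is reduced while its peak time is
unchanged**.

Clinical FVEP recordings cannot be redistributed, so the package ships a
generator (`simulate_fvep()`) that reproduces the *study design* rather
than any particular patient: every synthetic patient contributes exactly
four sweeps (left and right eye, twice each) and a patient-level age drawn
uniformly from 4–88 years. Each sweep is a sum of Gaussian bumps — latency
= mean, one width parameter per component — which is the simplest smooth
unimodal shape; the default latencies (45, 75, 105, 135, 180, 220 ms) and
amplitudes (−3, 4, −4, 8, −5, 5 µV) are configurable conventions, not
claims about any population. On top of the clean waveform:

* **patient-level variability**: a common latency shift (SD 5 ms) and a
  log-normal amplitude scale (SD 0.15) shared by a patient's four sweeps,
  so within-patient sweeps correlate more than between-patient sweeps — a
  property the tests assert;
* **record-level nuisance**: white Gaussian noise (SD 1 µV by default,
  optionally band-passed 0.312–100 Hz to mimic the acquisition filter),
  slow sinusoidal drift (0.5 µV, 0.5–1.5 Hz), and a per-record constant
  baseline offset (SD 1.5 µV) representing residual offset that survives
  high-pass filtering and averaging;
* **the RP contrast**: the P2 amplitude is multiplied by
  `rp_p2_attenuation` (default 0.5) with its latency untouched, and all
  other components by the milder `rp_secondary_attenuation` (default
  0.75). The secondary factor reflects that generalized retinal
  dysfunction shrinks the whole cortical response, with P2 the most
  prominent marker; setting it to 1 recovers a strictly P2-only contrast.
  Together with the baseline offset this makes peak-to-peak amplitude —
  a baseline-invariant measure — the strongest single correlate of the
  label among the signal features, matching its clinical standing; the
  feature tests assert exactly that ranking;
* **out-of-distribution sweeps** ("abnormal"): one of three subtypes per
  patient — all component latencies shifted by 30–60 ms, a near-flat
  response (amplitudes × 0.02–0.08), or a noise-dominated sweep (noise SD
  inflated 5–10×). The subtype mixture is config-exposed.

All randomness flows from one seed; per-record substreams are derived
deterministically from (seed, patient, eye, repeat), so datasets are
reproducible record for record. Because the generator is built from
Gaussian bumps, passing tests demonstrate that the *method* behaves as
claimed under the stated contrasts — they cannot certify performance on
real cortical potentials, whose component shapes, artefact structure and
label noise are richer.

## EMD denoising

`emd_decompose()` implements standard empirical mode decomposition:
upper/lower envelopes are cubic splines through the local extrema
(mirror-extended by up to two extrema at each boundary, the dominant
convention), the envelope mean is subtracted, and sifting stops when the
normalized squared envelope mean between successive sifts drops below
0.2 (at most 50 sifts per IMF); extraction stops when the remainder has
fewer than three extrema or 10 IMFs have been produced. The
completeness identity — IMFs plus residual reconstruct the input to
floating-point accuracy — holds by construction and is asserted over
hundreds of random signals. `emd_denoise()` keeps IMF3–5 by default
(residual excluded; the residual does not count in the IMF indexing),
which suppresses both high-frequency noise (IMF1–2) and slow drift.
Denoising is *not* idempotent (EMD is not a projection) and is therefore
an optional preprocessing flag in training (default off), since the
method's description places it under acquisition rather than model
fitting. Whether denoised or raw sweeps should feed the network is left
as a config decision for the user.

## Feature engineering

`extract_features()` computes a representative catalogue per domain —
temporal (lag-1 autocorrelation, mean absolute first difference, sample
entropy with m = 2, r = 0.2·SD), statistical (max, min, median, mean, SD,
IQR, 10-bin histogram counts over the per-record range, peak-to-peak),
spectral (FFT mean coefficient magnitude, spectral centroid, band power,
level-3 Haar wavelet detail energies) — plus age. It deliberately does not
reproduce any external feature library's full catalogue. Selection is
variance filtering (threshold 0: drop constants) followed by Pearson
correlation against the binary label (default |r| ≥ 0.1; a zero-variance
column has correlation defined as 0). Both filters are frozen on the
training split only and then applied to test data, preventing selection
leakage.

The 7-element manual vector fed to the network is a reconstruction — the
exact clinical feature set is not documented beyond peak-to-peak and age —
and is config-overridable: peak-to-peak amplitude; maximum amplitude in a
configurable P2 window (default 100–180 ms post-trigger, since expert P2
marking is unavailable; argmax ties break to the first sample); that
maximum's latency; SD; median; mean absolute first difference; age.

## The network

Three branches are concatenated and fused:

| branch | structure | output |
|---|---|---|
| global | one conv layer, kernel length T = 320, 64 filters, ReLU | 64 |
| local | (conv 5×64 → ReLU → max-pool 2) → (conv 3×64 → …) → (conv 3×64 → …), flatten | 38 × 64 = 2432 |
| manual | dense 128, ReLU over the 7 features | 128 |

All convolutions are stride-1, valid (no padding) — this is what makes the
length-320 global kernel produce exactly one scalar per filter. The fusion
layer is dense-128 with ReLU (width chosen to match the manual branch; the
architecture description leaves it open) and feeds two heads: softmax over
M = 2 classes and a sigmoid confidence scalar. No dropout or batch
normalization is used in this architecture (they are described only for
baseline models elsewhere). The local branch flattens rather than
global-average-pools, which is reserved for a different baseline design.
Weights are initialized He-style uniform (±√(6/fan-in)) under the run
seed. The fusion activations (the penultimate embedding) are exposed for
the feature-space OOD detectors.

The forward and backward passes are hand-written; the hot primitives
(valid/transposed convolution, fused conv-ReLU-pool stages) are
Rcpp/RcppArmadillo, exploiting that each convolution tap's im2col block is
a contiguous memory slab, so a convolution is k memcpys plus one BLAS
gemm. Every gradient is verified against central finite differences in the
tests, and the compiled primitives against pure-R reference
implementations.

## The loss

With softmax output p and confidence c, a random `hint_fraction` (default
0.5) of each batch is hinted: p̂ = c·p + (1 − c)·y. The focal term is

L_t = −Σ_i [ y_i (1 − p̂_i)^γ log p̂_i + (1 − y_i) p̂_i log(1 − p̂_i) ],

γ = 2 (the canonical focusing value; the source description leaves γ
unstated). Note the negative-class term carries *no* γ exponent in this
form; whether that is intentional is unknowable from the description
alone, so both behaviours ship — `symmetric_gamma = TRUE` switches to the
standard p̂^γ form — with the as-printed form the default. The confidence
penalty is L_c = −log c (natural log throughout) and the total is
L = mean(L_t) + λ·mean(L_c) with λ = 0.1 fixed (the adaptive-budget
variant of the original confidence-branch method is deliberately not
used; λ is config-exposed). Probabilities are floored at 1e-12 inside
logarithms.

Partial hinting matters: with all-batch hinting the network can trade c
against the focal term too cheaply; with none, c receives no gradient
from the classification task. Half-batch hinting is the established
middle ground and `hint_fraction = 1` recovers always-hinted behaviour.

**Numerical stability.** Hinting decouples p̂ from the softmax, so the
1/p̂ factor in the focal gradient is no longer cancelled by the softmax
Jacobian; a saturated wrong prediction can produce per-record gradients of
order 1/ε. At the stated learning rate this can kill the confidence head
in one step. Minibatch gradients are therefore clipped to a global L2 norm
of 5 (config `clip_norm`, `Inf` disables) — a standard safeguard, and the
only numerical intervention in the training loop.

## Training protocol

Splits are **patient-grouped**: 70 % of normal and RP patients train,
30 % test; the abnormal pool splits 30 % train / 70 % test. All four
sweeps of a patient land on one side, and a leakage guard inside the
training loop aborts if any test patient could reach a gradient step.

Optimization is plain SGD with momentum 0.9 (Adam available by config),
learning rate 0.01, batch size 128, 50 epochs, and the epoch snapshot with
the **lowest training loss** is returned — exactly as the protocol states,
even though validation-based selection would be more orthodox; a config
switch (`select_best = "final"`) is provided. Sweeps are standardized by
the training pool's global mean/SD and manual features z-scored with
training-split statistics (age in years and amplitudes in µV differ by an
order of magnitude; without this the manual branch drowns).

**Pretraining.** `pretrain_autoencoder()` builds an encoder with exactly
the local-branch structure and a mirrored decoder (nearest-neighbour
upsampling by 2 + transposed convolutions 3/3/5, then a 1×1 linear
convolution back to one channel — the mirror convention, since the decoder
is otherwise unspecified) and trains it on reconstruction MSE over an
unlabelled sweep pool at lr 0.001 (0.01 diverges on this objective). The
encoder weights then initialize the local branch, which fine-tunes at lr
0.001 while all other parameters use 0.01 — two optimizer parameter
groups. Pretraining is the *only* switch distinguishing the pretrained
variant from the baseline variant of the model.

**Abnormal exposure.** The confidence-based OOD method has access to the
abnormal training split. How those records enter training is not specified
beyond being "needed"; this package's interpretive choice is an auxiliary
loss −log(1 − c) on abnormal-class records (weight 1.0, config-exposed),
pushing their confidence toward 0 without ever touching the class head.
With no abnormal training records the loss reduces to plain confidence
training.

## OOD detection

All five detectors emit scores oriented **higher = more anomalous**:

* **confidence**: score = 1 − c;
* **entropy**: Shannon entropy of p (training-free baseline);
* **LOF** (k = 20), **one-class SVM** (RBF, ν = 0.1), **MCD** (robust
  Mahalanobis distance from the minimum-covariance-determinant estimate)
  fitted on the penultimate embeddings of in-distribution training
  records. "The last fully connected layer" is read as the
  post-concatenation fusion layer. Near-constant embedding dimensions
  (dead ReLU units) are dropped before fitting; the MCD additionally
  drops zero-IQR coordinates and falls back to the classical covariance
  when the sample is too small for a stable determinant search in that
  dimension, with a small ridge for invertibility.

Decision thresholds maximize F1 over **training-split** scores (grid over
observed values); test metrics are computed at that frozen threshold, with
OOD as the positive class. Hyperparameters for the classical detectors are
config keys; none are prescribed by the method description.

## Evaluation

`confusion_metrics()` computes TP/FP/FN/TN with accuracy, precision,
recall, F1 (zero denominators report 0 with a warning flag), and
`auc_score()` is the rank-based Mann–Whitney statistic with midranks for
ties. For classification, "normal" is treated as the positive class — the
convention is not stated in the protocol, but the reported recall values
against a normal-majority dataset are only consistent with this reading;
it is a config argument, not an assertion. OOD metrics treat
out-of-distribution as positive.

## Problem sizes used by the test suite

The acceptance-style tests train on 200 labelled synthetic patients (100
normal, 100 RP; 25 abnormal patients for exposure and OOD evaluation),
P2 attenuation 0.5 and noise SD 1 µV, for 50 epochs across five seeds;
component-level oracles run on hundreds of random instances. These sizes
were chosen as the smallest at which the statistical properties under test
(patient-held-out accuracy over majority, detector orderings) are stable
across seeds.

## Known limitations

* The generator's Gaussian-bump waveforms and three OOD subtypes are far
  simpler than clinical reality; results on synthetic data bound what the
  pipeline can do, not what it will do in a clinic.
* The exact identity of the original 7 manual features, the Pearson and
  variance thresholds, the fusion width, γ, λ, and the hinting rule are
  undocumented in the protocol this package follows; all defaults here are
  reconstructions, flagged as such and config-exposed.
* EMD's IMF indexing is data-dependent: low-noise sweeps may decompose
  into fewer than five IMFs, in which case the IMF3–5 selection falls back
  to the available components with a warning.
* Model selection by training loss can overfit relative to
  validation-based selection; it is kept for fidelity and switchable.
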