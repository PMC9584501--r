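---
title: "Attention-modulated Chebyshev graph convolution for motor-imagery EEG: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-modulated Chebyshev graph convolution for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcnn)
```

## The problem

Motor imagery — mentally rehearsing a movement without executing it —
modulates the power of sensorimotor rhythms (mu, ~8–13 Hz; beta, ~14–30 Hz)
over class-specific scalp regions. Decoding which movement a subject
imagined from multichannel EEG is the core task of non-invasive
brain–computer interfaces. EEG electrodes do not live on a Euclidean grid:
their scalp layout is better treated as a graph, and the discriminative
signal is jointly spatial (which electrodes), spectral (which band) and
temporal (when during the trial). This package implements a dual-branch
graph convolutional classifier that models all three dimensions at once,
with learned attention reweighting the coupling between electrodes and
between time/frequency steps.

## Model

### Electrode graph and spectral operators

A montage assigns each electrode a cell on an integer grid
(`montage()`, `read_montage()`). Two electrodes are adjacent when their
cells differ by at most one in both row and column (Chebyshev grid distance
1), so an interior electrode has the 8 natural neighbours; every node is
also self-connected, giving a binary adjacency $A$ with unit diagonal.
From $A$ we form the degree matrix $D$, the symmetric normalized Laplacian
$L = I - D^{-1/2} A D^{-1/2}$ (spectrum in $[0, 2]$), and the rescaled
$\tilde L = 2L/\lambda_{\max} - I$ (spectrum in $[-1, 1]$). Spatial
filtering uses the Chebyshev polynomial stack
$T_0(\tilde L) = I,\; T_1(\tilde L) = \tilde L,\;
T_k = 2 \tilde L T_{k-1} - T_{k-2}$, which evaluates a degree-$K$ spectral
filter without any eigendecomposition; the eigendecomposition appears only
as an independent test oracle.

$\lambda_{\max}$ is computed exactly by a symmetric eigensolver rather than
approximated by 2: montages have at most a few dozen electrodes, so
exactness is essentially free. Electrodes with no grid neighbour are legal;
their self-loop normalizes their Laplacian row to zero, and they simply do
not exchange information in the graph step.

### Representations

Each trial $X \in \mathbb R^{N \times T}$ becomes two graph tensors:

* **spatial–temporal** `to_spatial_temporal()`: the time axis resampled to
  $T$ steps (default 100). The resampler is Fourier-domain (band-limited),
  since naive decimation of a 250 Hz trial to 100 steps would alias beta
  band activity; plain decimation is available as a configuration choice
  for comparison. No DSP package is assumed, so the band-limited route is
  implemented directly on the FFT.
* **spatial–spectral** `welch_psd()`: per-electrode Welch power spectral
  density — mean-detrended, Hann-tapered segments (default length
  $\min(256, T_{\text{samples}})$, 50 % overlap) — pooled by averaging into
  $F$ equal-width bins (default 100 bins spanning 0.5–50.5 Hz, covering
  delta through low gamma). Bins narrower than the Welch resolution are
  filled by linear interpolation at the bin centre. These Welch defaults and
  the band are package choices: the source protocol fixes only $F = 100$.

Per-trial, per-electrode z-scoring is applied by default before either
representation, removing trial-level amplitude offsets; it is toggleable.

### Attention

For input $x \in \mathbb R^{N \times L \times C}$ the raw spatial attention
is a factored bilinear form: both factors contract channels with a learned
weight vector and pass through $\tanh$, and their product gives an
$N \times N$ association-intensity matrix (`pairwise_attention()`);
the temporal/spectral version transposes the contraction to give
$L \times L$. Rows are then normalized to unit Euclidean norm
(`l2_normalize_rows()`), so every node's (or step's) outgoing attention has
unit energy; all-zero rows pass through unchanged. Row-wise normalization
is a deliberate reading of an ambiguous normalization: it matches the
intra-region-compactness motivation for preferring L2 over softmax, and a
global-norm alternative would only rescale the whole matrix.

The published formulation gives the attention biases full
$N \times T$ shape. This package uses shared scalar biases instead: full
matrices would tie the parameters to one fixed montage and break node
permutation equivariance, which the test suite asserts (permuting
electrodes everywhere leaves class probabilities unchanged).

### The two branches

Each branch applies, in order:

1. **Attention-modulated graph convolution** (`attn_graph_conv()`):
   $x_1 = \mathrm{ReLU}\big(\sum_{k=0}^{K} (T_k(\tilde L) \odot a'_s)\, x\,
   \theta_k\big)$, where $\odot$ is the element-wise product and each
   $\theta_k$ is a $C \times C_1$ channel map — the standard ChebNet
   generalization of scalar Chebyshev coefficients, needed because the
   output has $C_1$ channels. Attention multiplies **every** polynomial
   order, including the $k = 0$ identity term: modulation is a uniform
   reweighting of the propagation structure.
2. **Attention-modulated temporal/spectral convolution**
   (`temporal_spectral_conv()`): the step axis is contracted with $a'_t$,
   then a $(1, 5)$ stride-1 convolution with $C_2$ filters and ReLU is
   applied with valid padding, so $L_2 = L - 4$ and the node axis is
   untouched.
3. **Global feature aggregation** (`global_aggregate()`): an $(N, 1)$
   kernel collapses nodes, then a $(1, L_2)$ kernel collapses steps; both
   ReLU-activated, yielding a length-$C_2$ branch descriptor. Valid padding
   is what makes these kernels collapse each axis exactly.
4. **Shortcut**: the branch input, averaged over nodes and steps and passed
   through a learned $C \times C_2$ linear map, is added to the aggregated
   feature. The residual connection is underdetermined in the source
   description; the global-mean-plus-projection form is the minimal
   shape-consistent choice and is stated here as a package design decision.

The two branch features are concatenated and passed through one fully
connected layer and softmax. A single FC layer over the concatenation
subsumes the per-branch weight blocks of a weighted-sum fusion, reconciling
the two fusion descriptions in the source.

### Training

Minibatch Adam (learning rate 0.001, batch 64 by default) minimizes mean
cross-entropy. Forward and backward passes are hand-written in base R (no
deep-learning framework exists in the target environment); the backward
pass is verified against central finite differences to a relative error
below $10^{-4}$ for every parameter of every ablation variant. ReLU-layer
biases initialize at 0.01 rather than 0: with dead inputs a zero bias puts
pre-activations exactly on the ReLU kink, where subgradients and finite
differences legitimately disagree, and the small positive offset also keeps
units alive early in training. Weights are Glorot-uniform, seeded.

All randomness derives from one master seed through named substreams
(`derive_seed()`), so changing, say, the augmentation settings does not
perturb weight initialization; identical config + seed reproduces an
identical cross-validation result bit for bit.

### Evaluation protocol

`cross_validate()` performs stratified 5-fold cross-validation on **source**
trials. Augmentation — sliding windows (the in-protocol 2 s window /
0.32 s step quadruples 3 s trials) or SNR-parameterized white noise —
is applied only inside each training fold, and fold membership follows
`trial_id`, which every augmented segment inherits. The source protocol
does not state whether augmentation preceded the split; split-then-augment
is enforced here because the alternative leaks segments of held-out trials
into training. Metrics are accuracy and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$; the degenerate $p_e = 1$ case returns 0
with a warning.

## Synthetic data: what it does and does not establish

`synthetic_spec()` / `generate_trials()` produce band-limited oscillatory
trials: per-electrode $1/f^{\alpha}$ pink background (spectral shaping of
white noise, $\alpha = 1$) plus white sensor noise, and a class-specific
amplitude-modulated sinusoid (random phase, 0.5 s linear on/off ramp
mimicking event-related desynchronization timing) on a class-specific
electrode set. The default "easy" task is a 3×3 montage, two classes with
disjoint 3-electrode active sets, carriers at 10 Hz and 22 Hz (mu vs beta),
3 s trials at 250 Hz, and carrier amplitude 2 against a unit-variance pink
background (white noise σ = 0.5).

This emulates the spatial-spectral contrast motor-imagery decoding
exploits, and nothing more: there is no volume conduction, no head model,
no artifacts, no non-stationarity beyond the envelope, and no
between-subject variability. A green learnability test therefore
establishes that the architecture, gradients, training loop and protocol
work end to end and that attention + aggregation help on a task with
genuine spatial-spectral structure — it does not establish the published
benchmark accuracies, which require the four external datasets and are out
of scope.

## Numerical and interface choices

* Fourier resampling preserves constants exactly and is the identity when
  the target length equals the input length.
* `welch_psd` output is clamped at 0 (interpolation could otherwise
  produce tiny negative values) and satisfies a Parseval-style check:
  integrated PSD ≈ signal variance within 20 % for white noise.
* Chebyshev stacks, adjacency and operators are plain dense matrices:
  montages are small ($N \le 64$), sparsity would add complexity for no
  measurable gain.
* Containers: trial sets, tensors and model weights serialize to RDS, and
  configurations to JSON, because the target environment provides no HDF5
  or YAML bindings; the field contracts (signals/labels/trial_ids/fs, CV
  result JSON, loss CSV, prediction CSV) are unchanged. EDF/GDF ingestion
  is omitted for the same reason — the RDS container plus the synthetic
  generator cover every supported path.
* The CLI (`cgcnn_cli()`, wrapper in `inst/cli/cgcnn`) chains
  simulate → preprocess → train → evaluate → predict, logs the resolved
  configuration next to each artifact, and rejects unknown configuration
  keys.

## Known limitations

* Pure-R training is CPU-bound: the default 64-channel, $T = F = 100$
  configuration is practical for small studies but slow for dataset-scale
  work; the learnability tests use a scaled-down model (8 channels, 32
  steps) for exactly this reason.
* The exact electrode grids used for the published datasets are not
  public; shipped montages (e.g. the 22-electrode layout) are labelled
  reconstructions, so per-subject published numbers are not exactly
  recoverable even with the original data.
* Only the fixed 8-neighbourhood montage graph is supported — no
  functional-connectivity or learned adjacency.
* Cross-subject generalization is explicitly out of scope.
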