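---
title: "Reconstructing natural images from fMRI with node-edge interaction graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing natural images from fMRI with node-edge interaction graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neirecon)
```

## The problem

Visual image reconstruction asks: given the fMRI activity a person's visual
cortex produced while looking at a natural image, recover the image itself.
The recordings are voxel activation vectors from seven regions of interest
(ROIs) — V1, V2, V3, V4, LOC, FFA and PPA — with unequal voxel counts per
region. Classical decoders concatenate all voxels into one long vector and
ignore that the regions talk to each other; this package models that
communication explicitly.

## The model

**Graph construction.** Each ROI's (zero-padded) voxel vector is one node of
a fully connected graph over regions. Edge values are initialized as
functional connectivity, the cosine of the two region signals:

$$C_{ij} = \frac{F_i \cdot F_j}{\lVert F_i\rVert_2\,\lVert F_j\rVert_2 + \varepsilon},
\qquad \varepsilon = 10^{-8}.$$

**Node-edge interaction block.** One block performs two layers in sequence.
The edge-to-node layer aggregates every node (self included) with edges as
weights, $N_i' = \sum_j E_{ij} N_j$. The node-to-edge layer updates each
edge from its two (updated) endpoints and all edges incident to either,
fused by learnable parameters: a weight vector $w_i$ per ROI (dotted with
$N_i'$) and a scalar $w_{ij}$ per edge. No nonlinearity is applied inside
the block. Stacking $K$ blocks lets information travel $K$ hops; each block
owns its own parameters. $K = 2$ is the default; $K = 0$ (a pass-through)
up to $K = 4$ are exposed for ablation.

**Decoder.** The post-graph node vectors are concatenated (ROI-major, length
$R \cdot D$) and decoded by a multi-stage reconstruction network: a linear
block to a $14 \times 14 \times 64$ seed tensor, then three blocks of
(nearest $\times 2$ upsample, $5\times5$ same-padded convolution to 64
channels, group normalization with 8 groups, swish). Four heads
($5\times5$ convolution to 3 channels + sigmoid) tap the trunk after each
stage, emitting reconstructions at 14, 28, 56 and 112 pixels. The 112
output is the reconstruction; the coarser heads exist to constrain
training from global structure to local detail.

**Encoder.** A separate encoder maps an image to an estimated fMRI
response: a frozen four-branch feature backbone (feature maps at
112/56/28/14 pixels), per-branch processing (3x3 spatial convolution +
ReLU, 1x1 channel-mixing convolution), flattening without global pooling,
and one linear fusion layer onto the flat fMRI vector, with padded
positions masked to zero. The built-in backbone is a small fixed-seed
random convolutional net honouring the same four-branch contract as a
pretrained VGG-style hierarchy; it keeps the package self-contained and
deterministic, and doubles as the perceptual-loss feature extractor and
the test-profile embedding backend.

## Training

Stage 1 fits the encoder on image/fMRI pairs with
$L_{enc} = L_{MSE} + L_{CosSim}$, where the cosine term is the negative
cosine of the flat vectors. Stage 2 freezes the encoder and fits the graph
blocks plus reconstruction network with two branches per step:

* supervised — real fMRI $\to$ connectivity $\to$ $K$ blocks $\to$ decoder,
  against the stimulus pyramid;
* self-supervised — unlabeled image $\to$ frozen encoder $\to$ estimated
  fMRI $\to$ the same decoding path, against the unlabeled image's own
  pyramid (the stacked autoencoder).

Both branches share the loss composition
$L = L_{MAE} + L_{Per} + \lambda_{TV} L_{TV}$, with MAE and TV applied on
every constrained scale and the perceptual term (mean negative cosine
between backbone feature vectors at every spatial position, averaged per
layer and over layers) applied at the 112 scale only. At test time the
encoder plays no role: real (repeat-averaged) fMRI is decoded directly.

## Numerical and design choices

* **Padding.** ROI vectors are tail-padded with exact zeros (masks
  recorded), so cross-region dot products are unaffected; every
  normalization guards its norms with $\varepsilon = 10^{-8}$ rather than
  relying on non-zero padding.
* **Cubic pyramid.** Downsampling uses a separable Catmull-Rom kernel
  ($a = -0.5$) in the align-corners = FALSE convention with the kernel
  support widened by the scale factor (anti-aliasing) and border
  replication; outputs are clipped to $[0, 1]$.
* **TV weight** $\lambda_{TV} = 0.002$. The total-variation term is a raw
  sum over pixel pairs, so a faithful reconstruction of a smooth stimulus
  carries a TV of order $10^2$ while the whole MAE range is of order 1.
  With every weight at 1 the flat mid-gray image is the global optimum of
  the decoder objective and training demonstrably collapses to it;
  0.002 calibrates the regularizer so that a faithful fit attains a lower
  objective than the flat solution while TV still suppresses pixel noise.
  All weights remain configurable (`loss_config(term_weights = ...)`).
* **Smooth linear-block initialization.** The linear block's projection
  rows are drawn on a coarse 4x4 grid per channel and cubically
  interpolated across the 14x14 seed map (Xavier scale). An iid
  initialization starts the decoder with spatially white outputs whose TV
  dwarfs every other term; scaling the output heads toward zero instead
  parks the network at a saddle (gradients into the trunk are multiplied
  by the near-zero head weights). The spatially correlated initialization
  starts in the smooth regime with full gradient flow.
* **Optimization.** Adam throughout; decoder learning rate 1e-3, encoder
  1e-4. The encoder's flattened branch concatenation is ~47k-dimensional,
  and Adam's coordinate-normalized steps scale with the l1 norm of the
  input features: at 1e-3 stage 1 overshoots by orders of magnitude, at
  1e-4 it descends cleanly.
* **Group normalization** uses 8 groups (the group count must divide the
  64-channel trunk width); upsampling is nearest-neighbour.
* **RGB conventions.** Images are RGB in $[0, 1]$ everywhere. MAE averages
  over channels; TV is computed per channel and summed; the perceptual
  cosine runs over channel vectors at each spatial position with
  per-layer spatial normalization (layers differ in spatial size, so a
  single global normalizer is ill-defined).
* **Ties.** In the n-way identification protocol a reconstruction passes
  a trial when its similarity to the true stimulus is at least as optimal
  as to every distractor; exact ties pass. SSIM uses the standard
  11x11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03 at data range 1,
  averaged over channels and valid window positions.
* **Test repeats** are averaged before decoding by default (the
  conventional choice for repeated test presentations); per-trial
  decoding is available via `reconstruct_trials()`.

## The synthetic study generator

`generate_study()` emulates the structure of a generic-object-decoding
experiment at desk scale: 64 training images presented once, 10 test
images with 5 repeats each, 32 unlabeled images, and seven ROIs with
voxel counts (20, 24, 18, 16, 12, 14, 8). Stimuli are smooth random
fields (coarse Gaussian latents, cubically upsampled, logistic-squashed
into $(0,1)$). Each ROI's response is a fixed random linear map of the
stimulus's 14x14 pyramid level plus Gaussian noise whose per-ROI variance
sets Var(signal)/Var(noise) to the requested SNR (default 1.0, a
favourable regime; the printed subject-level SNRs of real recordings are
an order of magnitude lower and are exercised in the SNR sweep). The
ground-truth map is returned for recovery tests.

What the generator does *not* emulate: hemodynamics, nonlinear encoding,
voxel correlations beyond the shared linear drive, semantic category
structure, or natural image statistics. Passing tests therefore
demonstrate that the pipeline recovers a known smooth linear forward model
— a necessary, not sufficient, condition for performance on real
recordings.

The SNR estimator divides the across-stimulus variance of repeat means by
the mean within-stimulus variance, after subtracting the
$\sigma^2/m$ inflation of the repeat means ($m$ repeats); without the
correction the estimator converges to SNR + $1/m$ rather than the SNR.

## Problem sizes

All defaults are desk-scale choices so that the complete seeded pipeline
(simulate, two training stages, reconstruction, evaluation) finishes in
minutes on a single CPU: encoder 10 epochs at batch 8; decoder 10 epochs
at batch 4 with a balanced self-supervised batch of 4 and a 16-channel
trunk. The 64-channel trunk is the reference configuration
(`recon_net_params()` default, parameter count asserted in tests), but at
desk scale one 64-channel optimization step costs seconds of CPU and the
~160 steps the decoder needs to generalize would not fit an interactive
budget; the narrow profile reaches the same qualitative behaviour in
minutes, and width is a single configuration switch
(`train_config(channels = 64)`). Scaling up epochs, widths and study
sizes is a matter of configuration, not code.

## Known limitations

* The built-in backbone is a random feature hierarchy, not a pretrained
  one; absolute reconstruction quality on real data would benefit from a
  pretrained backbone plugged into the same contract.
* The graph is dense over 7 ROIs; no sparse representation is provided.
* The forward model in the generator is linear; decoder capacity beyond
  the linear regime is not exercised by the synthetic studies.
* Single-precision/GPU execution is out of scope; all computation is
  double-precision CPU.
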