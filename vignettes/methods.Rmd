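---
title: "Decoding visual semantics from EEG: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual semantics from EEG: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdecode)
```

## The problem

A participant views a rapid stream of natural images while 64-channel EEG is
recorded. Can the semantic content of the viewed image be recovered from a
single averaged EEG response - for categories the decoder has never seen?
`eegdecode` implements a two-stage answer:

1. **Contrastive alignment.** An EEG encoder maps each trial
   (channels x time) into the embedding space of a pretrained image encoder.
   Training pulls each EEG embedding toward its paired image embedding and
   pushes it away from the other pairs in the batch (symmetric InfoNCE).
   Zero-shot decoding is then n-way retrieval: rank candidate image
   embeddings by cosine similarity to the EEG embedding.
2. **Diffusion prior.** Raw EEG embeddings live slightly off the image
   manifold, which hurts downstream generation. A denoising diffusion model
   on embedding vectors, conditioned on the EEG embedding via classifier-free
   guidance, translates them into clean image-embedding space before an
   image generator consumes them.

Everything runs at desk scale on one CPU: pretrained vision backbones and
latent-diffusion image generators are replaced by a synthetic data generator
and a toy linear decoder with an identity feature extractor, so the package
tests the *machinery* - objectives, architectures, protocols, metrics - not
the absolute numbers that require the real recordings and pretrained weights.

## The synthetic data generator

`make_concept_bank()` draws unit-norm concept vectors (one per stimulus
category) in image-embedding space, grouped into clusters that later share
broad semantic tags. A disjoint train/test category split enforces the
zero-shot structure. Image embeddings of individual exemplars are
`normalize(concept + sigma_img * eta / sqrt(D))`; `sigma_img` (default 0.1)
is the expected norm of the exemplar perturbation, independent of the
embedding dimension.

`make_forward_model()` fixes how a concept becomes an EEG trial: the concept
is projected to `r = 8` source coefficients through a fixed Gaussian matrix,
sources radiate along unit-norm smooth temporal waveforms into channels with
unit-norm spatial loadings, and the six posterior channels (O1, O2, Oz, PO3,
PO4, POz) are scaled by `posterior_boost` before i.i.d. Gaussian sensor noise
of SD `noise_sd` is added. Because loadings are unit-norm, a posterior
channel carries exactly `posterior_boost^2` times the expected signal power
of any other channel - the generator's encoding of the empirical fact that
visual information concentrates over visual cortex, and the lever behind the
perturbation experiment.

Default study conditions (the "scaled" configuration): 100 training
categories x 3 exemplars, 20 test categories x 1 image, 2 subjects, 4
repetitions averaged per image, 17 channels (a 10-10 subset that always
retains the posterior six), 50 samples per trial, `D_img = 16`,
`posterior_boost = 4`, `noise_sd = 1`. The reference configuration mirrors
the full benchmark (1654 train categories x 10 images + 200 test categories
= 16,740 images, 64 channels, 250 samples for 0-1000 ms at 250 Hz) and is
used for structural checks and counting; trials at that scale are not
synthesized in the tests. The preprocessed sampling rate of the original
recordings is not fixed by the protocol description, so 250 Hz is a
configurable choice.

What the generator does **not** emulate: volume conduction from a
biophysical head model, non-stationarity and artifacts, inter-subject
anatomical variability (subjects differ only through noise realizations),
and the heavy-tailed statistics of real EEG. Passing tests therefore show
the pipeline recovers planted structure under the stated conditions - not
that it decodes real brains.

## The EEG encoder

`build_encoder()` assembles, per trial:

sinusoidal time encoding -> a transformer block over the **channel axis**
(channel attention, 1 head) -> two parallel convolutional branches -> fused
token sequence with a second sinusoidal position encoding -> multi-head
self-attention block (5 heads) -> a learned class token cross-attending to
the sequence (8 heads at reference width), added back residually -> flatten
-> fully connected layer (the 1440-D intermediate representation at the
reference configuration) -> per-subject linear map -> residual GELU
projection head into the 1024-D embedding space.

Choices the architecture description leaves open, and what this package
does:

* **Conv geometry.** Each branch owns, per feature map, one spatial pattern
  over all channels and one length-25 temporal kernel ("valid"
  convolution), followed by average pooling. The constructor *solves* the
  pooling stride so the flattened sequence hits `intermediate_dim` exactly
  (40 maps x 36 tokens = 1440 at 64 x 250) and errors, naming the stage, if
  impossible. With such factorized per-map filters the spatial-then-temporal
  and temporal-then-spatial orders are algebraically identical, so the two
  branches are realized as independent factorized stacks and differ through
  their parameters; they are concatenated and linearly fused.
* **Positional encoding** is fixed sinusoidal, applied twice: over time
  samples before channel attention and over tokens before self-attention.
* **The class token's output is added residually** to every token before
  flattening, which keeps the printed 1440 exact rather than growing the
  flattened width.
* **Subject maps initialize to the identity**, so untrained subjects are
  interchangeable and the map only learns per-subject corrections.
* **Dropout** (p = 0.1) lives in the projection head, active only in
  training mode; evaluation is deterministic.

## Contrastive training

Both modalities pass through one-hidden-layer GELU MLP projectors into a
shared space (width = the image-embedding dimension). When a projector's
input and output widths match it carries a residual skip, so it starts out
cosine-preserving. Similarities are scaled by a learned temperature
initialized at `log(1/0.07)` and clamped below `log(100)`; the loss is the
symmetric InfoNCE (EEG-to-image and image-to-EEG cross-entropies averaged) -
the standard two-direction form, adopted because it is the field's
convention for paired-modality alignment.

The optimizer is AdamW with lr `2e-4`, betas `(0.5, 0.999)`; the nominal
batch size 1024 shrinks to the per-subject dataset size on desk-scale data.
Batches are drawn within subject, matching the within-subject evaluation
protocol. Two recipe details matter on small synthetic datasets and are on
by default:

* **Input-noise augmentation** (`augment_sd = 0.3`, relative to the batch
  SD) - the encoder otherwise memorizes the small category set and
  generalizes poorly to unseen categories.
* **Epochs default to 60** (about 600 steps on the scaled dataset), which
  saturates test retrieval there; the reference recipe of 200 epochs x 5
  seeds remains available through `epochs` and `fit_contrastive_seeds()`.

All training runs on the package's own reverse-mode autodiff tape
(`R/autograd.R`): a flat-tape engine over plain matrices with custom
primitives for the conv and blockwise-attention layers. Every backward rule,
and the gradient through the fully assembled encoder and prior, is checked
against central differences in the test suite.

## Zero-shot retrieval

`evaluate_nway()` samples, per trial, a query EEG embedding and `n_way - 1`
distractor images from other unseen categories; the prediction is correct
when the true image has the single highest cosine similarity. Ties count
against the model (conservative reading of "ranked highest"). Distractor
panels are resampled per trial with a seeded RNG (1000 trials by default);
when `n_way` equals the candidate-set size the single deterministic full
panel is evaluated instead. One subtlety the tests encode: chance-level
checks need many *items*, not just many trials, because per-item win rates
have high variance under a fixed finite embedding set.

## The diffusion prior

A cosine schedule `alpha_bar(t) = f(t)/f(0)`, `f(t) =
cos^2(((t/T + s)/(1+s)) pi/2)` with `s = 0.008` and `T = 1000` defines the
forward corruption. The denoiser is a 6-block residual MLP with mirrored
U-Net-style skips (block 4 reuses block 3's activation, 5 reuses 2's, 6
reuses 1's; bottleneck widths shrink toward the middle), conditioned through:

* a sinusoidal time embedding entering each block as a feature-wise **gain
  and shift** (plain additive time conditioning cannot express the
  step-dependent linear maps that noise prediction requires); the gain is
  `1 + tanh(.)`, bounded in (0, 2), because an unbounded gain can compound
  across blocks and destabilize training at higher learning rates;
* the EEG condition entering as `cond - null_token` through zero-initialized
  projections, so the unconditional branch is exactly the network with zero
  condition input and an untrained network is exactly unconditional;
* a direct linear skip from the noisy input to the output, since the optimal
  noise estimate approaches the input itself at high noise levels.

Training minimizes MSE between predicted and true noise at uniformly sampled
steps, replacing each condition with the null token with probability 0.10
(classifier-free guidance training). Sampling is ancestral DDPM over 50
evenly strided steps with guidance
`eps_null + w (eps_cond - eps_null)`, `w = 3.5` by default; `w = 0` and
`w = 1` reduce exactly to the unconditional and conditional branches. Two
numerical safeguards: `alpha_bar` is floored at `1e-6` and the running
clean-embedding estimate is clipped to norm 1.5 (targets are unit-norm), both
countering the cosine schedule's vanishing tail. Full ancestral noise
(`eta = 1`) empirically outperforms deterministic denoising here - the
injected noise anneals out early prediction errors - so it is the default,
with `eta` exposed.

For retrieval-oriented refinement, `refine_embeddings()` averages the
unit-normalized guided samples of `k = 8` draws per condition (an estimate of
the conditional mean direction) at a moderate guidance scale `w = 2`; in the
16-D synthetic embedding space the stronger generation-oriented default
`w = 3.5` over-extrapolates and single samples carry avoidable sampling
noise. Both settings are arguments; the config keeps 3.5 as the sampling
default.

Whether the original prior predicts noise or the clean embedding is not
fully explicit in its description ("trained to predict and remove this
noise"); noise prediction is adopted. The guidance parameterization is the
standard affine form stated above.

## Metrics

**CAT score.** Each test image carries 5 tags (2 broad, 1 specific, 1
background, 1 attribute); a generated image scores one point per tag matched,
so 200 images give a 1000-point scale. This package scores *decisions*, not
images: `match_tags()` uses exact string equality after lowercase/trim
normalization, and upstream tag extraction / human adjudication is an
external pluggable step. Whether the original manual scoring granted
partial or synonym credit is unknown; exact matching is the implemented
contract.

**Frechet distance.** `fid()` computes
`||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})` with 1/(n-1)
covariances; the matrix square root comes from symmetrized
eigendecompositions with negative eigenvalues clipped at `-1e-10`. The
feature extractor is pluggable and defaults to the identity on embeddings
(the toy decoder's images are deterministic functions of the embeddings, so
embedding-space Frechet distance is the desk-scale analogue of an
inception-feature distance).

## The perturbation experiment

`perturb_channels()` replaces the six posterior channels with i.i.d.
Gaussian noise - SD matched per channel and trial by default, a fixed-SD
mode for ablation - leaving all other channels bitwise unchanged, at
evaluation time only. `run_perturbation_experiment()` then compares
retrieval accuracy and the toy Frechet distance across conditions under
identical evaluation seeds. Whether the original experiment perturbed before
or after repetition averaging is unstated; here the averaged trials are
perturbed. On generators with `posterior_boost > 1` the perturbation removes
most of the usable signal, and the degradation grows with the boost.

## Problem sizes and determinism

The test suite trains the mini encoder (17 channels x 50 samples, 20 feature
maps, 140-D intermediate, 64-D embedding) on the scaled dataset for 60 epochs
at batch size 64, and the prior for 8000 + 3000 steps (two learning-rate
stages, 3e-3 then 3e-4) - a few minutes on one CPU.
The reference 64 x 250 encoder is built and run forward once for the
structural checks. Every stochastic step - generation, initialization,
batching, dropout, conditioning dropout, sampling, panel resampling - flows
from named integer seeds; reruns with the same configuration are
bit-identical, which the pipeline tests assert on file hashes.

## Known limitations

* The synthetic forward model is linear and stationary; conclusions about
  real EEG decoding performance cannot be drawn from it.
* Tag adjudication is exact string matching; the CAT numbers here are not
  comparable to manually adjudicated scores.
* The toy decoder is a fixed random linear map, a stand-in interface for a
  generative backbone rather than a learned generator.
* Desk-scale retrieval uses 20 test categories; the 200-way protocol is
  exercised structurally (full-panel mode) but its absolute accuracies are
  not meaningful at this scale.
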