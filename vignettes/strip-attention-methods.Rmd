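---
title: "Methods: a high-resolution strip-attention network for vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a high-resolution strip-attention network for vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Retinal vessel segmentation is a dense binary classification of fundus
photograph pixels.  Two properties make it hard: vessels span widths from a
single pixel to roughly twenty, and their contrast against the retina is
low and uneven.  Encoder–decoder networks (U-Net and relatives) lose thin
structures to repeated downsampling and re-inject encoder detail through
skip connections that cannot distinguish vessel signal from background
clutter.

The network implemented here takes the opposite route: a *main stream* that
stays at the input resolution H×W with C channels from the first layer to
the output, plus two *branch streams* at H/2×W/2 (2C channels) and H/4×W/4
(4C), created from the stream above by stride-2 3×3 convolutions.  All
convolutions are 3×3 stacks — two stacked 3×3 layers see the 5×5 window of
a single 5×5 convolution at lower cost — and every convolution is followed
by batch normalisation and ReLU.  After each stage the streams exchange
information: features travel down through chained stride-2 3×3
conv+BN+ReLU blocks and up through bilinear upsampling followed by a 1×1
convolution and batch norm (no ReLU before the additive merge).  A final
1×1 convolution and sigmoid on the main stream produce the probability
map.

### Strip attention

At each fusion point the merged feature map passes through a strip
attention module.  Dense self-attention would relate every pixel to every
other pixel at O((HW)²) cost; vessels, however, are elongated and mostly
axis-aligned at local scale, so the module restricts attention to rows and
columns.  The horizontal mechanism projects the input X through three
1×1-conv+BN+ReLU stacks into query/key/value maps, reshapes queries and
keys to a `W × (C·H)` matrix, and forms

AW[i, j] = exp(q_i · k_j) / Σ_i exp(q_i · k_j),

a `W × W` matrix normalised over its *first* index, so each column sums
to one.  This normalisation axis follows the published equations as printed;
it is unconventional (softmax over queries rather than keys), so the
implementation also offers `attention_softmax = "over_keys"`, with
`"as_printed"` the default for fidelity.  Values reshaped to `(C·H) × W`
are mixed with the transpose of AW and reshaped back.  The vertical
mechanism mirrors this over rows with an `H × H` matrix.  Both outputs pass
through one more 1×1-conv+BN+ReLU stack and join the input residually:

Z = X + λ₁·Z₁ + λ₂·Z₂,

with λ₁ = λ₂ = 0 at initialisation.  The module therefore starts as an
exact identity — the attention-enabled network and the plain-fusion
baseline are bit-identical at initialisation — and learns how much
attention to admit.  Per module the attention weights number H² + W²
rather than (HW)².

Two typographical inconsistencies in the published equations were resolved on
dimensional grounds: the vertical softmax denominator must run over H (an
H×H matrix cannot normalise over W), and the final vertical product must
use the transpose of the attention matrix, not of the value matrix
(mirroring the horizontal mechanism).

The reshape convention is fixed and documented: `[C,H,W] → [W, C·H]` keeps
W as the leading axis and ravels (c, h) with h fastest; the equivalence
tests pin this down against brute-force loop evaluations.

### Loss

Training minimises L = L_BCE + L_Dice, the mean binary cross-entropy plus
the smoothed Dice complement `1 − (2Σyp + ε)/(Σy + Σp + ε)` with ε = 1e-5.
The Dice term counters the class imbalance (vessels are ~10% of FoV
pixels).  Probabilities are clipped at 1e-7 inside the BCE logs; the
clipping bound is a numerical guard, not a tunable.

## Training protocol

Patches of 48×48 are sampled uniformly over each training image (1000 per
image at full scale; sampling is not FoV-restricted — the FoV enters only at
evaluation), and 10% of the pooled patches form the validation set, giving
the 18000/2000 and 17100/1900 splits for 20- and 19-image training sets.
Optimisation is minibatch Adam, batch 64, initial learning rate 1e-3,
weight decay 1e-4, He (fan-in, ReLU-gain) initialisation, per-epoch
reshuffling.  After each epoch the validation loss drives the schedule: a
loss not improving the best by more than 1e-6 counts as flat; after 5
consecutive flat epochs the learning rate halves (and the plateau counter
restarts — standard plateau semantics); after 20 consecutive flat epochs
training stops.  The weights of the minimum-validation-loss epoch are
returned.  `max_epochs` (default 150) is a safety bound only.  An epoch is
one pass over the training patches; runs are bit-reproducible per seed on a
single machine.

## Inference

Whole images are reflect-padded so a stride-s grid of 48×48 tiles covers
them, every tile is predicted, and each pixel takes the mean of all
overlapping predictions (stride default 16; reconstruct∘tile is the exact
identity, verified to 1e-6 for all strides 1–48).  Confusion metrics
binarise at 0.5 (the threshold is a reporting convention, not part of the
model).  AUC uses a threshold sweep over unique scores with ties grouped and
trapezoidal integration, pooled over all FoV pixels of the evaluated images
rather than averaged per image.

## The phantom generator

Real fundus datasets cannot be redistributed here, so tests and the
acceptance script run on synthetic phantoms: `n_trees` branching
random-walk strokes (per-branch width uniform in [1, 20] px, branching
probability 0.02 per step) inside a circular field of view, darker than the
background by `vessel_contrast = 0.35` of the dynamic range in the
green-like channel, over a smooth illumination gradient (amplitude 0.15)
with Gaussian noise (sd 0.03).  Default geometry is 584×565, matching
common fundus resolutions, and defaults put the vessel fraction near 10% of
the FoV, typical of real retinas.  Labels use hard strokes; image strokes
are anti-aliased.  Phantoms emulate the *statistical* structure the method
assumes — thin curvilinear foreground, low contrast, uneven illumination,
circular FoV — but not optic discs, lesions, colour pathology or inter-image
appearance variation; passing tests therefore demonstrate the pipeline's
mechanics and trainability, not clinical-grade performance on real retinas.

## Numerical choices

* Tensors are `[H, W, C, B]` arrays; the engine records a forward tape and
  replays it in reverse, releasing buffers as it goes to bound peak memory.
* 3×3 convolutions evaluate their im2col GEMM in single precision — the
  customary deep-learning arithmetic — while 1×1 convolutions, batch norm,
  the attention arithmetic and all losses remain double precision.  The
  attention equivalence tests (tolerance 1e-5) run entirely on the double
  path; network-level gradient checks use tolerances consistent with
  float32.
* Batch norm uses biased batch variance with momentum 0.1 running
  statistics; inference uses the stored running statistics (all attention
  oracle tests run in inference mode).
* Softmaxes subtract the column/row maximum before exponentiation.
* Bilinear resizing uses the half-pixel (align-corners-false) convention
  with edge clamping.
* Gray conversion defaults to ITU-R 601 luminance with a `green` option,
  since fundus work often prefers the green channel; normalisation is
  dataset-wide z-scoring followed by an affine rescale of the set to
  [0, 255]; CLAHE defaults to clip limit 2.0 on an 8×8 tile grid and gamma
  to 1.2 — conventional fundus values, all configurable.  CLAHE internally
  reflect-pads to a tile-divisible size and crops back.
* FoV estimation thresholds the normalised red channel at 0.10, applies a
  small (3-px) morphological closing, keeps the largest connected
  component and fills holes.  A larger closing brush measurably erodes the
  disc boundary, which is why the small brush is paired with hole filling.

## Design decisions in the open parts of the architecture

The stream widths (C, 2C, 4C) and resolutions are fixed contracts; the
block counts are not part of the published description and are therefore
configuration: defaults C = 16, two 3×3 blocks per stream per stage, three
stages with a full cross-stream fusion after each non-final stage.
Transitions create the medium stream after stage 1 and the low stream after
stage 2.  Strip attention is applied to every stream's fused feature
(configurable via `attention_streams`), and the head performs a final
all-to-high fusion before the 1×1-conv+sigmoid output.  This topology is a
declared reconstruction consistent with the stated contracts, not a claim
about the original implementation's exact wiring.

## Desk-scale experiments

The test suite and the acceptance script size their experiments for one
CPU: networks with C = 8, 20 phantoms of 584×565 with 200 patches per image
(3600 train / 400 validation), one training epoch at the published
optimiser settings, predictions at stride 24, and an overfit probe (10
patches, 200 Adam steps, joint loss < 0.2).  One epoch of the small network
already reaches a held-out phantom Dice near 0.9 because phantom vessels
are better contrasted than real capillaries.  At this scale the
attention-vs-baseline comparison has limited statistical power: λ₁, λ₂ grow
from zero within the epoch, so the attention branch contributes only
mildly, and the comparison across three seeds mainly checks that attention
does not hurt.  Variance across seeds of the held-out Dice is a few
hundredths; the acceptance checks use means over seeds.

## Known limitations

* Only horizontal and vertical strips: diagonal vessels rely on the
  residual path and the convolutional context.
* Single-device determinism only; no GPU or multi-core path.
* The phantom generator draws constant-width branches; real vessels taper.
* No augmentation beyond random cropping, matching the training protocol it
  implements.
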