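---
title: "Adversarial multi-modal medical image fusion: model, losses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial multi-modal medical image fusion: model, losses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusegan)
```

## The fusion problem

Clinical imaging pairs a *structural* modality (MRI, CT: high-resolution
anatomy, sharp edges, texture) with a *functional* one (PET, SPECT:
physiological activity rendered as pseudo-color blobs on a mostly black
background). Fusion combines one co-registered pair into a single image
that keeps the anatomy's texture and the functional signal's color.
`fusegan` implements an unsupervised generative-adversarial approach: no
ground-truth fused images exist, so the supervision comes from the inputs
themselves, through screened reconstruction losses and an adversarial game
played on *gradient maps*.

## Color handling

PET/SPECT color must survive fusion untouched. The RGB functional image is
decomposed into full-range BT.601 YCbCr
(\(Y = 0.299R + 0.587G + 0.114B\), chroma zero-centered then offset by
+0.5); only the luminance plane enters the network, and the fused
luminance is recombined with the original Cb/Cr before converting back to
RGB. CT companions are single-channel and bypass this path. Out-of-gamut
pixels after the inverse transform are clipped, never rescaled, so
in-gamut pixels survive bit-for-bit.

One consequence worth stating plainly: chroma passthrough is *exact* only
for pixels whose recombined (fused-Y, source-chroma) triple lies inside
the RGB gamut. Replacing the luminance of a saturated color with a
brighter fused value can leave the gamut, and the mandated clipping then
moves that pixel's chroma. This is a property of any clipped YCbCr fusion
pipeline, not of this implementation; the tests assert exact passthrough
on in-gamut pixels.

## Networks

The generator runs two weight-independent branches (one per modality):
two 3x3 conv-ELU layers, a back-project dense block (BPDB), and a
convolutional block attention module (CBAM). Branch outputs are
concatenated and pass through a composite BPDB + CBAM at doubled width,
then a conv-ELU / conv / sigmoid head emits the fused image. Every
convolution is stride-1 and padded, so spatial size is preserved end to
end.

The BPDB exists to suppress the influence of large black backgrounds. Its
three stages are back-projection arithmetic on features: an enhancement
stage (encode, take the difference between a conv-activation of the code
and the code itself, add it back, decode), a residual stage (the
*absolute* difference between a conv-activation of the enhanced features
and the features, decoded), and a reconstruction stage (encode the
residual, add the enhanced features, decode). Several wirings of the
difference stage are defensible; the one above is the only one in which
the difference is both added back during enhancement and absolute-value
subtracted during the residual stage, and it is exposed as a single
function so alternative wirings can be swapped in tests.

CBAM gates features twice: channel attention (global max- and avg-pooled
descriptors through a shared bottleneck MLP, reduction ratio 8) and
spatial attention (channelwise max and mean maps through a 1x1
convolution). The architecture this follows activates both gates with
ELU, which is unconventional — ELU gates are unbounded and can be
negative — so ELU is the default for fidelity and a `sigmoid` gate is
provided as the conventional bounded option
(`generator_config(attention_gate =)`).

The discriminator never sees images, only Laplacian gradient maps: a
stack of stride-2 conv-ELU layers (16, 32, 64, 64 channels by default),
global average pooling, and one sigmoid unit. Reference channel widths
and depths are not available for either network; the defaults here are
config-driven stand-ins sized for CPU work.

Weight initialization is Kaiming fan-in from the session seed, with one
exception: the final head convolution is scaled down by 0.1 so that the
initial fused image sits near the sigmoid midpoint rather than deep in
saturation, where the pixel and gradient losses see vanishing gradients.

## Gradient machinery and losses

The Laplacian is the 3x3 4-neighbor stencil (8-neighbor available) under
edge-mirroring padding — zero padding would make the frame of a
black-background image its strongest "edge" and corrupt the adversarial
signal. The adversarial "false data" is `Grad1 = |∇G(M,I)|`; the "real
data" is the joint gradient map `Grad2 = max(|∇M|, |∇I|)`, the stronger
edge of the two modalities at every pixel. Maps reach the discriminator
unnormalized (a config flag can change that; default off).

The generator minimizes

\[ L \;=\; L_{Gan} + \lambda_1 L_{pixel} + \lambda_2 L_{grad}, \]

with squared adversarial loss \(L_{Gan} = \frac1N \sum (D(|\nabla
G|)-1)^2\) (the square supplies gradient where a log loss would
saturate), a screened pixel loss \(\frac{1}{XY}\sum \mathrm{Map}_1 (G -
M)^2 + \mathrm{Map}_2 (G - I)^2\), and the analogous screened loss on
Laplacians. The discriminator minimizes \(\frac1X\sum (D(Grad_1)-0)^2 +
(D(Grad_2)-1)^2\).

The screening maps decide, per pixel, which source the fused image should
match. The judgment rule is windowed-variance saliency (window 7,
configurable): `Map1 = 1` where the structural image's local variance
strictly exceeds the companion's, 0 where it is strictly lower, 0.5 on
ties, and `Map2 = 1 - Map1`. A constant-0.5 mode exists as a fallback
that needs no tuning. The maps depend only on the inputs and are cached
per record before training.

The weights \(\lambda_1, \lambda_2\) are meant to make the three terms
equally important; no published values exist. Defaults are 1 and 1, and
`calibrate_loss_weights()` (or `train_config(calibrate_weights = TRUE)`)
rescales them on the first training batch so the three components match
the adversarial term in magnitude.

## Training protocol

Adam (defaults: learning rate 1e-4, betas 0.9/0.999) updates the
discriminator exactly `p = 2` times per generator update; within one
cycle the same mini-batch serves all updates, and the generator forward
that builds `Grad1` for the discriminator steps is computed once (the
generator does not change between them). One epoch runs `K = floor(n/b)`
cycles, reading "one iteration is divided into K steps" as the number of
mini-batches per epoch. One master seed drives initialization and
shuffling, making runs bit-reproducible on one machine; non-finite losses
abort with a diagnostic. There is no early stopping; validation metrics
are logged per epoch when a validation set is supplied.

Two profiles are used throughout. The full-scale profile (batch 32, 300
epochs, 256x256 slices, 32 base channels) is in
`inst/config/paper_scale.yaml`. The desk-scale profile — 64x64 phantoms,
8 base channels, batch 4 — is the default `train_config()` and is what
the tests and the acceptance script run; the vignette and README numbers
all come from it.

### Desk-scale GAN dynamics

At desk scale the adversarial game is fragile in a way worth
documenting. The discriminator separates joint from fused gradient maps
almost immediately (its loss falls to ~1e-3), the adversarial term then
saturates near 1, and with it the generator's sigmoid output can be
driven into a flat, fully saturated image — an absorbing state, since
the sigmoid derivative vanishes there. Two measures keep desk-scale
optimization in the responsive regime, and the acceptance script uses
both: first-batch loss-weight calibration (above), and a larger desk
learning rate of 5e-4 chosen once for this profile. The package default
stays at the conservative 1e-4, which is the sensible setting for the
full-scale profile.

## Fusion quality metrics

Four reference-free metrics judge a fused image `F` against sources `A`,
`B`:

* **AG** — mean forward-difference gradient magnitude on the
  (H−1)x(W−1) grid with the factor 1/4 *inside* the square root, as the
  defining formula states. The more common convention uses 1/2;
  `average_gradient(quarter = FALSE)` selects it, and the two differ by
  \(\sqrt2\).
* **EI** — mean 3x3 Sobel magnitude under mirrored borders.
* **q_abf** — per 8x8 window, the universal image quality index \(Q_0\)
  of each source against `F`, blended by relative windowed-variance
  saliency \(\lambda = s_A/(s_A+s_B)\) and averaged over windows. The
  label "Qabf" usually denotes the Xydeas-Petrović edge-transfer metric,
  but the defining equation implemented here is the windowed-quality
  form, so that is what is computed. \(Q_0\) itself is not spelled out in
  the source material; the universal image quality index is the member of
  that metric family with exactly this \(\lambda\)-weighted two-source
  window structure. Degenerate windows fall back to the surviving factor
  of \(Q_0\), and two identically-constant equal windows score 1.
* **q_cv** — difference images `A−F`, `B−F` are band-filtered with a
  Gaussian (σ = 1.5 by default, a smooth stand-in for the contrast
  sensitivity of the visual system), and their windowed (16x16) mean
  squared errors are combined with weights equal to each source's
  windowed mean Sobel magnitude, normalized by total weight. Lower is
  better; 0 at perfect self-fusion.

Windows tile the image domain including final partial windows; all
windowed choices (sizes, strides, σ, saliency exponent) are arguments.
Every metric accepts plain matrices and does not require [0,1]
intensities. Each has an independent brute-force oracle in the test
suite, matched to 1e-6 relative error on random images.

## Synthetic phantoms

`phantom_spec()` defines co-registered pairs emulating the statistical
contrast the method assumes: the structural member has overlapping
ellipses and rings with sharp boundaries, sinusoidal texture (8 cycles
across the image) and additive Gaussian noise (sd 0.02); the functional
member has smooth Gaussian activity blobs (width 8% of the image side)
*centered inside the structural anatomy* and colored by a
black-blue-green-yellow-red ramp, with at least 60% of pixels exactly
zero. Co-registration comes from shared seeded geometry, not warping —
registration is out of scope. The default size is 256x256, matching
whole-brain atlas slices; tests use smaller sizes explicitly.

Two ground-truth orderings make the metric sanity checks meaningful: the
structural member dominates AG/EI, and it dominates the joint gradient
map on ≥90% of pixels at the default spec (measured 0.92–0.94 across
seeds; at 48–64 px miniatures blob curvature grows and the fraction can
dip to ~0.87, which is why that invariant is checked at the default
conditions).

What the phantoms deliberately do not model: anatomy, scanner physics,
partial-volume effects, registration error, intensity nonuniformity.
Passing tests on phantoms demonstrates that the machinery optimizes what
it claims to optimize under the method's assumptions — not clinical
image quality.

## Numerical and engineering choices

No deep-learning framework is involved: the package carries its own
engine — im2col-lowered convolutions executed as BLAS matrix products
(with compiled kernels in `src/`, cross-checked in the tests against a
pure-R lowering), a define-by-run reverse-mode tape, and Adam. Analytic
gradients are verified against central finite differences through the
entire generator-plus-losses graph to ~1e-6 relative error.

Other choices: max-pooling ties break to the first index
(deterministic); `abs()` uses subgradient 0 at 0; the Laplacian's
adjoint folds mirrored border contributions back onto edge pixels;
gradient-map TIFF dumps are min-max normalized because float TIFF
storage outside [0,1] is undefined (the original range is returned for
exact recovery); checkpoints serialize weights, config, seed and the
loss log into one RDS archive.

Problem sizes in the shipped runs: unit tests train 4-channel models on
24x24 phantoms; acceptance-style checks run a 200-generator-step session
at 64x64 with 8 base channels and a 7-row ablation harness at 32x32; the
acceptance script trains the desk profile on 14 pairs and evaluates on 6
held-out pairs.

## Known limitations

* Published layer widths/depths and \(\lambda\) values are unknown;
  everything is config-driven but the defaults are stand-ins.
* Whether the two branches share weights is unstated; they are
  independent here (the architecture diagrams show parallel branches).
* The ELU attention gate is implemented as published, but its
  unboundedness can amplify activations; the sigmoid option is the
  stable alternative.
* Desk-scale adversarial training demonstrates optimization direction
  and reproducibility, not converged fusion quality; no claim of
  numeric parity with published full-scale results is made, and the
  third-party metric implementations used there are not reproduced.
* 2-D single-slice only; no DICOM/NIfTI, no 3-D volumes, no ICC color
  management, no video-range YCbCr.
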