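# fusegan

Unsupervised adversarial fusion of co-registered multi-modal medical image
pairs — MRI with CT, PET or SPECT — in R.

## The problem

A structural scan (MRI/CT) carries sharp anatomy; a functional scan
(PET/SPECT) carries physiological activity as pseudo-color blobs on a
mostly black background. Clinicians want one image with both. No ground
truth exists for "the correct fused image", so the model is trained
unsupervised: the inputs themselves supervise the output, through screened
reconstruction losses and an adversarial game played on gradient maps.

Color is preserved exactly by construction: the functional image is
decomposed into YCbCr (full-range BT.601), only the luminance Y is fused
with the MRI, and the fused Y is recombined with the original Cb/Cr.

## The model

A generator G fuses the two grayscale planes through two
weight-independent branches (conv-ELU extraction → back-project dense
block → channel+spatial attention), a composite stage at doubled width,
and a sigmoid reconstruction head. A discriminator D sees only Laplacian
gradient maps and learns to tell the fused image's gradient map

&nbsp;&nbsp;Grad₁ = |∇G(M, I)|

from the joint gradient map of the inputs

&nbsp;&nbsp;Grad₂ = max(|∇M|, |∇I|).

The generator minimizes

&nbsp;&nbsp;L = L_Gan + λ₁·L_pixel + λ₂·L_grad,

where L_Gan = mean (D(|∇G|) − 1)², and L_pixel, L_grad are
mean-squared distances of the fused image (and its Laplacian) to
whichever source wins a per-pixel windowed-variance saliency screen
(Map₁/Map₂). The discriminator minimizes
mean (D(Grad₁) − 0)² + (D(Grad₂) − 1)², with two discriminator updates
per generator update, under Adam.

There is no deep-learning framework underneath: the package ships its own
engine — im2col convolutions on BLAS (compiled kernels under `src/`), a
reverse-mode autodiff tape, Adam — verified against finite differences
and a pure-R lowering in the test suite.

Four reference-free fusion metrics are included: average gradient (AG),
edge intensity (EI), the windowed quality index `q_abf` (higher is
better, 1 at perfect self-fusion) and the visual-error index `q_cv`
(lower is better, 0 at perfect self-fusion). A synthetic phantom module
generates co-registered structural/functional pairs with the statistical
contrast the method assumes.

## Worked example

The data machinery in a few lines — generate a co-registered pair and
look at the structure the method relies on:

```r
library(fusegan)
spec <- phantom_spec(size = c(64, 64), seed = 7)
pair <- make_pair(spec)            # structural gray_image + functional color_image
y <- rgb_to_ycbcr(pair$functional)$y

average_gradient(pair$structural)  # 0.0391
average_gradient(y)                # 0.00906
metric_report(pair$structural, y, pair$structural)
#>          ag       ei     q_abf       q_cv
#> 1 0.0390975 0.480472 0.9145489 0.04808583
```

The structural phantom is ~4x sharper than the functional luminance (AG
0.0391 vs 0.00906), and its joint gradient map is dominated by the
structural member on 91% of pixels — exactly the asymmetry the screening
maps and the adversarial mechanism exploit. "Fusing" the structural image
with itself as candidate scores `q_abf` 0.91 and `q_cv` 0.048: good but
not perfect, because the candidate ignores the functional source entirely.

Training and fusing (desk-scale profile; a few minutes on one CPU):

```r
records <- lapply(1:14, function(j) {
  sp <- phantom_spec(size = c(64, 64), seed = 1000 + j)
  fusion_record(make_structural(sp), make_functional(sp))
})
cfg <- train_config(batch_size = 4, epochs = 150, lr = 5e-4,
                    calibrate_weights = TRUE, seed = 1,
                    gen = generator_config(base_channels = 8))
ck <- train(cfg, records)
fused <- fuse_pair(ck, pair$structural, pair$functional)  # color_image
```

`fuse_pair` routes a color companion through YCbCr automatically and
returns an RGB image whose chroma matches the input's wherever the result
is in gamut. A thin CLI wraps the same functions
(`inst/cli/fusegan synth|train|fuse|evaluate|gradmap|ablate`), and
`run_ablation()` reproduces the module/loss ablation table structure on
phantoms.

See `vignettes/fusion-methods.Rmd` for the model, every tunable with its
default and rationale, and known limitations.

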