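---
title: "Prompt-driven multi-domain medical image translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-driven multi-domain medical image translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptI2I)
```

## The problem

Multi-domain image-to-image (I2I) translation maps a medical image from one
appearance domain (say a T1-weighted brain MRI) into another (a T2-weighted
one) while preserving the anatomy. When many datasets with many acquisition
protocols are pooled, the usual one-hot domain encoding breaks down: it
cannot express that two protocols differing only in fat saturation are
semantically close, and it cannot address a domain that was never assigned a
code. This package encodes domains as natural-language *medical prompts*
generated from scan metadata, embeds them with a contrastively aligned dual
encoder, and conditions a single generator on the prompt embedding — so any
domain a prompt can describe is addressable, including unseen attribute
combinations (zero-shot translation).

## Medical prompts

`extractKeywords()` merges DICOM-style tags with curated overrides into a
canonical `KeywordSet` (essential tokens: organ, modality, plane; optional:
sequence, time point, contrast agent, scanner, acquisition parameters,
preprocessing). `renderPrompt()` emits the fixed sentence template, e.g.

```{r prompt}
kw <- extractKeywords(
  tags = list(Manufacturer = "Philips", MagneticFieldStrength = 3.0),
  overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
                   Sequence = "T2-weighted", Preprocess = "skull removal"))
renderPrompt(kw)
```

Sentences whose keywords are absent are omitted. Sentences carrying the
appearance-defining tokens — sequence/modality/organ (with the time-point
ordinal rendered inside that first sentence), contrast and preprocessing —
are flagged essential; scanner, acquisition-parameter and plane sentences
are optional. During training, `augmentPrompt()` drops each optional
sentence independently (default probability 0.5 — the deletion rate is a
free parameter here, kept configurable) and shuffles the survivors; whether
the leading sentence stays first is likewise configurable (`keepFirst`,
default off, i.e. full shuffle).

Prompt/image matching (`matchPrompts()`) uses exact sentence-text identity
after whitespace normalisation: a candidate matches an original when all its
sentences occur in the original and all the original's essential sentences
occur in the candidate. The relation is deliberately asymmetric. The
resulting binary matrix (`buildMatchMatrix()`) labels the contrastive loss,
and one prompt may match several images acquired under the same protocol.

## The dual encoder and its contrastive objective

The text encoder is a causal transformer (full size: 12 layers, width 768,
12 heads, lower-cased BPE vocabulary of 49,152 symbols, context 256) whose
top-layer activation at the `[EOS]` token is layer-normalised, linearly
projected and L2-normalised. The image encoder is a ConvNeXt-style network
(7x7 stride-1 stem with 96 channels; stages 96/192/384/768 with blocks
3/3/9/3 and strides 4/2/2/2) pooled by a single multi-head QKV attention
layer whose query is the global average-pooled feature, then projected into
the same space. The shared projection dimension is not dictated by the
architecture; we default to 512 (the common CLIP convention) and use 64 in
the reduced configurations.

Both embeddings being unit-norm, `promptContrastiveLoss()` is the symmetric
multi-positive InfoNCE: for each text the average over matched images of
the negative log softmax (temperature 0.07) over all images in the batch,
plus the mirrored image-to-text direction. Rows or columns with no match
contribute zero — augmentation guarantees each image matches its own
prompt, so this is a guard, not a modelling choice. With an identity match
matrix the loss reduces exactly to the standard symmetric CLIP objective
(tested against an independent reference).

The tokenizer is trained deterministically (`bpeTrain()`) on the template
lexicon for desk use; a full-scale vocabulary can be loaded instead. Merge
ties break lexicographically so training is reproducible byte-for-byte.

`pretrainDualEncoder()` optionally logs zero-shot domain accuracy on a
validation split each epoch and restores the encoders to the
best-accuracy epoch at the end — the same validation-based model
selection the translation stage uses with PSNR, and the guard that makes
the contrastive study robust to optimisation noise.

## The translation triad

* **Structure encoder** `encodeStructure()`: 7x7 stride-1 stem (96
  channels), then two stages of channels 192 and 384 (blocks 1 and 3,
  strides 2 and 2) built from ResNeXt blocks with a single-head pre-norm
  self-attention block between each two. Output: the anatomy map at 1/4
  resolution.
* **Conditional decoder** `decodeConditional()`: mirrors the encoder.
  Stride-2 convolutions become 2x nearest upsampling followed by stride-1
  convolutions; the convolutions inside the ResNeXt blocks are
  *hyper-convolutions* whose kernels are generated from the domain
  encoding; output through a LeakyReLU (slope 0.01, our choice — the
  output activation slope is not architecturally constrained).
* **Discriminator** `discriminate()`: three kernel-4 stride-2 convolutions
  (96/192/384), conditional ResNeXt blocks with interleaved self-attention,
  and a 1x1 single-channel patch-scoring head at 1/8 resolution.

The conditioning contract of a hyper-convolution is: a two-layer perceptron
maps the domain encoding to `rank` coefficients, and the kernel (and bias)
is the coefficient-weighted combination of learned basis kernels — a
grouped low-rank factorization that bounds parameters while keeping the
kernel linear in the coefficients. Zeroing the perceptron except its final
bias makes the coefficients constant, so the decoder provably collapses to
an unconditional network; the test suite uses exactly this property as the
oracle for correct weight routing. We interpret the conditioning notation
`G(E(X) | T)` as hyper-convolutional kernel generation rather than channel
concatenation, consistent with the dynamic-convolution description of the
generator.

Self-attention placement in the decoder mirrors the encoder (the exact
placement is under-specified; mirroring is the symmetric choice). The
discriminator's normalisation layers are also unspecified; we use none and
rely on the least-squares objective's boundedness at these scales.

## Losses

With `w <- lossWeights()` (lambdaL1 = 10, lambdaP = 0.1, lambdaCon = 1,
lambdaAdv = 5, lambdaCos = 0.1, tau = 0.07):

* `reconstructionLoss()` — paired L1 plus perceptual distance of both
  cross-reconstructions.
* `structureConsistencyLoss()` — MSE between the two structure maps (raw
  features) plus the pixel contrastive term on per-pixel L2-normalised
  features over the common foreground mask, max-pooled 4x to the feature
  grid (a 4x4 block is foreground if any pixel is, matching the stride-4
  receptive field).
* `pixelContrastiveLoss()` — symmetric per-pixel InfoNCE over masked
  pixels; empty masks give 0.
* `triangularLoss()` — L1 plus perceptual distance of the round trip
  through an intermediate domain from another dataset of the same organ.
* `adversarialLosses()` — least-squares GAN: the discriminator minimises
  `(D(real)-1)^2 + D(fake)^2` with the fake detached, the generator
  minimises `(D(fake)-1)^2`. The printed min/max orientation of the
  adversarial objective reads inverted against standard practice; we adopt
  the standard least-squares convention and record the interpretation.
* `cosineSemanticLoss()` — negative cosine between the frozen image
  encoder's embedding of the generated image and the target domain
  encoding.
* `totalLoss()` — `Linit = Lrec + lambdaCon*Lcon` and
  `Lfine = Lrec + lambdaCon*Lcon + Ltri + lambdaAdv*Ladv + lambdaCos*Lcos`.

**Reductions.** All L1/MSE terms are means over elements rather than
unreduced norms, so the published component weights stay meaningful across
image sizes. For the same reason the contrastive term inside
`structureConsistencyLoss()` is averaged over the masked pixels: as a raw
sum it grows with foreground area and would dominate the mean-reduced
reconstruction term by orders of magnitude at any resolution (we observed
exactly this — a components ratio near 200:1 and stalled optimisation —
before adopting the averaged form). `pixelContrastiveLoss()` itself keeps
the literal summed form. For the structure-map MSE we use raw features and
reserve normalisation for the contrastive term, which is the reading that
keeps the two sub-terms complementary (MSE constrains scale, the
contrastive term constrains direction). Adversarial gradients propagate
through both the decoder and the structure encoder (configurable at the
optimiser level by excluding parameters).

The perceptual extractor is pluggable. The built-in
`mkFeatureExtractor()` is a deterministic bank of fixed random 3x3
convolutions with 2x average pooling between levels: reproducible with no
external weights, and sufficient as a multi-scale feature distance for
training and testing. A pretrained backbone can be substituted anywhere an
`extractor` argument appears.

## Preprocessing

`normalizeIntensity()` applies `N(X) = (max(X, Rmin) - Rmin) / RX` with
`Rmin = 0` (MRI) or `-1024` (CT, CBCT) and `RX` the 99.5th percentile for
MRI, 3000 for CT, 1500 for CBCT. No upper clipping: the MRI tail maps above
1, and the PSNR convention `R = 1` assumes the nominal [0, 1] range. The
MRI percentile is computed over all voxels including background zeros by
default (configurable; the alternative restricts to positive voxels).
`resampleVolume()` performs separable trilinear resampling to 1x1x1 mm
(brain, breast) or 2.5x1x1 mm (abdomen, pelvis). `sampleSlice()` zero-pads
or randomly crops to the working cube, draws one of the three planes
uniformly, and — critically for supervision — reuses the same offsets,
plane and slice index across all volumes of a paired subject. Evaluation
uses centred, deterministic placement.

## Metrics

PSNR uses `10*log10(R^2/MSE)` with `R = 1`, computed per slice and averaged
over cases (the per-slice-vs-per-volume reduction is unstated in most
reporting; per-slice is the finer-grained choice). An identical pair yields
`Inf`, surfaced as such rather than clamped. SSIM uses 7x7 uniform windows
with `c1 = 1e-4`, `c2 = 9e-4` (unit intensity range) and population
variances. The perceptual patch distance sums squared feature differences
over extractor levels. Dice defines empty-vs-empty as 1. ASSD extracts
8-connectivity border pixels (image-edge pixels included) and computes
exact pairwise Euclidean distances honouring anisotropic spacing. AUC uses
the rank formula with mid-rank ties.

## The synthetic phantom generator

`generateStructure()` draws a smooth random blob (a base radius modulated
by three angular harmonics) with nested tissue classes — rim ("skull"),
fat-like ring, parenchyma, and an elliptical lesion — deterministic per
seed, each class at least 1% of the foreground by construction.
`makeDomainSpec()` maps prompt attributes one-to-one onto appearance
operators: sequence selects the per-class intensity lookup, contrast adds a
lesion boost (+0.35), fat saturation scales the fat class (x0.15), skull
removal zeroes the rim. Operators act on disjoint classes, so attribute
composition commutes and held-out combinations (e.g. fat-saturated T2) are
renderable without appearing in training — the fixture for the zero-shot
translation check. Additive Gaussian noise (sigma 0.02 on foreground,
clipped to [0, 1]) keeps PSNR ceilings analytic (about 34 dB at this
noise).

What the generator emulates: multiple datasets with partially disjoint,
compositionally described domains; spatially aligned within-dataset pairs;
unpaired cross-dataset subjects sharing organ semantics. What it does not:
MRI physics (bias fields, partial volume, k-space artefacts), anatomical
variability beyond blob geometry, or inter-slice 3D structure. Passing the
desk-scale studies therefore demonstrates that the machinery — prompts,
alignment, conditioning, two-stage optimisation — works end to end, not
that clinical-grade image quality is reached on real scans.

## Desk-scale study sizes and schedules

The studies in the test-suite and the acceptance script are sized for a
single CPU: 64x64 slices, the reduced configurations (text width 64 with 2
layers; image stages 16/32/64/128; translation channels at one eighth with
blocks 1/1; hyper-network rank 4). The contrastive study uses a 4-domain,
2-dataset corpus of 400 slices, batch 20, 8 epochs, AdamW at 1e-3 — enough
for the domains, separable by construction, to reach high zero-shot
accuracy. The translation study pre-trains the dual encoder on 300 slices
over the 5 seen domains, then trains the triad at batch 6 (3 pairs per
step, 20 steps per epoch) with most epochs in the paired initial stage
and a short fine-tuning stage: at desk scale the reconstruction pathway
needs the bulk of the step budget, and the best checkpoint is selected by
validation PSNR either way. The full-scale defaults (`experimentConfig()`,
`textEncoderConfig()`, etc.) retain the published schedule: batch 60 for 50
contrastive epochs; 5 + 45 translation epochs at batch 6, AdamW 1e-4,
256x256 slices; best model by validation PSNR with ties to the later
epoch. The contrastive pre-training optimiser settings are not separately
published; we reuse the translation AdamW settings, flagged as an
assumption. Unpaired intermediates are drawn uniformly from other datasets
of the same organ within the mini-batch (the exact sampling scheme is
unstated; uniform-per-organ is the simplest unbiased choice).

## Numerical choices and degenerate inputs

AdamW uses betas (0.9, 0.999) and weight decay 0.01 (unstated; the common
defaults), identical for generator and discriminator. Zero-match rows in
the contrastive loss contribute zero. Empty foreground masks reduce the
structure consistency loss to its MSE term. Tokenizer merge ties and the
zero-shot argmax both break ties deterministically (lexicographic; lowest
index). Degenerate volumes whose normalisation range is non-positive are
rejected. Embeddings are checked unit-norm after every projection (1e-6).
All randomness flows through R's global RNG, so `set.seed` makes any
training run reproducible; there is no hidden threading.

## Known limitations

The networks run on an in-package reverse-mode autodiff core written for
clarity and testability; it is fast enough for the reduced configurations
but not for full-scale 256x256 training, which would require a GPU
framework. Volume I/O is NIfTI-only (DICOM metadata enters through tag
mappings and JSON sidecars, not pixel data). The perceptual distance uses
the deterministic extractor unless a pretrained backbone is supplied. 2D
slices only; the plane token is the only 3D awareness, mirroring the
underlying design.

At the reduced scale, rendering fidelity is not uniform across target
domains. Domains whose appearance differs from a neighbouring domain only
inside a thin structure — here the fat-suppressed ring, a 3-5 pixel
annulus at 64x64 — are reconstruction-limited: with one-eighth channels
the decoder reconstructs such targets at about 13-14 dB even from their
*own* structure map, and this ceiling is insensitive to step budget,
stage depth and learning-rate schedule (we verified all three). Because
an untranslated input from a close domain already sits near that level,
translation margins over the identity baseline collapse for exactly those
domain pairs, while cross-sequence pairs gain 5-9 dB. The limit is a
property of the reduced width at the 4x upsampling stage, not of the
conditioning mechanism: the same runs show clearly separated domain
encodings and correct attribute behaviour in the rendered output.
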