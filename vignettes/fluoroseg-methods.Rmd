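---
title: "Methods: adversarial corneal-ulcer segmentation with a cross-scale attention bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial corneal-ulcer segmentation with a cross-scale attention bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fluorescein staining makes corneal epithelial defects fluoresce green under a
slit lamp, and the stained area is the clinical measure of ulcer severity.
Delineating that area automatically is hard for three reasons: ulcer
morphology spans scattered sub-millimetre dots ("point-like"), mixed
dot-and-patch presentations ("point-flaky") and large confluent patches
("flaky"); lesion boundaries are blurred; and expert pixel annotations are
scarce — in practice many images (especially point-like cases) are never
annotated at all. `fluoroseg` implements a semi-supervised conditional
adversarial approach that learns from labeled image/mask pairs *and* from
unlabeled images.

## Model

### Segmentor

The generator is an encoder–decoder. The encoder follows the residual-18
stage layout: a strided 3×3 stem halves the input, then four residual stages
(default widths 64, 64, 128, 256, 512) each halve it again, so the top stage
sits at 1/32 resolution. Images enter as `(B, 3, H, W)` arrays in `[0, 1]`
and are mapped internally to `[-1, 1]` (zero-centred inputs remove the
systematic positive correlation of raw intensities and, empirically, make
short training runs far less initialisation-sensitive).

At the bottleneck sits the cross-scale self-attention block. Feature maps
from stages 2–4 are bilinearly downsampled to the top stage's spatial size,
passed through one 3×3 convolution each to match the top channel count
`C`, and summed into a fused map `F_A`. A single query/key/value spatial
attention is then computed:

* `Q = Conv1x1(F_A)` with `C/r` channels (`r = 8` by default),
* `K = Conv1x1(F_T)` with `C/r` channels, `V = Conv1x1(F_T)` with `C`
  channels, where `F_T` is the top-stage map,
* `energy[i, j] = <Q_i, K_j>` over row-major flattened positions, and
  `Att = softmax(energy)` **over the key axis**, so each query row is a
  convex combination of value vectors,
* `F_M[i] = sum_j Att[i, j] V_j`, and the block output is
  `F_final = F_T + gamma * F_M`.

`gamma` is a learnable scalar initialised at 0, so the block is exactly the
identity on `F_T` at initialisation and learns how much attended context to
blend in. No `1/sqrt(d)` temperature is applied to the dot products, no
positional encoding is used, and a single attention application (not a
transformer stack) is performed. The softmax axis is not dictated by the
architecture drawing alone; normalising over keys is the standard non-local
convention and the only choice that makes `F_M` a convex combination.

The decoder mirrors the encoder: four levels of 2× bilinear upsampling +
3×3 convolution + ReLU, a final 2× upsample undoing the stem, and a 1×1
convolution with a logistic output giving per-pixel lesion probabilities.
Each decoder level also receives the matching encoder stage through a 1×1
projection, added after upsampling. These additive skips are a deliberate
design choice: the package's end-to-end smoke runs train 64×64 images whose
/32 bottleneck is a 2×2 grid, and without any skip path the decoder cannot
localise lesions at all (held-out Dice 0 across every configuration we
tried), whereas with them the same runs reach Dice 0.82–0.89. The flag
`skip_connections = FALSE` restores the skip-free decoder. Interpolation +
convolution was preferred over transposed convolution to avoid checkerboard
artefacts; both read "simple upsampling" equally well.

### Discriminator

A fully convolutional patch classifier on 4-channel inputs (RGB image ⊕
mask): four 4×4 convolutions with strides 2, 2, 2, 1 and widths 64, 128,
256, 512, a stride-1 4×4 output convolution, leaky-ReLU (0.2) activations
and a logistic output. Each output unit judges one N×N input patch with
N = 70, verified analytically at construction by the receptive-field
recurrence `rf <- rf + (k - 1) * jump; jump <- jump * stride` and
empirically by a gradient-footprint probe. Weights are initialised
N(0, 0.02), the patch-discriminator convention, which starts the classifier
near chance and lets adversarial gradients ramp up gently.

## Losses

For probabilities clamped to `[1e-7, 1 - 1e-7]`:

* `L_BCE`: mean pixel binary cross-entropy between prediction and mask.
* `L_Dice`: soft Dice loss `1 - (2 sum(p y) + eps) / (sum p + sum y + eps)`
  per image, averaged over the batch (`eps = 1e-6`). A soft prediction has
  no set union, so the sum-of-areas denominator is used.
* `L_Adv = -mean log D(x, G(x))`: low when the discriminator is fooled.
* `L_D = -mean log(1 - D(x, G(x))) - mean log D(x, y)`: patch labels are 0
  for prediction pairs and 1 for ground-truth pairs; on unlabeled batches no
  real pair exists and the real term is omitted (a config switch can instead
  resample a labeled real pair).
* `L_joint = L_BCE + L_Dice + L_Adv` (unweighted; optional weights exist for
  ablations only), `L_supervised = L_joint + L_D`,
  `L_unsupervised = L_Adv`, `L_semi = L_supervised + L_unsupervised`.

All spatial reductions are means, so loss values are invariant to batch and
image size. Two printed-form corrections are deliberate: the discriminator
and pixel cross-entropies are implemented as *negative* log-likelihoods
(non-negative, minimised by gradient descent), and the Dice denominator is
the standard soft sum of areas.

One implementation subtlety matters for robustness: the training engine
takes the generator gradient at the output *logit*. The pixel BCE term then
has the closed form `(p - y) / n`, which stays informative even when the
logistic output saturates; propagating instead through the sigmoid's
`p(1 - p)` factor can silently kill the whole gradient once predictions
saturate near 0 or 1 — we observed exactly this dead-network collapse in
early smoke runs. Loss *values* are unaffected.

## Training protocol

Each iteration updates the generator first (discriminator frozen), then the
discriminator (generator frozen, predictions detached — the discriminator
loss never updates segmentor parameters). In semi-supervised mode each
iteration draws one labeled and one unlabeled batch and applies both branch
types in strict alternation; `warmup_epochs` can delay the unlabeled branch.
Validation Dice is computed each epoch and the weights with the best
validation Dice are kept (`selection = "last"` disables this). Optimisation
is Adam with the published full-scale setting as the default configuration:
learning rate 5e-4, weight decay 1e-4, batch size 4, 100 epochs, 512×512
inputs.

## Synthetic data

`generate_sample()` renders a dark background, a centred cornea disk
(radius 0.35–0.45 of the side, bluish-green with smooth radial shading) and
bright fluorescein-green lesions in the three clinical phenotypes:
`point_like` (3–15 dots, radius 1–2 px at the 128-px reference size),
`point_flaky` (dots plus 1–3 patches of radius 4–10 px) and `flaky` (1–2
large irregular blobs, each a lightly smoothed union of 5–15 overlapping
disks of radius 8–18 px). Geometry scales linearly with image size so
phenotype proportions are size-invariant. Gaussian pixel noise (sd 5
intensity levels) and ±10% brightness jitter are added after the mask is
recorded, so the mask is the exact lesion support of the noiseless render.
Point-like samples are unlabeled by default, mirroring clinical collections
in which such lesions are too small to annotate; labeled sets alternate
point-flaky and flaky. Lesion colour is simply green-channel dominance
inside the cornea — enough signal for the networks to learn from, with no
claim of clinical realism. Passing tests on these images demonstrates that
the implementation trains and generalises within this family; it says
nothing about performance on real slit-lamp photographs, which have specular
highlights, eyelashes, uneven illumination and far subtler lesion contrast.

The augmentation pipeline applies, each with probability 0.5: rotation
uniform in ±10°, horizontal flip, vertical flip, additive Gaussian noise and
a mild affine perturbation (scale 0.9–1.1, translation ≤ 5%); image and mask
share the geometric transform and masks are re-binarised after
nearest-neighbour resampling. The probabilities and affine magnitudes are
our choices (kept mild and configurable); whether unlabeled images are
augmented is configurable and defaults to yes. Labeled ids are split into
four folds; the canonical 354-image case reproduces the historical fold
sizes 90/90/90/84 exactly, any other size splits near-equally.

## Numerical choices

* Bilinear resampling uses half-pixel (non-aligned-corner) source
  coordinates everywhere, implemented as per-axis interpolation matrices.
* The 3×3 convolutions of the downsample-normalise path use stride 1,
  padding 1.
* Channel reduction requires `C` divisible by `r`; construction fails
  loudly rather than rounding.
* Binarisation threshold defaults to 0.5 and is boundary-inclusive.
* Empty prediction *and* empty ground truth score 1.0 on the overlap
  metrics; Pearson correlation on constant inputs is returned as `NA` with a
  warning and excluded from aggregation. Report standard deviations use the
  population (n) divisor.
* All float comparisons in tests use a 1e-5 max-abs tolerance; 32-/64-bit
  double arithmetic throughout (R's native numeric), no mixed precision.

## Smoke-run scale

All end-to-end checks run on one CPU at a deliberately small scale chosen
once: 8 labeled + 8 unlabeled 64×64 images, the tiny encoder (widths 8, 8,
16, 32, 64), a width-8 discriminator and 10 epochs at batch size 1 — about
80 generator updates per run, a couple of minutes of wall clock. Two
hyperparameters of `tiny_train_config()` differ from the full-scale
defaults, for reasons that are arithmetic rather than empirical tuning: the
learning rate is 0.01 because ~80 Adam updates at 5e-4 cannot move a freshly
initialised network anywhere, and the discriminator's rate is scaled by 0.05
because an equally fast discriminator flips between calling everything real
and everything fake within a handful of updates, which destabilises the
whole game at this step count (at the published scale — hundreds of images,
100 epochs — the shared setting is the default and is what the package
ships). The smoke benchmark trains both protocol branches to held-out mean
Dice ≥ 0.8 on fresh synthetic draws; this is a trainability gate for the
implementation, not a claim about clinical performance.

## Known limitations

* Pure-R execution: a full-scale 512×512 run with the 512-channel encoder
  is computationally possible but slow; the package is designed for
  correctness, testability and small-to-moderate scale, not GPU-class
  throughput.
* Encoder weights are always seeded-random; genuinely pretrained
  residual-18 weights can be injected via the checkpoint mechanism but are
  not bundled.
* Single-class (lesion vs background) segmentation only; no boundary
  metrics, no instance counting, no significance testing.
* The bilinear convention is fixed; interoperating with frameworks that use
  aligned corners will produce small boundary differences.
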