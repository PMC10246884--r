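---
title: "Predicting fruit rind color transformation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fruit rind color transformation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

For many citrus species the rind turns from green to orange over a multi-week
window as chlorophyll degrades and carotenoids accumulate. Because this color
transformation tracks fruit development, a photograph of a fruit plus a horizon
*N* (days) carries enough information to anticipate its appearance at harvest
decisions. rindcast implements a complete workflow for this: segment the fruit,
synthesize its appearance *N* days ahead, paste the synthesized fruit back over
the untouched background, and score the result colorimetrically.

The pipeline has three parts:

1. **Segmentation network** — a U-Net style encoder-decoder that maps an RGB
   frame to a per-pixel fruit probability.
2. **Generative network** — a time-conditioned encoder-decoder that maps
   (image, *N*) to a future image, with background re-fusion through the mask.
3. **Loss network** — a fixed feature extractor feeding a *local perceptual
   loss*: content fidelity plus a mask-normalized style distance. There is no
   adversarial discriminator; the hand-designed losses replace it.

## Segmentation

The encoder applies repeated (3×3 convolution, ReLU) pairs with 2×2 stride-2
max pooling; the decoder mirrors it with nearest-neighbor upsampling and skip
concatenations; a final 1×1 convolution and sigmoid produce the probability
map. Training minimizes a smoothed Dice loss,

$$\mathcal{L}_{\mathrm{Dice}} = 1 - \frac{1 + 2\sum_{ij} p_{ij} g_{ij}}
  {1 + \sum_{ij} p_{ij}^2 + \sum_{ij} g_{ij}^2},$$

where $p$ is the predicted map and $g$ the binary truth. The added 1 in the
numerator and denominator keeps the loss finite and exactly 0 when both masks
are empty — the degenerate frames that break the unsmoothed ratio. The
smoothing constant is fixed at 1 (not a tunable epsilon).

Defaults: Adam with learning rate 0.001 and moment estimates (0.9, 0.99),
batch size 56, 50 epochs, input 192×256 (landscape), depth 4, 16 base
channels doubling per stage, no normalization layers in the small default
(instance normalization behind `use_norm`). The architecture's width/depth are
package choices — only the operator inventory (3×3 convolutions, 2×2 stride-2
pooling, skip concatenation, sigmoid head) is fixed by the method. The
checkpoint retained is the epoch with the best validation MIoU. Binarization
uses a strict `> 0.5`, so exact ties go to background.

MIoU pools confusion counts over the whole evaluation set ("dataset-level"
convention) and averages the fruit and background IoU; per-image averaging is
available behind `per_image = TRUE`.

## Generative network

The encoder is two 4×4 stride-2 convolutions (3→32→64 channels by default; the
64 of the second stage is structural, see below) followed by a stack of
identical 3×3 residual blocks at 64 channels. The decoder uses *resize
convolutions* — nearest-neighbor doubling followed by a 4×4 stride-1
convolution — rather than transposed convolutions, avoiding checkerboard
artifacts, and ends in a 3×3 convolution through a scaled tanh
$127.5(\tanh z + 1)$ so every output pixel lies in $[0, 255]$ by construction.
Instance normalization and ReLU follow every convolution except the output
layer. Encoder features are concatenated into the decoder at matching
resolutions.

**Time conditioning.** Two trainable embedding tables map each representable
interval $N \in \{1, \dots, N_{\max}\}$ ($N_{\max} = 45$, the observation
span) to 64-vectors that gate — per-channel multiply — the 64 feature maps of
the second encoder convolution and of the second decoder convolution. Because
"second decoder convolution" is ambiguous in a resize-convolution decoder, the
package gates the output of the second decoder stage's convolution, which is
constrained to carry exactly 64 channels for that reason. Embeddings are
initialized at 1 (identity gating), so an untrained model is unconditional and
the conditioning is learned. One merged model thus serves every horizon from a
single weight set; the embedding-free ablation
(`train_fixed_interval_generator()`) needs one weight set per interval and is
provided for the merged-vs-individual comparison.

**Background re-fusion.** Only the fruit is synthesized:
`mask * generated + (1 - mask) * original`. Background pixels are bit-equal to
the input, and the operation is idempotent. Training uses the ground-truth
annotation masks (the two networks are trained separately); the segmentation
network supplies masks at inference.

The generator consumes the raw full frame (not the pre-segmented fruit):
re-fusion presupposes a full-frame input, and the skip connections let the
network copy structure cheaply while the losses shape the fruit region.

## The local perceptual loss

Features come from a fixed extractor with named layers `Conv<i>_<j>`. Content
similarity uses high layers; style similarity uses Gram matrices
$G^l(x)_{mn} = \sum_t F^{l,m}_t F^{l,n}_t$ of low-layer features, which
summarize channel co-activation independent of spatial layout. The content
loss is the per-layer mean squared feature difference summed over content
layers. The *local* style loss masks each image's features with its own fruit
mask (resized to each layer by nearest neighbor, preserving binarity) and
normalizes each Gram matrix by the mask sum:

$$\mathcal{L}^*_{\mathrm{style}}(y, \hat y) = \sum_l w_l\, \pi_l \sum_{m,n}
  \left[ \frac{G^l(\hat y \odot M^l_{\hat y})}{\sum M^l_{\hat y}}
       - \frac{G^l(y \odot M^l_y)}{\sum M^l_y} \right]_{mn}^2 .$$

Masking removes the background; the mask-sum division removes the region's
area, so a constant-textured fruit photographed small or large yields the same
normalized Gram (exactly $c\,c^\top$ for a constant color $c$). The test suite
demonstrates both invariances against the two baselines that lack them: the
classical global style loss and its black-background variant (mask-multiplied
images fed to the global loss), which kills background influence but stays
size-sensitive. `style_difference_matrix()` reproduces the pairwise comparison
harness, including 5-level equal-width quantization.

Two open normalization choices, both exposed in `style_config()`:

* **Prefactor** $\pi_l$: `"as_printed"` is $1/(H_l W_l C_l)^2$, mirroring the
  global loss; `"channels_only"` is $1/C_l^2$, on the ground that the mask-sum
  division already normalizes spatial extent. The printed grouping is
  typographically ambiguous; the two conventions rescale but never reorder
  single-layer comparisons (tested), and neither is asserted as "the" reading.
* **Layer weights** $w_l$ are free parameters with no published values;
  default 1 per layer.

The local perceptual loss driving the generator is
$\mathcal{L}_{\mathrm{content}}(x, \hat y) +
\mathcal{L}^*_{\mathrm{style}}(y, \hat y)$ with 1:1 weights by default
(configurable), computed on the re-fused output.

**Extractors.** The package provides (a) the identity/pixel extractor, whose
single layer is the channel-first pixel array — closed-form testable and the
default for CPU-scale training — and (b) a VGG19-topology extractor (blocks of
2/2/4/4/4 3×3 convolutions with pooling between, layers named `Conv1_1` …
`Conv5_4`) with frozen, seeded, He-initialized random weights. Random
convolutional features are a recognized basis for perceptual distances; the
package does not ship or download pretrained weights, and the extractor is
documented as what it is. Default content layers `Conv4_2`, `Conv5_2`; default
style layers `Conv1_1`–`Conv5_1`; ImageNet channel means are subtracted before
the stack. Training backpropagates through whichever extractor is configured.

With the identity extractor, the content term (a full-frame pixel MSE against
the input) and the style term (mask-normalized color Gram difference against
the target) compete directly over the fruit pixels. The training default for
this extractor therefore uses the channels-only prefactor — the as-printed
prefactor divides the already-normalized Gram difference by $(HWC)^2$ and
makes the style term vanish numerically — and a style weight of 10, chosen
once so that rind color fidelity dominates the (skip-aided) reconstruction
term inside the mask. Both are ordinary `style_config()` fields, not special
cases.

## Evaluation metrics

* **PSNR** $= 10\log_{10}(255^2/\mathrm{MSE})$ over all pixels and channels;
  identical images report `Inf` (serialized as `"inf"` in reports). The
  reference image is ambiguous in a paired setting without pixel
  correspondence; the package defaults to the *input* frame — well-defined
  because the background is re-fused from it — with `"target"` behind a flag.
* **MLSL** — the mean local style loss against ground truth over an
  evaluation set; the color-accuracy headline.
* **CCI** — mean RGB over the mask, converted to Hunter Lab, then
  $1000\,a/(L\,b)$: negative for green rinds, positive for orange. Hunter Lab
  (distinct from CIELAB) uses $L = 100\sqrt{Y/Y_n}$,
  $a = K_a(X/X_n - Y/Y_n)/\sqrt{Y/Y_n}$, $b = K_b(Y/Y_n - Z/Z_n)/\sqrt{Y/Y_n}$
  with D65 and $K_a = 172.30$, $K_b = 67.20$ by default (consistent with sRGB
  camera imagery; the classical illuminant-C colorimeter convention
  $K_a = 175, K_b = 70$ via `white = "C"`). The white point is taken as the
  matrix image of linear white so neutral grays map to exactly $a = b = 0$.
  The CCI denominator degenerates only off the rind-color locus: a neutral
  mean color returns 0; otherwise a near-zero $b$ is clamped at $10^{-6}$ with
  a warning. **CCI error** is the L1 distance between predicted and true CCI.

## Data model and splitting

Manifests are CSV/JSON tables `(sample_id, day, view, image_path, mask_path)`
with `day` a relative integer index (the acquisition mapping only needs
differences). Pairing enumerates all within-sample day pairs with
$N \in [n_{\min}, n_{\max}]$; views may differ between input and target by
default — the method does not require strict structural correspondence — with
`same_view = TRUE` available. All splitting is *sample-disjoint*: a fruit's
images never straddle partitions. The 3:1:1 split gives validation and test
$\lfloor n/5 \rfloor$ samples each with train taking the remainder (10 → 6/2/2,
107 → 65/21/21); k-fold assigns shuffled samples to folds differing by at most
one, each sample tested exactly once. Both are pure functions of
(sample set, seed).

## The synthetic orchard generator

Real orchard campaigns are expensive; the package ships a generator whose
output has the statistical structure the pipeline must handle, so every stage
is testable end-to-end. Each sample is an ellipse-rendered fruit (exact mask by
construction) whose HSV hue declines linearly in expectation from green
(~95°, s.d. 4) toward orange (~30°, s.d. 3) at a per-sample rate drawn from
1.1–1.8°/day — spanning the ~45-day transformation window — with 1.5° per-day
jitter, striped and spotted hue modulation (uneven coloration), multiplicative
radial shading with a 0.85–1.15 lighting gain (roughly similar illumination),
low-frequency texture, and a day-independent colored-noise background with
foliage-like blobs. Fruit size and position vary per view; 5% of frames drop
out by default, emulating missed acquisition days. Default frame size is 64×64
(256×192 available): the signal the pipeline must recover is colorimetric, not
high-frequency, and desk-scale training is the point.

What the generator does **not** emulate: specular highlights, occlusion by
leaves, perspective or shape change, camera noise, illuminant drift, or any
real rind texture statistics. Green tests on synthetic data therefore
demonstrate that the machinery — losses, conditioning, compositing,
colorimetry — recovers a known color trajectory; they are not evidence about
accuracy on real orchard imagery.

## Numerical choices and degenerate inputs

* Dice smoothing constant 1, exactly; loss finite for all-empty inputs.
* Mask binarization threshold 0.5 strict `>`; mask PNGs are {0, 255} with
  read-time binarization at >127.
* Nearest-neighbor everywhere a mask is resized (binarity) and in the resize
  convolutions (checkerboard avoidance).
* Degenerate (empty) masks: an explicit error in the losses, naming the layer;
  training pairs with empty target masks are skipped with a warning.
* Adam (0.9, 0.99, $\varepsilon = 10^{-8}$), learning rate 0.001 for both
  stages (the generative stage inherits the published segmentation settings,
  which name no generator-specific values); generator batch 32, 80 epochs at
  full scale.
* Generator model selection follows the two-stage rule: among the 10 epochs
  with the best validation MLSL, the best-PSNR epoch is kept (candidate sets
  recorded in the fitted object).
* All randomness flows through integer seeds via a splitmix-style derivation;
  training is bit-reproducible given (data, config, seed), and the network
  engine has no nondeterministic op.
* The convolution engine evaluates im2col patch products in BLAS and
  backpropagates with cached sparse scatter matrices; gradients of every layer
  (and of both full networks) are finite-difference-verified in the test
  suite.

## Desk-scale problem sizes

The package's own tests and the acceptance script train at sizes a laptop CPU
handles in minutes, chosen once as the package's study conditions: 20 samples
× 20 days at 64×64 (depth-3, 8-channel U-Net) for segmentation, and 12
samples × 16 days at 32×32 (stems 16→64, 2 resblocks, intervals 2–10 days)
for the generator; the test suite trains 6 and 12 epochs respectively, the
reproduction script 8 and 16. The headline checks are recovery properties:
held-out MIoU of the trained U-Net, the Pearson correlation between predicted
and target fruit hue on held-out pairs, and the monotone response of predicted
CCI to the requested interval for a fixed input.

## Known limitations

* The loss network's random features are not a perceptual match for a
  pretrained VGG19; MLSL values are comparable within a configuration, not
  across extractors.
* The generator is trained and evaluated here on synthetic imagery only; real
  deployments should retrain on annotated orchard series via the same API.
* Environmental covariates (temperature, humidity) are out of scope; the
  embedding-gating mechanism is the natural extension point.
* Hue summaries use the arithmetic mean, valid for the green-orange arc
  (30–110°) which never wraps 0°.
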