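---
title: "Methods: a lightweight two-stage plant detector in R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight two-stage plant detector in R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Field photographs of wild plants are cluttered, unevenly lit, and shot at
arbitrary resolutions; the devices that should identify plants in situ
(forestry edge hardware) have little compute. `plantrcnn` implements a
two-stage detector built for that regime, together with everything needed
to exercise it end to end on synthetic data: image enhancement, a
lightweight backbone with spatial attention, a region proposal network
(RPN) and RoI head, Pascal VOC I/O and metrics, a scene generator, and a
complexity profiler.

Three components define the method:

**Unsharp masking.** A Gaussian low-pass `B = G_sigma * I` is subtracted
from the image to isolate high frequencies, which are added back with
intensity `k`:

    I_sharp = I + k (I - B) = (1 + k) I - k B

At the default `k = 1.5` the expansion is `2.5 I - 1.5 B`. This is applied
*online* at training time (stored files are never modified), sharpening
plant edges and textures before feature extraction. Four comparison
enhancers (Laplacian, Sobel, high-boost, HSV value equalization) are
provided behind the same dispatch so enhancement ablations are one flag
away.

**Split spatial attention.** For an input feature map `X` of shape
(B, C, H, W), the channels are split into `G` groups (default `G = 1`).
Each group is summarized by channel-wise max and average pooling (two
1-channel maps preserving H×W), the 2-channel summary passes through one
shared 7×7 convolution, and the sigmoid of the result gates the group
elementwise. Output shape always equals input shape, and because the gate
lies strictly in (0, 1), the gated activations never exceed the input in
magnitude — both facts are asserted as invariants in the test suite.

**Light bottleneck.** The ResNet bottleneck's 3×3 convolution is made
depthwise (one filter per channel), keeping the 1×1 compression and
expansion convolutions pointwise. Conv-weight count per block drops from
`C·M + 9M² + M·C'` to `C·M + 9M + M·C'`; for the canonical (256, 64, 256)
block that is 69,632 → 33,344 weights. Assembled in the ResNet-50 layout
(stem + stages of 3/4/6/3 blocks), the light backbone carries under 60 %
of the standard backbone's convolution parameters. The extractor ends
after stage 3 at total stride 16 (600×600 input → 38×38 map); stage 4 is
the RoI head trunk.

The detector is classic two-stage: 9 anchors per feature cell (ratios
0.5/1/2 × scales 8/16/32, anchor side = scale × stride), an RPN scoring
and regressing them, greedy NMS at IoU 0.7 on proposals, RoI max pooling
to a fixed grid, and a classification (+ background) / box-regression
head. Evaluation is VOC-style: greedy IoU-0.5 matching, per-class
precision/recall/F1 at a single confidence threshold, AP as the area under
the monotone precision envelope, and unweighted class means.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k` | 1.5 | — | stated enhancement intensity |
| `sigma`, `kernel_size` | 2.0, 13 | px | unstated in the source; 13 ≈ 2·ceil(3σ)+1 gives full 3σ support |
| `groups` (attention) | 1 | — | stated; larger G fragments memory access |
| attention kernel | 7 | px | stated operator definition |
| anchor ratios / scales | 0.5,1,2 / 8,16,32 | — | stated RPN table |
| `feat_stride` | 16 | px | stated; fixed by the 3-stage extractor |
| RPN NMS IoU | 0.7 | — | stated |
| input size | 600 | px | stated, letterboxed |
| lr / batch / epochs | 1e-4 / 4 / 100 | — | stated training table |
| optimizer | adaptive-moment, β₁ = 0.9 | — | "momentum 0.9" read as the first-moment decay, the only momentum such an optimizer has |
| weight decay | 5e-4 | — | stated |
| test score threshold / NMS | 0.5 / 0.3 | — | unstated; single operating point matching single printed P/R values |

## Numerical and implementation choices

* **Borders**: image-enhancement convolutions reflect at the border
  (symmetric mirror), avoiding dark halos; network convolutions zero-pad,
  the field convention.
* **Clipping**: enhancers compute in floating point and clip to [0, 255]
  at the end; `unsharp_mask(..., clip = FALSE)` exposes the raw linear
  combination for verification.
* **Coordinates**: 0-based half-open boxes everywhere inside the package;
  VOC's 1-based inclusive corners are converted only in the annotation
  layer.
* **"Resized without loss of information"** is read as an
  aspect-preserving letterbox onto a gray square canvas; any other square
  resize distorts.
* **"DS_Conv2d" for the 1×1 compression** is read as a standard pointwise
  convolution — a depthwise 1×1 cannot change the channel count, so this
  is the only reading that can compress.
* **Attention placement**: applied to each block's output after the
  residual addition, per-stage toggles; the weakest assumption consistent
  with inserting the module "within the feature extraction layer".
* **Ties**: NMS keeps the earlier index on equal scores; channel-max
  pooling routes gradient to the first channel attaining the maximum.
* **Pooling arithmetic** is floor-mode with padding 1, which yields the
  documented 600 → 300 → 150 → 75 → 38 spatial chain.
* **RoI pooling** quantizes region corners to feature cells (floor/ceil)
  and clamps degenerate regions to one cell; no RoI-Align variant is
  provided (out of scope).

## Choices the sources left open (and why we made them)

The training-dynamics choices below were adopted after the first
end-to-end runs on synthetic scenes; they address optimization failures
visible at desk scale and are not tuned against any published number.

* **Sampling ratios are enforced, not filled.** The cited architecture
  samples 256 anchors at 1:1 and 128 RoIs at 1:3 but fills the quota with
  negatives when positives are scarce. With one or two objects per
  synthetic scene that fill produces ≈3 positives versus 125 backgrounds
  and the head collapses to predicting background. We keep the stated
  ratios literally (negatives ≤ positives, resp. ≤ 3× foregrounds, with a
  floor of 8 so a background signal always exists).
* **Class-agnostic box regression** (4 outputs instead of 4 per class):
  with five classes and tiny data, per-class regressors see too few
  positives each.
* **Jittered ground-truth RoIs** (4 copies, corner noise ~ N(0, 0.15) of
  the box size) join the head's sampling pool, giving the regressor
  diverse (RoI → target) pairs from the first step instead of mostly
  zero-delta examples.
* **Head feature vector**: the ResNet convention (global average pooling
  after stage 4) discards the spatial layout inside the RoI, which the box
  regressor needs at small scale; `head_pool = "flatten"` keeps it. The
  default remains `"avg"`.
* **Normalization statistics at inference**: training always computes
  batch statistics (batch size is 1 image for the extractor), so the
  running averages blend statistics of images that differ strongly; the
  mismatch visibly broke inference on tiny models. `predict_detector()`
  therefore defaults to per-image batch statistics (`batch_stats = TRUE`),
  with the conventional running-stats mode available.
* **One iterative box-refinement pass** at prediction: the regressed boxes
  are fed back once as RoIs. This is standard iterative bounding-box
  regression and measurably tightens localization on coarse feature maps.

## The synthetic world

`make_scene()` emulates the *statistical* structure documented for the
real dataset, not its appearance: varied resolutions drawn from a pool;
mean grayscale gain-adjusted into [100, 120] (the documented brightness
concentration); five classes with distinctive color/shape signatures
(star, ring, ellipse, diamond, disc with distinct hues); cluttered
backgrounds (low-frequency noise fields plus muted ellipses); optional
occluding bars. Boxes are tight mask extents; generation is bit-identical
under a seed.

What it deliberately does **not** emulate: photographic texture,
intra-class appearance variation, perspective, multiple species per
image, extreme object scales. A trivial mean-color classifier separates
the classes (> 90 % on crops — an asserted invariant), which is exactly
the point: a green end-to-end test establishes that the *pipeline*
(anchors, sampling, losses, backprop, pooling, decoding, NMS, metrics) is
wired correctly, and nothing about accuracy on real plants.

The desk-scale smoke configuration shrinks the stated world to fit a CPU
test budget: 128×128 scenes, one object of 50–70 % of the image side,
backbone widths (4, 8, 16, 16) with one block per stage, anchor scales
(2,) 4–5 at stride 16, 200 optimizer steps at batch 2 and learning rate
2e-3 (the full-scale defaults of the configuration tables stay in
`default_config()`). The stated end-to-end bar — ≥ 0.5 mAP@0.5 on the
five training scenes after 200 steps — is asserted in the acceptance
suite.

## Known limitations

* Pure-R + Rcpp execution: full-scale (600×600, ResNet-50 widths)
  training is out of desk reach; the package trains faithfully at reduced
  scale and *profiles* the full-scale model analytically instead
  (`count_params()`, `count_macs()`).
* No pretrained backbone weights (shapes differ for light blocks anyway).
* Published parameter/GFLOP totals depend on head and counting
  conventions the source does not state; the profiler reports both MACs
  and 2×MACs and treats printed totals as audit references only.
* The edge-performance model (speed-up ratios, simulated FPS) is pure
  arithmetic over supplied constants; no hardware timing is performed.
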