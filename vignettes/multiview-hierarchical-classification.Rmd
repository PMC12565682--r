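---
title: "Multiview hierarchical classification of skeletal abnormalities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview hierarchical classification of skeletal abnormalities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvskel)
```

This vignette documents the modeling decisions behind `mvskel`: the label
model, the multiview representation, the two classifier families, the
evaluation protocol, the phantom generator, and the numerical choices made
where the design was genuinely open. It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## The label model

Whole-body mouse X-ray screens annotate each image with a subset of a
catalogue of expert abnormality codes. `mvskel` organizes these into a
three-level hierarchy:

* **Level 1** — `abnormal` iff at least one code is present;
* **Level 2** — each code maps to one anatomical subclass
  (`Limbs`, `Ribcage`, `Skull`, `Spine`, `Whole-body`);
* **Level 3** — each code maps to one specific subclass
  (`Caudal`, `Thoracic`, `Cervical`, `Lumbar`, `Morphology`, `Shape`,
  `Digits`, `Fusion`, `Joints`, `Other`).

A specimen's code set is the union over its images: an abnormality marked on
any acquisition marks the animal. Because skull and limb findings are rare
in whole-body projections, the `Skull` and `Limbs` subclasses are excluded
from modeling by default; a specimen whose only findings are in excluded
subclasses **remains level-1 abnormal** but contributes no level-2/3 bits.
We chose this reading (rather than dropping such specimens entirely)
because exclusion is motivated by class sparsity at levels 2/3, not by any
doubt about the animal's top-level status.

The retained classes define a binary 1 × 13 vector (3 + 10 slots, level-2
block first, both in fixed documented order). The encoding is exactly
invertible; the test suite checks the round trip exhaustively over all
`2^13` set pairs.

The bundled 53-code taxonomy (`inst/extdata/default_taxonomy.csv`) is
synthetic: it covers every subclass member commonly named in phenotyping
protocols (kyphosis, lordosis, scoliosis, rib fusion, syndactylism, ...)
and fills the remainder with plausible placeholder codes, because no
complete public code-to-subclass table exists. Any real deployment should
supply its own taxonomy file (`load_taxonomy(path)`); the algebra is
independent of the specific catalogue.

## The multiview composite

Each specimen is represented by a single `size × size × 3` array:

1. **mean DV** and **mean LAT** images (channels 1–2): repeat acquisitions
   are averaged after bilinear resizing and per-image min–max
   normalization. Averaging suppresses acquisition noise; min–max
   normalization removes most inter-center brightness variation.
2. **blended edge map** (channel 3): Canny edges of the two mean images,
   cleaned by removing connected components below 10 pixels, then combined
   as `0.6 · DV + 0.4 · LAT`. The DV view gets the slightly higher weight
   because its symmetric, unforeshortened geometry makes edges easier to
   attribute anatomically; the weights are configurable and constrained to
   sum to one.

Canny parameters default to `sigma = 1`, hysteresis thresholds `0.1 / 0.2`
on the gradient magnitude of `[0, 1]`-scaled intensities with
unit-normalized Sobel kernels (a full-contrast step has magnitude ≈ 0.5).
Two numerical details are deliberate: gradient magnitudes are rounded to
12 decimals before non-maximum suppression so that exactly symmetric inputs
(an image and its negative) fall on the same side of suppression ties, and
plateau ties keep only the positive-direction pixel, which yields
single-pixel lines on symmetric step edges.

Quality filtering precedes everything: per-view cohort intensity outliers
(mean intensity outside `μ ± 3σ`) and aspect ratios outside a configured
band are rejected and logged. The pipeline order is
filter → resize → group → mean → edges → clean → blend → stack; edge maps
are computed from the *mean* images rather than per acquisition, since the
mean is the representation actually fed to the models and per-image edges
would re-introduce the acquisition noise the mean removes.

## Classifier families

Both families share the chained level structure: each level's head consumes
a representation learned by the previous level, and all upstream layers are
frozen while a head trains (the tests verify bit-identity of upstream
weights after downstream training).

**Backbone family.** A spatial CNN trunk feeds global average pooling, a
32-unit ReLU dense layer and a single sigmoid unit (level 1, trained end to
end). The level-2 head reshapes the 32-vector into the smallest even
square-ish tensor (4 × 4 × 2), applies a 32-filter 3 × 3 convolution,
2 × 2 max-pooling, flattening, three L2-regularized ReLU dense layers
(defaults 128/64/32, penalty 1e-4) and a 3-unit sigmoid output; the level-3
head repeats the pattern from level 2's second-to-last layer with a 10-unit
output. The trunk is a pluggable `mvskel_net`; the desk-scale default is a
small trainable two-stage CNN. Large pretrained backbones fit the same
interface but are out of scope here. `extract_combined_features()`
implements channel-wise concatenation of per-view feature maps
(concatenation rather than averaging, because it loses no information and
lets the level-1 head learn its own view weighting).

**CAE family.** A convolutional autoencoder — encoder
conv/ReLU/pool × 2, decoder mirrored with nearest upsampling — is trained
by reconstruction MSE. Two non-obvious choices:

* the decoder output layer is **linear** (clipped to `[0, 1]` when
  reconstructions are extracted). Radiographs are predominantly dark; a
  sigmoid output saturates toward zero early in training and stalls
  learning of the sparse bright structure.
* latent features are **standardized** with training-set statistics before
  the heads, with the per-feature scale floored at 1/20 of the mean scale
  so near-constant latent units are not amplified into noise.

Level 1 is a dense sigmoid probe on the flattened latent trained with
binary cross-entropy — the simplest classifier consistent with "the encoder
serves level 1", chosen because the alternative (thresholding
reconstruction error) provides no class probabilities and performed no
better on phantoms. The level-2 head is two ReLU dense layers with dropout
(0.3) and a 3-unit sigmoid output; no convolutions, since the encoder has
already convolved. The level-3 head consumes the post-ReLU output of
level 2's **first** hidden layer. This is the one place we deviate from a
"second-to-last layer" hand-off: the deeper level-2 layers are specialized
to the 3-class task and demonstrably discard within-subclass location
information (on phantoms, a probe trained directly on the latent recovers
level-3 classes almost perfectly, while the same probe on the narrow
penultimate layer does not). Taking the first, wide level-2 representation
keeps the hierarchy — level 3 still reads frozen level-2 features — while
bounding the information loss by that layer's width, which is therefore a
benchmark-relevant hyperparameter (512 in the standard benchmark).

Level-2 and level-3 heads train and evaluate on **abnormal specimens
only**: the subclass questions are conditional refinements of "abnormal",
and including the normal majority would let heads score well by re-solving
level 1.

**Training engine.** All models train with minibatch Adam
(β₁ = 0.9, β₂ = 0.999), binary cross-entropy (MSE for reconstruction),
batch size 32, at most 100 epochs, and early stopping on validation loss
with patience 3, restoring the best weights. These defaults mirror the
standard hyperparameter sheet for this architecture family, including the
published per-level learning rates (0.001/0.0001/0.00011 backbone,
0.00001 CAE heads). The published CAE-head rate of 1e-5 assumes long
training on tens of thousands of specimens; at desk scale it cannot move a
freshly initialized head within the epoch budget, so the phantom benchmark
specifies its own optimization configuration (below). The engine is
deterministic given a seed (initialization, shuffling and dropout all draw
from the seeded R stream), which the protocol relies on for
reproducibility. Convolution forward/backward passes are im2col + BLAS with
compiled gather/scatter kernels, verified in the tests against a naive
convolution oracle and central-difference gradients.

## Evaluation protocol

Specimens are split 70/20/10 into train/validation/test, stratified by the
level-1 label only (stratifying by rarer strata at realistic imbalance
produces empty cells). The split, training and dropout randomness all
derive from one repetition seed; the experiment repeats over several seeds
(five by default, three in the standard benchmark) and reports per-class
mean ± sd across seeds.

AUC is computed as the Mann–Whitney pair statistic (ties one half),
verified exactly against a brute-force all-pairs oracle. One-vs-rest AUC is
computed per class on the sigmoid outputs; classes without both positives
and negatives in a test split are flagged missing (`NA`) and skipped — not
imputed — by the per-level unweighted mean. Reported standard deviations
are across seeds.

SSIM uses a uniform 7 × 7 window, `k1 = 0.01`, `k2 = 0.03`, dynamic range
1, population variances, averaged over valid window positions; the tests
pin it to a per-window closed-form oracle.

## The phantom generator

The generator's purpose is **structural** fidelity, not anatomical realism:
two full-body projections per specimen with repeat acquisitions, strong
normal/abnormal imbalance (default abnormal fraction 0.1), frequently
co-occurring abnormalities (classes drawn independently per specimen),
per-center brightness factors plus per-image jitter, additive noise — and,
crucially, *view-dependent abnormality visibility*. Phantom geometry lives
in two offset functions along the spine axis (coronal and sagittal); the DV
render projects the coronal plane, the LAT render the sagittal plane, so an
edit confined to one plane is pixel-invisible in the other projection by
construction. The injection map is:

| Level-3 class | edit | visibility |
|---|---|---|
| Cervical / Lumbar | localized coronal vertebral displacement | DV only |
| Thoracic | localized sagittal displacement | LAT only |
| Shape | global sagittal (kyphosis-like) spinal curvature | LAT only |
| Fusion | merged rib arcs (ribs are drawn in the coronal projection) | DV only |
| Joints | limb-joint gaps (limbs likewise coronal) | DV only |
| Digits | merged digits (level-1 only: Limbs is excluded at level 2) | DV only |
| Caudal | tail truncation | both |
| Morphology | stroke-width change | both |
| Other | pelvic nodule | both |

The `Shape` class is realized as the sagittal curvature edit rather than a
global aspect distortion: curvature is the canonical spinal *shape*
abnormality, and a single-plane edit preserves the view-visibility contract
that makes the multiview comparison informative (a both-view Shape edit
would leave the DV model blind to only one class and mute the contrast the
generator exists to expose). Stroke width defaults to 2 px at the 128-pixel
reference scale — thinner strokes are sub-pixel at the 64-pixel benchmark
resolution, which no real skeletal radiograph exhibits.

What the phantoms do **not** emulate: X-ray physics, bone density, organ
shadows, pose variation, foreshortening, or realistic mouse anatomy.
Passing the phantom benchmark therefore demonstrates that the pipeline
*can* exploit complementary views when complementary information exists; it
does not predict absolute performance on real screens.

## The standard phantom benchmark

`phantom_benchmark()` fixes the study conditions once: 600 specimens at
64 × 64, abnormal fraction 0.5, prevalences 0.15 for the six spine-region
classes, 0.30 for Fusion/Joints/Other, 0.05 for Digits, three repetition
seeds, CAE family. The choices have stated reasons: a realistic 0.1
abnormal fraction would leave ~6 abnormal test specimens per split, making
per-class AUC meaningless at this cohort size; uniform prevalences would
make the Spine level-2 class positive for essentially every abnormal
specimen (six of the ten level-3 classes are spinal), leaving its AUC
undefined. Benchmark training: autoencoder Adam 2e-3, batch 8, ≤ 25
epochs; heads Adam 1e-3, batch 16, ≤ 40/100/100 epochs; patience 3; head
widths 512/128/64. On one CPU the benchmark takes roughly ten minutes; the
test suite runs the same sizes.

## Known limitations

* The hierarchy hand-off width bounds what level 3 can see; narrow level-2
  heads measurably hurt multiview level-3 scores (see the hand-off
  discussion above).
* Class activation maps linearize through ReLUs (gradient-weighted
  channels); they reduce to the classical dense-weight construction for
  GAP + dense heads but are heuristic for deeper paths. Maps are rectified
  before normalization, so purely suppressive evidence is not visualized.
* Per-class AUC on abnormal-only test subsets is noisy at desk scale
  (tens of specimens); conclusions should rest on per-level means across
  seeds, as the benchmark's acceptance property does.
* The curation stage assumes grayscale radiographs with bright bone on dark
  background; min–max normalization would amplify noise on blank frames
  (such frames are meant to be caught by the intensity-outlier filter).
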