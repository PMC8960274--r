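---
title: "Classifying 3D joint shapes with a convolutional supervised auto-encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying 3D joint shapes with a convolutional supervised auto-encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Rheumatoid arthritis (RA) and psoriatic arthritis (PsA) remodel periarticular
bone in characteristic, opposite ways: RA *removes* cortical bone (erosions,
typically in the bare area of the joint), PsA *adds* bone (spurs /
enthesophytes at ligament and capsule insertions). High-resolution 3D imaging
of the metacarpal head therefore carries a class signal in the outer shape of
the bone alone. `csae` classifies such volumes into healthy-control, erosive
and proliferative patterns, and attributes the decision back to voxels.

The model is a convolutional supervised auto-encoder. The encoder has
`n_stages` stages; a stage is two 3×3×3 convolutions, each followed by a
LeakyReLU and 3D (channel-wise) dropout, and stages are connected by factor-2
max pooling with channel widths increasing toward the bottleneck. A mirrored
decoder (factor-2 nearest-neighbour upsampling, then the stage's conv block,
then a final linear 3×3×3 projection to one channel) reconstructs the input,
and a single linear layer on the flattened bottleneck produces the class
scores. Everything is trained jointly on

$$L_\text{total} = (1-\lambda)\,\frac{1}{N}\sum_{i=1}^{N}(x_i-\hat x_i)^2
  \;+\; \lambda\, w_c \,\big(-\log \hat y_c\big),$$

with a *single* mixing weight $\lambda$ rather than two independent loss
weights. The reconstruction term acts as a shape-aware regularizer that
forces the bottleneck to stay a faithful summary of the volume; the
classification term makes that summary discriminative. $w_c$ is the
inverse-frequency weight of the true class (mean 1 over classes), countering
class imbalance.

### Reading of the loss's classification term

The source formulation prints the classification term in a two-term binary
form whose first factor is the *prediction* rather than the annotation
(`ŷ log ŷ`), which is the entropy of the prediction and cannot serve as a
supervised loss; we read this as a typographical slip for the standard
categorical cross-entropy $-\sum_j y_j \log \hat y_j$ over the 3-class
softmax, which is what "cross entropy" denotes for a 3-class task. This is
implemented in `combined_loss()`, whose limits are tested exactly: at
$\lambda = 0$ it *is* the MSE, at $\lambda = 1$ it *is* the weighted CE.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_stages` / `channels_per_stage` | 5 / 8,16,32,64,128 | depth and width; desk-scale work uses 3 stages (8,16,32) |
| `lambda_weight` | 0.9 | loss mixing weight; 0.9 lets classification dominate while reconstruction regularizes |
| `dropout_rate` | 0.1 | 3D channel dropout in every conv block (encoder and decoder) |
| `leaky_slope` | 0.01 | LeakyReLU negative slope |
| `target_extent` | — | network input extent; each component divisible by `2^(n_stages−1)` |
| `epochs`, `batch_size`, `learning_rate` | 30, 4, 1e-3 | Adam training settings |
| triage `threshold` | 0.75 | minimum winning probability; *smaller than* the threshold is disregarded, the boundary is kept |

Channel widths, dropout, the optimizer and its learning rate are not pinned
by the underlying description ("increasing number of channels" only), so they
are exposed and default to values small enough for single-CPU training.
Dropout is applied in both encoder and decoder blocks, since the generic
conv-block definition does not restrict it to the encoder.

The canonical full-scale input extent 128×128×80 is not divisible by
2^4, so five-stage full-scale runs must pad the third axis (to 96) before the
network and crop the reconstruction back; `csae_config()` rejects
non-divisible extents explicitly rather than padding silently. Desk-scale
extents used throughout the tests (24×24×16, 16×16×8) are chosen divisible.

## Preprocessing contract

Each scan contributes an intensity sub-region and a binary bone mask. The
pipeline crops the mask's tight bounding box (plus a 10% margin — the margin
is not prescribed anywhere, 0.1 is our choice), resizes to `target_extent`
(trilinear for intensities, nearest-neighbour for masks — "resize" is read as
interpolation, not padding), and normalizes by the *training set's* pooled
mean and SD, refit inside every cross-validation fold. Three representations
feed the model: `subregion` (normalized intensities), `mask` (the raw binary
mask — normalizing a {0,1} field would only apply an affine shift, so it is
fed as is, and the prediction then rests purely on volumetric shape), and
`product` (voxel-wise intensity×mask, normalized with statistics fit on
product images, keeping all three representations on one normalization
contract).

Cross-validation splits **patients**, never scans, stratified by class
(stratification is our addition for stability at small cohort sizes; the
split unit itself is prescribed). Leakage is tested, not assumed: perturbing
held-out scans must leave the fold's normalization statistics and class
weights bit-identical.

## The synthetic phantom generator

The real cohort (932 HR-pQCT scans) is not public, so the package ships a
generator that emulates its *statistical structure*, not its anatomy:

* a superellipsoid head (exponent 2.5 — flatter poles than an ellipsoid,
  giving high-curvature rims analogous to a metacarpal head) on a cylindrical
  shaft;
* **erosive** phantoms subtract 1–3 hemispherical concavities centred on the
  head surface inside a fixed "bare-area" azimuth sector (55°–125°);
  **proliferative** phantoms add spherical-cap protrusions in a distinct
  "entheseal" sector (235°–305°); the removed/added material is the
  ground-truth lesion mask;
* per-patient anatomy (radii, lesion sites and sizes) and per-scan nuisance
  (pose rotation up to ±12°, centre jitter, texture, noise) come from two
  separate seeded streams, so repeat scans of one patient share anatomy —
  which is exactly what makes patient-level splitting matter;
* intensity = mask × (1 + 0.3 · smoothed noise) + background noise, a
  stand-in trabecular texture with ~3-voxel correlation length;
* undifferentiated phantoms draw a hidden erosive/proliferative truth that is
  recorded only in the manifest's `latent_class` sidecar for triage
  validation; training code never reads it.

Lesion radii default to 4.5–7 voxels on a 64×64×40 generation grid with
head radii 14–18. No quantitative morphometry of real erosions/spurs is
available to copy, so these defaults are chosen for class separability
rather than anatomical realism — deliberately so, since the acceptance-scale
cohort must be learnable by a small network in minutes. Passing tests
therefore demonstrate that the *pipeline* (preprocessing, patient-level CV,
training, attribution, triage) works end to end; they do not certify
clinical performance on real bones, where class overlap, scanner physics,
motion artifacts and segmentation errors all intrude.

## Problem sizes used by the test suite

The published experiments ran five-fold CV over 932 scans at 128×128×80 with
a five-stage network — far beyond a single-CPU test budget. The package's
end-to-end acceptance check runs the identical protocol at a desk scale
chosen up front from the arithmetic cost of the network: 60 patients
(repeat-scan probability 0.2, ≈72 scans), input extent 24×24×16, 3 stages
(channels 8/16/32), λ = 0.9, 15 epochs, batch 4, Adam 1e-3, 5-fold
patient-level CV, seed 0, for both the mask and the product representations.
The bars are macro one-vs-rest AUROC ≥ 0.90 for the mask input and
mask ≥ product − 0.05 (the shape-only input should not fall behind the
combined one). The epoch budget (15 rather than 30) is part of the same
desk-scale choice; training on this cohort converges well within it.

## Attribution and triage

Heat maps are **guided backpropagation**: the gradient of the target class's
score (logit) with respect to the input, with the backward signal zeroed at
every LeakyReLU whose forward activation was non-positive or whose incoming
gradient is negative. Two remarks: (i) methods text governs over a stray
"GradCAM" mention elsewhere in the source description, so guided backprop is
what is implemented; (ii) at a LeakyReLU the standard ReLU-style guided gate
is used — the negative slope is ignored in attribution, as is conventional.
The decoder has no path into the class score, so attribution traverses only
the encoder and head. Hotspots are the top 1% of voxels by absolute
magnitude (ties at the cut included); the localization score is the fraction
of hotspot voxels inside the ground-truth lesion dilated by 3 voxels, whose
random-hotspot expectation is the dilated lesion's volume fraction — the
acceptance bar is a ≥3× enrichment over that baseline.

Triage applies the trained model to undifferentiated scans. After
cross-validation "the trained network" is taken to be the ensemble average of
the five fold models (each with its own normalization statistics); the
argmax class is kept when its probability is at least the 75% certainty
threshold (strict "smaller than" discards, so the boundary is kept).
Distributions are always reported with both denominators — over all cases and
over retained cases — because the two conventions genuinely differ and the
source reports are ambiguous between them.

## Numerical choices and degenerate inputs

* The network runs in single precision (BLAS sgemm via im2col); forward
  passes match a pure-R double-precision reference to ~1e-5 relative, and
  analytic gradients match finite differences of that reference to <1e-3.
* Weight init: He-normal for convolutions, Xavier for the head; biases 0.
* A predicted probability of exactly 0 at the true class is clamped at 1e-12
  (with a message) rather than propagating −∞.
* Non-finite training losses abort with the epoch/sample context rather than
  silently continuing.
* `specificity = 1` makes LR+ infinite; it is returned as `Inf` with a
  warning, and McGee's ΔP is reported as `NA` there.
* Empty masks, constant heat maps, empty hotspot sets, single-class AUROC
  inputs and non-simplex probabilities are all explicit errors.
* Seeds: one integer seed fans out to stage-specific sub-seeds by a stable
  hash, so any stage can be re-run in isolation; all sub-seeds stay below
  2³¹.

## Known limitations

* The phantoms are separable by construction; absolute metric values on them
  say nothing about clinical accuracy (the published real-data AUROCs of
  68–82% are *not* reproducible without the cohort).
* Nearest-neighbour upsampling in the decoder and the flattened-bottleneck
  (no global pooling) classifier follow the figure-level description; a
  transposed-convolution decoder and a per-class sigmoid loss variant would
  be straightforward extensions but are intentionally not defaults.
* Guided backpropagation is known to be partially input-dependent rather
  than purely class-dependent on deep networks; the localization test guards
  against degenerate maps, not against every known attribution pathology.
* No data augmentation and no early stopping are implemented (none are
  described for the original experiments).
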