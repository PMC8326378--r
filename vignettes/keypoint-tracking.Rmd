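---
title: "Multi-task keypoint tracking for TAVI aortography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task keypoint tracking for TAVI aortography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During transcatheter aortic valve implantation (TAVI) the operator
positions and deploys a prosthetic valve under X-ray aortography. The
useful information on each frame is a handful of landmarks: the aortic
annulus pair AA1/AA2 and sinotubular junction pair STJ1/STJ2 (visible
only while contrast dye fills the root), the delivery-catheter
landmarks CP/CM/CD/CT, the pigtail reference catheter PT, and the
stent frame edges FE1/FE2 (visible only once deployment begins).
`aortrack` tracks these 11 keypoints per frame and turns them into
positioning guidance.

Two predictions are needed per frame and they are coupled: *which*
keypoints are present (a multi-label classification over 11 classes,
since visibility varies with contrast and procedure stage), and
*where* each present keypoint is (a 22-dimensional regression of
normalized coordinates). The package follows the hard-parameter-sharing
multi-task design: one convolutional feature extractor feeds both a
classifier head (11 sigmoid outputs) and a regressor head (22
outputs).

## Model

Coordinates are normalized to $[0,1]$ by image width/height, origin
top-left, x rightward, y downward, interleaved as
$[x_1, y_1, \dots, x_{11}, y_{11}]$ in the fixed label order
`AA1, AA2, STJ1, STJ2, CP, CM, CD, CT, PT, FE1, FE2`. Absent keypoints
hold a placeholder 0 with a mask of 0.

The desk-scale backbone `tiny_cnn` is four 3x3 stride-2 convolution
blocks (8/16/32/64 channels, ReLU) over a 64x64x3 input, followed by a
1x1 channel projection and flattening of the final 4x4 map into a
128-dimensional feature vector. Flattening (rather than global average
pooling) is deliberate: pooling discards spatial phase, which the
coordinate regressor needs, and with a 4x4 map the cost is negligible.
Each head is feature -> 256 (ReLU) -> output; the regressor output
passes through a sigmoid so coordinates are natively in $[0,1]$
(a linear output is available via `coord_activation = "linear"`).
The named large backbones (`mobilenet_v2`, `resnet_v2`,
`inception_v3`, `inception_resnet_v2`, `efficientnet_b5`) are exposed
with their canonical input sizes and feature dimensions, but are built
here as randomly initialised stand-in extractors of the same
interface: no pretrained weights are downloaded, and published
per-architecture parameter counts are treated as descriptive (the
exact head topology behind them is not documented), not as something
this package reproduces. With `fine_tune = FALSE` the backbone is
excluded from the trainable set and only the heads learn; `tiny_cnn`
defaults to `fine_tune = TRUE` because it is trained from scratch.

Grayscale frames are bilinearly resized to the backbone input size,
replicated to three channels and scaled to $[0,1]$. Channel
replication is the conventional way to feed grayscale radiographs to
3-channel architectures.

## Loss

Training minimizes

$$\mathrm{Loss} = w_1\,\mathrm{Loss}_1 + w_2\,\mathrm{Loss}_2,$$

where $\mathrm{Loss}_1$ is the mean binary cross-entropy over the 11
presence labels and $\mathrm{Loss}_2$ is the log-cosh coordinate loss
$\log\cosh(\hat y - y)$, which behaves like $e^2/2$ for small errors
and $|e| - \log 2$ for large ones — quadratic near the optimum, robust
to outliers, and twice differentiable. Defaults are $w_1 = 1$,
$w_2 = 10$: the log-cosh term is numerically much smaller than the
cross-entropy term, and the factor 10 keeps the two tasks balanced.

Numerical choices:

* **Masking.** A regressor always emits 22 numbers, but a frame
  annotates only its visible keypoints. Slots of absent keypoints are
  excluded from $\mathrm{Loss}_2$ (and from all regression metrics)
  via the mask. The alternative — regressing placeholders — would
  teach the network the placeholder value; it remains available for
  ablation by passing `mask = NULL`. Masked slots provably receive
  zero gradient (tested by perturbation).
* **Reduction.** $\mathrm{Loss}_2$ is the *mean* over masked-in
  entries pooled across the batch, keeping magnitudes comparable
  across frames with 1 versus 11 keypoints; $\mathrm{Loss}_1$ keeps
  its $1/N$ class average.
* **Clipping.** Probabilities are clipped to
  $[10^{-7}, 1 - 10^{-7}]$ before the logarithm.
* **Stability.** $\log\cosh e$ is evaluated as
  $|e| + \log(1 + e^{-2|e|}) - \log 2$, which neither overflows nor
  loses precision for any error magnitude (tested up to $|e| = 700$).

## Training protocol

The optimizer is Rectified Adam; the clinical-scale protocol
(`training_config(paper_scale = TRUE)`) uses learning rate $10^{-5}$,
batch size 64, up to 100 epochs. The desk-scale defaults — learning
rate $10^{-3}$, batch 16, up to 60 epochs — exist because a small CNN
trained from scratch on a few hundred 64-pixel phantom frames needs a
larger step size than a large pretrained backbone being nudged; both
protocols share the early-stopping rule. Training monitors the
composite loss on the hold-out validation set; an epoch counts as an
improvement when it undercuts the running best by at least 0.005, and
training stops after 5 consecutive epochs without one (running-best
semantics; with a constant validation loss this stops at epoch
`patience + 1`). The parameters of the best validation epoch are
restored on stop so that evaluation is reproducible.

The forward and backward passes are written in base R with the strided
convolutions expressed through precomputed sparse patch-extraction
(im2col) operators, so training is exactly reproducible for a fixed
seed: one seed determines initialization, epoch shuffles and hence the
entire history.

## Metrics

Classification uses per-class confusion counts at a presence
threshold of 0.5 (the standard sigmoid cut; the threshold is a
parameter). Precision, recall, F1 and accuracy are micro-averaged by
pooling counts across classes; the macro F1 is the *support-weighted*
average of per-class F1 (weights = per-class positive counts), with an
unweighted variant available. All 0/0 ratios resolve to 0.
Regression reports MAE, MSE and RMSE over masked-in coordinate entries
pooled across the evaluation set, matching the single-sum form of the
definitions; `pixel_error()` rescales a normalized MAE to a pixel
distance at a given image size. Every metric is cross-checked in the
test suite against an independent scalar brute-force implementation on
randomized batches.

## Guidance geometry

During contrast injection, AA1 and AA2 define the annulus plane: the
local frame has origin at their midpoint (the symmetric choice), the
X-axis along AA1 to AA2, and the Y-axis the X-axis rotated +90 degrees
in image coordinates — with AA1 left of AA2 this points image-downward,
toward the ventricle. Only perpendicularity is anatomically
meaningful; the sign convention is fixed so that signed errors are
reproducible, and all magnitudes are convention-free (rigid-transform
invariance is tested to $10^{-9}$). Because the pigtail catheter stays
visible without contrast, the offsets PT->AA1 and PT->AA2 are captured
while contrast is present and replayed later: the reconstructed frame
equals the contrast-built frame exactly whenever the geometry has not
moved.

From the frame, the package reports the annulus-catheter error (signed
Y-coordinate of the catheter tip), the annulus-stent error (signed
Y-coordinate of the FE1-FE2 midpoint) together with a stent tilt angle
(between the FE edge line and the annulus plane — midpoint distance
alone would miss dislodging), and the extraction degree as the raw
CP-CD Euclidean distance (no device constant is assumed, so it is not
expressed as a percentage of full extraction).

## The phantom generator

Clinical aortography series cannot ship with a package, so every
module is exercised against a synthetic phantom whose *statistical
structure* mirrors the source data:

* three procedure stages (positioning / capsule retraction /
  deployment) with mix 0.40/0.30/0.30;
* per-stage contrast probabilities (0.45/0.30/0.30, about 36 percent
  of frames overall) so that most frames lack the anatomical
  landmarks;
* FE1/FE2 only at deployment; CT always present; CD/CM/CP visible
  only while their arc position along the catheter lies inside the
  frame, driven by a stage-dependent insertion advance — presence is
  therefore always consistent with the rendered image;
* graded anatomical visibility under contrast (AA1 1.0, AA2 0.85,
  STJ1 0.9, STJ2 0.75): the downstream annulus point and the
  sinotubular pair are the hardest to see clinically, and the grading
  keeps per-frame keypoint counts spanning 1-11 with a roughly
  bell-shaped distribution with an interior mode;
* clustered geometry priors (annulus near (0.48, 0.58), catheter
  entering from the upper right) reproducing the spatial clustering
  of landmark scatter.

Rendering draws a dark catheter curve with marker bands at CD/CP and
the tip, a pigtail loop, stent edge ticks at deployment and a contrast
silhouette of the root, plus additive Gaussian pixel noise (sd 6 of
255). Annotation coordinates get Gaussian jitter (sd 0.01 by default)
emulating labeling error. Image noise uses a per-frame derived seed so
annotation streams are identical whether or not images are rendered,
and one configuration seed reproduces a byte-identical dataset.

What the phantom does *not* emulate: photorealistic fluoroscopy
texture, cardiac/respiratory motion, contrast washout dynamics, and
the exact class ratios of the clinical set (published only
graphically). Consequently, passing desk-scale tests demonstrates that
the learning machinery, losses, metrics and geometry are correct and
that the model can recover keypoints from images with this structure —
it does not certify clinical-grade accuracy, which in the source
setting required large pretrained backbones, GPU training and the
clinical dataset.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on one CPU: the
recovery check trains `tiny_cnn` on 500 phantom frames at 64x64
(80/20 split, five seeds, early stopping within 60 epochs, about 80 s
per seed), the metric fuzzing uses 1,000 randomized batches of up to
30 frames, the guidance invariance check 1,000 random scenes, and the
distributional checks 1,000 annotation-only frames. Under those
conditions validation micro-F1 typically lands between 0.95 and 0.99
and masked MAE between 0.03 and 0.04 (30-42 pixels at the clinical
1,000-pixel scale, consistent with the tens-of-pixels error regime
reported for the clinical models).

## Known limitations

* The split is frame-level by default (this reproduces the canonical
  2,984/746 partition, with training size
  `floor(0.8 * n + 0.5)`); frames of one video may straddle the
  split. A series-grouped split (`by_series = TRUE`) is provided for
  leakage-free evaluation, as it is unstated which was used
  clinically.
* Named large backbones are stand-ins without pretrained weights;
  plugging real pretrained extractors behind `backbone_spec` is the
  intended extension point.
* No temporal smoothing of keypoint streams: each frame is tracked
  independently.
* The early-stopping bookkeeping compares against the running best;
  other readings of "stopped improving" (e.g. against the previous
  epoch) would stop at slightly different epochs.
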