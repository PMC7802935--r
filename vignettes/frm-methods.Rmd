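---
title: "Fluorescence reconstruction from transmitted light: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence reconstruction from transmitted light: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frm)
```

## The problem

Fluorescence reconstruction microscopy (FRM) predicts fluorescence-channel
images (stained nuclei, cell-cell junctions, cytoskeletal fibers) directly
from label-free transmitted-light micrographs (phase contrast or DIC). A
convolutional network is trained on spatially registered pairs of
transmitted-light and fluorescence frames; once trained, it reconstructs the
fluorescent signal for new label-free images, removing the phototoxicity,
photobleaching and channel-budget costs of live fluorescence imaging. This
package implements the full workflow: paired-TIFF dataset preparation, the
U-Net regression model and its training loop, corrected correlation-based
accuracy metrics, sliding-window stitching over arbitrarily large images and
timelapses, and the downstream biological readouts through which
reconstruction quality should ultimately be judged.

## Data preparation

Camera frames are chopped into 256 x 256 px tiles (configurable), slicing
the transmitted and fluorescence channels identically. When a frame is not a
multiple of the tile size the grid is centered and the remainder cropped
symmetrically -- we prefer preserving the fixed tile size over resampling.
Fourteen-bit camera data are brought onto the 16-bit histogram by the
full-range linear map `v * 65535 / 16383`; a per-image min-max stretch is
also available (`stretch = TRUE`) since histogram normalization is sometimes
applied that way, but the full-range map is the default because it is
deterministic and intensity-comparable across images.

Each channel is z-normalized with a mean and *population* standard deviation
pooled over all pixels of all training tiles. The sample/population
distinction is immaterial at pooled-pixel scale, but fixing one convention
makes runs bit-reproducible. Predictions are de-normalized with the
fluorescence channel's statistics before any downstream use.

Splits hold out a random 20 % of tiles for testing and 10 % of the remaining
training tiles for validation, with floor rounding at each step and a fixed
seed. Tiles from one source frame can optionally be forced into the same
partition (`group =`), a leakage control that is off by default to match the
plain random-sub-image split.

## The network and its training

The model is a classic U-Net adapted for regression: `depth` encoder levels
of two 3 x 3 same-padded convolutions with ReLU and 2 x 2 max pooling,
a bottleneck, and a mirrored decoder with 2 x 2 transposed-convolution
upsampling and skip concatenation, closed by a linear 1 x 1 convolution.
Same-padding keeps the output exactly the input size. Weights are He-normal,
seeded; the implementation (im2col convolutions with analytic gradients,
verified against finite differences in the test suite) is self-contained
compiled code.

Two losses are provided. The mean squared error is applied across pixel
intensities. The Pearson-correlation loss is

$$\mathrm{Loss} = (1 - \mathrm{PCC})^2, \qquad
\mathrm{PCC} = \frac{\sum_i (R_i - \bar R)(G_i - \bar G)}
{\sqrt{\sum_i (R_i - \bar R)^2 \sum_i (G_i - \bar G)^2}},$$

pooled over every pixel of the minibatch -- the simplest reading of applying
the correlation "across pixel intensity values"; a per-image variant would
average per-tile correlations instead and is deliberately not the default.
The loss lies in [0, 4] and inherits the PCC's invariance to positive affine
rescaling of either signal. A zero-variance batch would make the PCC
undefined; the loss then returns 1 (the uncorrelated value) with zero
gradient and a logged flag, so optimization never sees a non-finite value.

Optimization uses ADADELTA with rho = 0.95, epsilon = 1e-7 and learning rate
1.0 -- the common framework defaults, since only the optimizer family is
part of the method. Batch size defaults to 16. Early stopping monitors the
validation loss with a strict-decrease criterion and a patience of 75
epochs; the weights of the best epoch are restored on return (restoration is
our choice; it makes the returned model independent of how far past the
minimum training ran).

Augmentation follows the two-stage scheme: an offline five-fold expansion in
which each tile contributes itself plus four copies rotated by distinct
random non-zero multiples of 45 degrees, and online random horizontal and
vertical flips plus zoom uniform in [0.8, 1.2] (resize then center-crop,
or reflect-pad when zooming out), with the identical transform applied to
input and target. Operating on tiles rather than pre-crop frames means
45-degree corners are undefined; they are filled with the tile's median
(background) level, which is invisible to the loss statistics in practice.

## Accuracy metrics

Whole-dataset mean PCC is biased downward by test tiles containing only
background: the network cannot (and should not) reproduce pseudo-random
noise, so such tiles score near zero and drag the mean. The corrected
accuracy score *P* therefore averages per-image PCC only over
*feature-positive* images -- those whose ground truth has at least
`min_feature_pixels` (default 64, ~0.1 % of a 256 x 256 tile) pixels above
an intensity threshold tau -- after scaled-MAD outlier removal
(3 median absolute deviations, scale constant 1.4826; with MAD zero only
values different from the median are dropped). The threshold is dataset- and
channel-specific; it can be given explicitly or selected by Otsu's method on
the pooled ground-truth histogram. Per-image PCC (not pooled-pixel PCC) is
the unit of the *P* distribution so that violin plots of per-image scores
are directly comparable.

The segmentation PCC restricts the correlation to ground-truth pixels above
tau -- a foreground-only agreement score; images whose mask is smaller than
two pixels or constant are skipped and counted. Note a degenerate corner
relevant to synthetic data: a noiseless rendering has constant foreground, so
every image is skipped and the statistic is undefined -- it is meaningful
only on data with intensity variation inside the mask. Cytofluorograms tally
every (truth, prediction) pixel pair into a 2-d histogram over the native
bit-depth range, with an optional zoom restricted to feature pixels.

## Stitching large images

Inference on arbitrarily large images slides a window (the network's input
size) with a stride of 64 px by default, averaging all predictions
contributing to each pixel without weighting. A margin of `border_exclude`
px (default 16) of each patch is discarded before averaging because
predictions near patch borders are less reliable -- except on sides where
the patch touches the image boundary, so edge pixels keep coverage. The
configuration requires `stride <= window - 2 * border_exclude`, which
guarantees every pixel at least one contribution; a final window flush with
each far edge is appended so the output size equals the input size exactly.
Images smaller than the window are reflect-padded and cropped back.
Timelapse stacks are processed frame by frame.

For cross-platform transfer, images from a different optical system are
bilinearly rescaled by the ratio of effective pixel sizes (camera pixel
pitch divided by objective magnification when magnifications are given, raw
pitch otherwise) before prediction, and can be mapped back to native
geometry afterwards. Both conventions are exposed because published
descriptions of such correction factors rarely state which is meant;
effective pixel size is the physically meaningful default.

## Downstream readouts

Reconstructions are useful exactly insofar as the analyses practitioners run
on real fluorescence also work on predictions, so the package applies
identical pipelines to both:

* **Nuclei**: Gaussian blur (sigma 2 px), Otsu or fixed thresholding,
  distance-transform watershed to split touching nuclei, connected
  components and size exclusion. Readouts are object counts (compared as
  `100 |n_pred - n_gt| / n_gt`), per-object areas in px^2 and um^2, and
  centroid displacements from greedy nearest-first one-to-one matching with
  a 15 px cap -- the two-frame linking trick, treating ground truth and
  prediction as consecutive video frames.
* **Junctions**: histogram normalization to 16 bits, thresholding at ~30 %
  of the dynamic range, binary skeletonization (Zhang-Suen thinning) to
  1-px cell outlines, a single 3 x 3 dilation to close them, inversion and
  4-connected component labelling (4-connectivity so 8-connected skeleton
  lines cannot leak between cells), yielding per-cell areas; border-touching
  regions are excluded by default as in standard particle analysis.
* **Line profiles**: bilinear interpolation at unit-spaced samples along a
  segment, for comparing intensity cross-sections of junctions.

## The synthetic generator

Real paired microscopy is neither shippable nor necessary for testing the
machinery, so the package generates deterministic synthetic scenes: seed
points (jittered grid or minimum-spacing uniform) define a rasterized
Voronoi tessellation whose edges emulate an epithelial junction network;
each cell carries an ellipse nucleus with analytic centroid and area
(pi a b); actin is a cortical band along boundaries plus sparse interior
fibers. The transmitted-light channel is a deterministic function of the
scene with the qualitative signatures a network exploits in phase contrast:
a bright halo and dark relief along boundaries, shading-gradient relief and
mild phase-darkening over nuclei, and low-frequency background texture. The
noise model is optical Gaussian blur plus additive Gaussian plus mean-scaled
Gaussian ("Poisson-like") noise -- adequate for testing metrics and
training, not camera-accurate. Defaults (16-bit levels: nuclei foreground
14000 on background 400, read noise SD 150, gain 0.05, blur 1 px, nucleus
semi-axes 8-14 px) were chosen once as plausible for cultured epithelial
monolayers imaged at moderate magnification.

Per-frame seeds are derived arithmetically from the master seed so frames
are independent yet reproducible; rendering is bit-identical for identical
specs. What passing tests on these scenes shows is that the *machinery* is
correct (losses, gradients, stitching, metrics, segmentation recover known
ground truth); it does not show that a network trained on real phase
contrast reaches any particular accuracy -- real optics, focus drift,
debris and staining variability are all absent.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
deliberately small scale: 128 x 128 px fields of 9 cells, 64 px tiles, a
depth-2 U-Net with 8 base filters trained for 300 optimizer steps, and a
training-set-size sweep over fractions {1/16, 1/4, 1} with 3 replicates at a
fixed 15-epoch budget. These sizes were chosen so a single CPU reproduces
every result in minutes while still exercising each code path at full
fidelity; paper-scale experiments (256 px tiles, depth 4, 64 filters,
hundreds of epochs) use the same functions with larger configuration values.

Other fixed numerical choices: He-normal initialization; strict-decrease
early stopping; floor rounding in splits; 0-based, row-major, top-left tile
origins with half-open extents; population SD in normalization statistics;
bilinear interpolation for every geometric resampling; predictions clamped
to [0, 65535] counts only when written as images.

## Known limitations

* The synthetic transmitted-light model is a stylized stand-in; transfer of
  conclusions to real DIC/phase data requires real paired acquisitions.
* The pooled-batch PCC loss differs from a per-image PCC loss when batch
  composition is heterogeneous; both readings are defensible, one is chosen
  and documented.
* Greedy nearest-first centroid matching approximates optimal assignment;
  for the small displacements of interest the difference is negligible.
* Training is single-threaded CPU code; it is meant for small networks and
  methodological work, not GPU-scale production training.
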