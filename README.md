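# frm: fluorescence reconstruction microscopy in R

`frm` predicts fluorescence-channel images — nuclei, cell–cell junctions,
actin — from label-free transmitted-light micrographs (phase contrast or
DIC), and evaluates those predictions the way cell biologists actually use
them. It is aimed at quantitative imaging groups who want label-free
estimates of stained structure for counting, tracking and morphometry
without the phototoxicity and channel budget of live fluorescence imaging.

At its core is an image-to-image U-Net regression trained on matched
256 × 256 px tile pairs, under either the mean-squared-error loss or the
Pearson-correlation loss

```
Loss = (1 − PCC)²,   PCC = Σᵢ(Rᵢ − R̄)(Gᵢ − Ḡ) / √(Σᵢ(Rᵢ − R̄)² · Σᵢ(Gᵢ − Ḡ)²)
```

with ADADELTA optimization and early stopping (patience 75 epochs on the
validation loss). Accuracy is summarized by the corrected score *P* — the
mean per-image PCC over test images that actually contain feature signal
above an intensity threshold, after scaled-MAD outlier removal — because a
plain whole-set PCC is dragged down by background-only tiles whose
reconstruction is necessarily noise. Large images and timelapse stacks are
reconstructed by sliding-window inference (stride 64 px, patch borders
excluded, per-pixel averaging), and downstream readouts (nuclei
segmentation/counting, centroid displacement, junction-based cell areas,
line profiles) run identically on ground truth and predictions.

The package is fully testable without microscopy data: a deterministic
synthetic generator renders paired phase-contrast-like and
fluorescence-like scenes (Voronoi cell polygons, ellipse nuclei, cortical
fibers, halo/relief transmitted contrast, additive and signal-dependent
noise) with exported ground-truth object tables.

## Worked example

Train a small U-Net on synthetic paired data, score it, and run the
downstream nuclei readouts on a stitched full-frame prediction:

```r
library(frm)

spec <- scene_spec(field_size = c(128, 128), n_cells = 9,
                   noise = list(gaussian_sd = 0, poisson_gain = 0, blur_sigma = 0))
data <- make_dataset(spec, n_frames = 12, seed = 1, tile_size = 64)
data
#> Tile dataset: 48 tiles of 64x64 (channel: nuclei)
#>       test      train validation
#>          9         36          3

fit <- frm_fit(data, loss = "mse",
               net_config = unet_config(64, depth = 2, base_filters = 8),
               batch_size = 8, max_epochs = 60, seed = 8)
fit
#> Fluorescence reconstruction U-Net (channel: nuclei)
#>   tiles 64x64, depth 2, base filters 8 (29,321 parameters)
#>   loss: mse; trained 60 epoch(s), best epoch 60 (val loss 0.08959)

frm_evaluate(fit, data, metric_config(feature_threshold = 5000))
#> Accuracy score P = 0.9582 (median 0.9575, n = 9 feature-positive images)
#> Raw whole-set PCC mean = 0.9582 (n = 9; tau = 5000.0 counts)

sc   <- generate_scene(scene_spec(field_size = c(128, 128), n_cells = 9, seed = 99,
                                  noise = list(gaussian_sd = 0, poisson_gain = 0,
                                               blur_sigma = 0)))
pred <- predict(fit, render_transmitted(sc), type = "image",
                stitch = stitch_config(64, 32, 8))
gt <- segment_nuclei(render_fluorescence(sc, "nuclei"))
fr <- segment_nuclei(pred)
pcc(render_fluorescence(sc, "nuclei"), pred)      # 0.962
count_error(gt, fr)                               # 0 (percent)
centroid_displacements(gt, fr)$summary$mean       # 0.36 um
```

The accuracy score P of 0.96 says the reconstructions correlate strongly
with ground truth on feature-bearing tiles; the downstream numbers say what
that buys in practice — an exact nucleus count and sub-half-micron centroid
accuracy on this synthetic field.

Every test tile here contains nuclei, so P equals the raw mean PCC; on
realistic datasets with background-only tiles the two diverge, which is the
point of the corrected score (`accuracy_score_P` reports both).

A thin command-line wrapper for shell use is installed at
`inst/cli/frm.R` (`synth`, `train`, `predict`, `evaluate`, `analyze`).

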