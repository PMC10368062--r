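# oct3dreg

Two-step registration of 3D optical coherence tomography (OCT) volumes
acquired by **different devices** — e.g. a commercial scanner (fewer
B-scans, co-registered SLO image) and a research scanner (denser B-scans,
wider field, noisier intensities). Registering them lets complementary
signals (polarization contrast, angiography, high-quality structure) be
fused voxel-to-voxel.

## Who this is for

Retinal-imaging researchers who have, per eye and visit, two OCT volumes
plus retinal-layer segmentations (at minimum the internal limiting
membrane, ILM, and the outer boundary of the retinal pigment epithelium,
RPE) from any segmenter, and optionally an SLO image co-registered with one
volume. Segmentations are consumed as inputs; the package never computes
them.

## The method

**Step 1 — en-face (2D) registration.** Each volume is reduced to a
frontal-view image: the SLO, or a layer-bounded axial-mean projection
(`outer`, `inner`, `hybrid`, `layer_based` bounds; `hybrid` — from 30 µm
below the image top to RPE + 20 % of the axial extent — is the default). A
jointly learned, fully convolutional keypoint network predicts per pixel a
128-d unit descriptor X, a repeatability heatmap S (its strict local maxima
are the keypoints) and a reliability heatmap R (how matchable the
descriptor is). It is trained self-supervised on single images warped by
random homographies, with the objective

    L = L_rep + L_AP,R
    L_rep  = L_cosim(S, S', U) + (L_peaky(S) + L_peaky(S')) / 2
    L_AP,R = mean over pixels of  1 − AP·R − k(1 − R),   k = 0.5

where `L_cosim` compares corresponding N×N heatmap windows under the known
flow U, `L_peaky = 1 − mean(max − mean)` over all overlapping N×N windows,
and AP is a differentiable (quantized) average precision of each descriptor
against its true correspondence among sampled negatives. Multi-scale
keypoints are matched by mutual nearest neighbour in descriptor space and
an affine transform `T2D` (moving µm → fixed µm, minimum 3 inliers) is
estimated by RANSAC in metric coordinates.

**Step 2 — axial (Z) registration.** With `T2D` applied, corresponding
A-scan columns differ only axially. Using the ILM as reference, either

* **Column shifting**: `Δ(b,a) = ILM_fixed − ILM_moving` per column, and
  `I_R(z) = I'(z − Δ)` — matches the ILM exactly, sensitive to single-cell
  segmentation errors; or
* **Layer point matching (LPM)**: a rigid or similarity transform per
  B-scan, RANSAC-fitted to the pre-paired ILM points — robust to corrupted
  cells, not exact.

Evaluation follows the standard protocol: landmark errors in µm with a
strict worse-than-overlay failure rule, five RPE-difference statistics on
the overlap mask, and the Dice coefficient of the two retinal bands
(ILM ≤ z < RPE).

A seeded phantom generator (`generate_phantom_pair()`) builds paired
two-device volumes — smooth layered retina, branching vessel shadows,
speckle, simulated SLO/projection modality gap — with exact ground-truth
transforms, so the whole pipeline is testable without clinical data.

## Worked example

```r
library(oct3dreg)
# a paired two-device phantom with known ground truth
pair <- generate_phantom_pair(phantom_config(seed = 42))
#> fixed:  48 B-scans x 160 axial x 96 A-scans | 125.00/3.50/62.50 um
#> moving: 124 B-scans x 160 axial x 96 A-scans | 64.52/3.50/62.50 um

# full two-step registration; oracle correspondences stand in for the
# network so the example runs in seconds (see below for training)
res <- register_pair(
  fixed  = list(volume = pair$fixed$volume, surfaces = pair$fixed$surfaces,
                enface = pair$fixed$slo, landmarks = pair$landmarks$fixed),
  moving = list(volume = pair$moving$volume, surfaces = pair$moving$surfaces,
                landmarks = pair$landmarks$moving),
  config = pipeline_config(oracle = pair$oracle, seed = 1))

res$transform2d
#> <affine2d> moving (um) -> fixed (um)
#>           [,1]       [,2] [,3]
#> [1,] 0.9993908 -0.0348995  120
#> [2,] 0.0348995  0.9993908  -80
```

The recovered affine is the phantom's ground truth (2° rotation,
(120, −80) µm translation). The report quantifies both steps:

```r
res$report$landmark_error_before_um   # 93.71  — raw overlay error
res$report$landmark_error_after_um    # 0.000  — after the 2D affine
res$report$dice                       # 1.0000 — retinal-band overlap
res$report$z_metrics_um$mean          # 0.009  — RPE error after column shift
```

`landmark_error_*` are mean distances over four labelled vessel landmarks;
`dice` is the 3D overlap of the ILM-to-RPE bands; the `z_metrics_um` are
the RPE-boundary error statistics — here at interpolation level because
both transforms are recovered essentially exactly.

To use the learned keypoints instead of oracle correspondences, train the
compact network (minutes on one CPU core at the desk preset) and pass it to
the pipeline:

```r
imgs <- lapply(1:50, function(i) { ... })   # en-face projections in [0,1]
fit  <- train_keypoint_net(imgs, training_config("desk", seed = 7))
cfg  <- pipeline_config(net = fit$net, seed = 1)
```

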