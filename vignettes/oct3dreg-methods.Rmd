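---
title: "Two-step multi-device 3D OCT registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step multi-device 3D OCT registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oct3dreg)
```

## The registration problem

Optical coherence tomography (OCT) devices image the same retina with very
different sampling: a commercial scanner might acquire 97 B-scans over a
6 x 6 mm field with a co-registered scanning laser ophthalmoscopy (SLO)
image, while a research device acquires 250 B-scans over 8 x 6 mm with
noisier intensity data. Fusing their information — for example, overlaying a
polarization-derived signal on a high-quality structural scan — requires
mapping one volume onto the other's grid.

`oct3dreg` decomposes that 3D registration into two steps that match the
physics of the acquisition:

1. **En-face (2D) registration.** Both volumes are reduced to frontal-view
   images (an SLO or a layer-bounded axial-mean projection). A jointly
   learned keypoint detector/descriptor network finds corresponding points,
   and RANSAC estimates an affine transform in *metric* (micrometre)
   coordinates. Because the transverse geometry of a raster scan is rigid,
   this transform aligns the full volumes in two of the three axes.
2. **Axial (Z) registration.** With the en-face alignment fixed, each
   moving A-scan column differs from its fixed counterpart only by an axial
   displacement. The internal limiting membrane (ILM) — the most reliably
   segmented retinal surface — serves as the reference: either each column
   is shifted independently by the per-column ILM difference (*column
   shifting*), or a low-degree-of-freedom transform per B-scan is estimated
   by RANSAC over the pre-paired ILM points (*layer point matching*, LPM).

The pipeline is modality-agnostic by construction: the fixed-side 2D image
can be an SLO (multimodal) or another OCT projection (monomodal), with no
code change — only configuration.

## Coordinate conventions

A volume is indexed `[b, z, a]`: B-scan (slow) axis, axial (depth) axis,
A-scan (fast) axis; en-face pixel `(y, x) = (b, a)`. Continuous coordinates
are 0-based with the origin at the first sample's centre, and surface
heights are real-valued axial *pixels* in `[0, n_axial)`; conversions to
micrometres are explicit via the per-volume spacing `(db, dz, da)`. One
internal unit avoids drift between pixel- and metric-space formulas; metric
units appear exactly where geometry demands them (affine estimation, LPM
point coordinates, reported errors).

## En-face projections

Four layer-bounded projections are provided (`projection_spec()`), each the
arithmetic mean of the intensities over a per-column half-open axial
interval:

| mode | interval |
|---|---|
| `outer` | ILM to RPE_outer + 20% of the axial extent |
| `inner` | 30 µm below the image top to RPE_outer |
| `hybrid` | 30 µm below the image top to RPE_outer + 20% of the axial extent |
| `layer_based` | IS/OS junction to RPE_outer |

Numerical choices: the "30 µm below the top" bound is measured from axial
index 0 (the image top, not the ILM) and converted with `dz`; interval
endpoints are rounded half-up to whole rows before averaging, because the
projection averages pixel rows — fractional-endpoint weighting would be an
unstated refinement; the lower bound is clamped to the axial extent, and a
column whose interval is empty after clamping is marked invalid rather than
raising an error (only an entirely missing surface is an error). Raw
intensities are averaged by default; a `log_compress` switch exists because
whether the averaging happens before or after log-compression is a free
choice in this design. Min-max normalization to `[0, 1]` is applied at the
network boundary (`normalize = TRUE`), not inside the projection itself,
so that the projection's values remain physically interpretable.

The hybrid projection is the pipeline default: it trades a little contrast
for markedly less speckle-driven punctate noise, which is what the keypoint
detector needs.

## The keypoint network and its objective

The network is a compact fully-convolutional net in the L2-Net style, with
dilation substituted for stride so that every output retains the input's
spatial size: a backbone of 3x3 convolutions (dilations 1, 1, 2, 4) and
three 1x1 heads — 128-dimensional L2-normalized **descriptors** `X`, a
**repeatability** heatmap `S` (sigmoid), and a **reliability** heatmap `R`
(sigmoid). The receptive field `M` (17 px for the default backbone) is
derived from the architecture, not hardcoded: each descriptor summarizes the
`M x M` patch centred on its pixel. Forward and backward passes are written
directly in vectorized R (im2col plus BLAS matrix products); every analytic
gradient — including the losses below — is verified against central finite
differences in the test suite.

Training is self-supervised on single images: each step synthesizes a pair
`(I, I')` by an optional rescale, a random homography ("tilt": rotation up
to ±25°, perspective up to ±5e-4, scale jitter ±10%, small translation) and
additive Gaussian pixel noise (σ = 0.02), with the exact correspondence
flow `U` retained. The homography magnitudes are chosen to keep at least
roughly 60% of pixels in-frame; they are configuration, not data.

The objective is `total = repeatability + reliability`:

* **Repeatability** = `cosim + (peaky(S) + peaky(S')) / 2`. The cosine term
  compares flattened `N x N` windows of `S` against the flow-resampled
  windows of `S'` (windows tile the image; windows with no valid flow are
  excluded). The peakiness term is `1 − mean over all overlapping N x N
  windows of (max − mean)`, which rewards exactly one peak per window — the
  window size `N` (default 16) therefore sets keypoint density.
* **Reliability** = mean over sampled query pixels of
  `1 − AP·R − k(1 − R)` with `k = 0.5`: where the descriptor ranks its true
  correspondence well (AP above `k`), `R` is pushed up; where it ranks
  poorly, down. At `AP = k` the loss is flat in `R`.

**Differentiable average precision.** Queries are taken on a stride grid
(stride = `N`), their true correspondents through the flow, and negatives
from a stride grid on the second image excluding a 3-px radius around the
true match. The AP of the single relevant candidate is quantized with
triangular kernels over `ap_bins` histogram bins spanning the *observed*
distance range — descriptor distances concentrate in a narrow band around
√2, which a fixed `[0, 2]` histogram cannot rank-resolve. Within a bin, the
positive's contribution is the expected reciprocal rank under a uniform
tie-break,

$$g(c, s) = \frac{\psi(2 + c + s) - \psi(1 + c)}{1 + s},$$

where `c` is the negative mass strictly below the bin, `s` the negative
mass sharing it, and ψ the digamma function. For an isolated positive this
is exactly `1/(1 + c)`, so the quantized AP converges to the exact
average precision (`exact_ap()`, the brute-force oracle) as the bin count
grows; for an all-tied candidate set it equals the expected AP of a random
ranking. The gradient includes the dependence of the bin edges on the
extreme distances. This construction is this package's own; it is validated
against `exact_ap()` only.

**Presets.** The `paper` training preset is the full-scale regime
customary for this family of detector/descriptor models (Adam with
β₁ = 0.9, β₂ = 0.999, learning rate 1e-4,
weight decay 5e-4, batch 8, 2500 epochs, random rescale to 256–768 px,
`N = 16`, `k = 0.5`). The `desk` preset is the CPU-scale configuration used
throughout the test suite: the small backbone (8-8-16-16 channels), ~96 px
training images, `N = 8`, batch 4, learning rate 1e-3, 12 epochs — minutes
on one core. Reported desk-scale numbers quantify this configuration, not
the full-scale regime.

## Inference: keypoints, matching, RANSAC

Keypoints are the strict 3x3 local maxima of `S` (plateau ties yield no
keypoint — determinism over density), computed over an image pyramid
(factors of 2^(1/4) down to a configurable minimum side) and reported at
native resolution; they are filtered by a repeatability then a reliability
threshold (defaults 0.7/0.7; these inference thresholds are conventions —
no canonical values exist — and are exposed in `keypoint_params()`).
Because the sigmoid heads' operating point drifts with training length, the
thresholds can alternatively be specified as quantiles of the candidate
maxima's own scores (`rep_quantile`/`rel_quantile`); the desk-scale runs
use the median, which keeps the selection meaningful even when a briefly
trained reliability head has not yet spread its output range.
Matching is mutual nearest neighbour under Euclidean descriptor distance,
the minimal symmetric pruning; no ratio test. Before extraction both
en-face images are resampled to a common isotropic pixel pitch (by default
the fixed image's finer axis) so descriptor patches cover comparable
retinal areas; keypoints are then scaled back through each image's own
pitch into micrometres for estimation.

The affine (minimum sample 3) is estimated by RANSAC with a deliberately
high fixed budget (default 10,000 iterations) to suppress its sampling
randomness, an inlier tolerance in micrometres (default 25 µm; metric,
because the two images differ in pixel pitch), a least-squares refit on the
best consensus, and one consensus re-expansion after the refit. Matches are
canonicalized by index order first, making the result invariant to input
ordering under a fixed seed. A consensus below 3 yields a
`registration_failure` object, distinguishable from a transform.

## Axial registration

**Column shifting** computes `Δ(b, a) = ILM_fixed − ILM_moving_warped` per
column and resamples each moving A-scan by `I_R(z) = I'(z − Δ)` with linear
interpolation — the displacement interpretation of the column-shift
formula; literal intensity subtraction would be dimensionally meaningless.
It matches the ILM *exactly* at every valid column (asserted to 1e-9 px in
the tests), at the price of locality: one corrupted ILM cell corrupts
exactly that column.

**Layer point matching** estimates a rigid or similarity transform per
B-scan by RANSAC over the pre-paired point sets `{(a, ILM(a))}` in metric
`(a, z)` coordinates (pixel-space rotations would depend on the anisotropic
spacing). Minimal sample 2; inlier residuals are converted back to pixel
units before thresholding so the tolerance respects the anisotropy. A
B-scan with too few valid pairs, or no consensus, falls back to the nearest
successfully registered B-scan's transform and is flagged — partial border
B-scans are the expected cause. An affine per-B-scan model exists behind a
flag but is excluded from the defaults: its extra degrees of freedom
amplify outlier damage without improving normal B-scans.

One geometric subtlety, surfaced by the tests: because the paired points
share their lateral coordinate, a pure axial magnification difference is
absorbed by the similarity model's scale only in proportion to the axial
share of the point variance. The similarity estimator itself recovers exact
2D similarity correspondences to machine precision; on realistic shallow
retinal relief, similarity and rigid LPM behave nearly identically — which
is consistent with how close these two variants score in practice.

## Evaluation protocol

2D: the mean Euclidean distance (µm) over four labelled landmarks, before
and after the transform; a case *fails* when the error after is strictly
larger than the raw overlay error (ties are non-failures). Aggregates:
mean, median, failure count, mean excluding failures. A repeat-run harness
(`evaluate_repeats()`) re-runs a stochastic registration three times and
reports the run selected by median failure count (or median median-error).

Z: per-column absolute differences of the outer retinal pigment epithelium
(RPE) boundary, scaled to µm, aggregated five ways — mean, median, max of
per-B-scan means, max of per-A-scan means (the transverse dual, i.e. the
mean over B-scans at a fixed A-scan index — the only symmetric reading of
the two aggregates), and max. All Z metrics are restricted to the overlap
mask: cells whose pre-image falls inside the moving field of view,
intersected with both surface-validity masks, so partial border B-scans do
not contaminate the statistics. The Dice coefficient is computed globally
over the implicit 3D voxel masks `ILM ≤ z < RPE_outer` (integer axial
samples; a per-B-scan variant is available as an option, since either
reading of "volume Dice" is defensible).

## The phantom: what it emulates, and what it does not

`generate_phantom_pair()` builds the study conditions entirely in code: a
smooth ILM (cosine random field, ~40 µm relief over ≥1.5 mm wavelengths), a
smoothly varying retinal thickness (~310 µm), an IS/OS junction 60 µm above
the RPE; a seeded branching vessel tree rasterized with a Gaussian
cross-profile whose shadows attenuate all layers below the inner retina
(this shared vessel structure is what makes cross-modality matching
possible); multiplicative gamma speckle (contrast 0.25); a monotone
intensity remap plus resolution difference between the SLO rendering and
the OCT projections (the simulated modality gap); and a two-device
asymmetry mirroring the target setting — defaults: fixed 48 B-scans over
6 x 6 mm with a 31.25 µm SLO, moving 124 B-scans over 8 x 6 mm, both with
1024-like dense A-scan sampling scaled to 96 columns and a 3.5 µm axial
pitch (160 samples; axial pitch is user-supplied in this domain, as devices
do not state it uniformly). The ground truth is exact by construction: an
en-face affine (default 2° rotation, (120, −80) µm translation; limits
±30°, scale 0.8–1.2 keep the pair overlapping) and a per-column axial
displacement, either constant or a smooth low-frequency field (default
amplitude 6 px) — the smooth field exercises column shifting beyond rigid
offsets. Everything is a pure function of (config, seed).

What the phantom does **not** model: physically realistic OCT speckle
statistics, pathology (drusen, fluid, atrophy), segmentation errors (the
supplied surfaces are exact unless a test corrupts them deliberately),
vessel pulsation or motion artefacts, and the true appearance gap between
an SLO and an OCT projection. Passing phantom tests therefore demonstrates
the *geometric and numerical* correctness of the pipeline and the
trainability of the objective — not clinical-grade accuracy on real scans,
where segmentation quality and pathology dominate the error budget.

## Desk-scale problem sizes

The test suite and the acceptance script run the whole pipeline at reduced
size, chosen once as a realistic miniature: 50 training projections
(~96 x 96 px at 62.5 µm), the desk training preset above, and 10 held-out
default-size phantom pairs registered multimodally (SLO vs hybrid
projection) with a 3000-iteration, 125 µm (= 2 moving-pixel) RANSAC and
median-quantile keypoint thresholds. On one CPU core this trains in a few minutes
and registers each pair in seconds. Under these conditions the trained
desk network reaches sub-pixel median landmark error and Dice above 0.99
with column shifting; the acceptance script recomputes these numbers from
scratch on every run.

## Known limitations

* The 2D stage is the single point of failure: if it fails (by the failure
  rule or RANSAC consensus), the axial stage is not attempted — axial
  registration cannot repair a wrong en-face alignment.
* Column shifting trusts the segmentation completely; LPM trades exactness
  for robustness. Neither uses neighbouring B-scans for context, and no
  deformable axial model is provided.
* The network, trained at desk scale on phantoms, transfers only to images
  statistically similar to those phantoms; real multi-device use requires
  retraining (`--preset paper`) on real projections.
* Surfaces are consumed as given; missing cells propagate as invalid
  rather than being interpolated, because silent in-fill would hide exactly
  the segmentation errors that corrupt axial registration.
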