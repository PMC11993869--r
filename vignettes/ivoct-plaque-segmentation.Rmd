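---
title: "Histology-style plaque-subtype segmentation of polar IVOCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-style plaque-subtype segmentation of polar IVOCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ivoctseg)
```

## The problem

Intravascular optical coherence tomography (IVOCT) images coronary artery
walls at roughly 10 µm resolution from a rotating catheter. Each full
rotation yields a B-scan stored natively in polar coordinates: rows are
A-lines (angles), columns are radial depth samples. Atherosclerotic plaque
appears in these images as characteristic intensity and attenuation
patterns, but subtypes that pathologists distinguish on histology — lipid
pool, calcified lipid, fibrofatty tissue, calcified fibrous tissue —
are hard for human readers to separate on OCT alone. `ivoctseg`
implements a complete, testable pipeline for learning per-pixel subtype
segmentations in the polar domain: a synthetic phantom generator standing
in for coregistered clinical data, lumen-justified preprocessing,
three-category mask construction, a circular-padded attention U-Net
trained with a Tversky focal loss under artery-grouped splits, and
Dice / A-line sensitivity–specificity evaluation.

Every stage is exercised against phantoms with known ground truth, which
is the only way the full loop can be validated without a private
histology-coregistered dataset.

## Coordinate conventions

Stated once, used everywhere: matrices are A-lines × depth; row `i`
corresponds to angle `2π(i−1)/n_alines` and the row axis is periodic
(A-line `n` is adjacent to A-line 1); column 1 is the catheter-proximal
sample; indices are 1-based. A lumen contour stores, per A-line, the
column of the first tissue pixel.

## The phantom generator

The generator is first-class, tested code: its output defines the study
conditions for every downstream stage.

**Image physics.** A single-scatter exponential-decay model. Along each
A-line, mean intensity beyond the lumen is
`base_reflectivity · exp(−2 Σ μ)` where the sum accumulates the per-pixel
attenuation coefficients of the tissues traversed from the lumen boundary
(exclusive of the current pixel), multiplied by gamma-distributed
multiplicative speckle with mean 1 (shape 4 by default, i.e. ~50%
intensity SD, spatially correlated over each tissue's texture scale) and
offset by an additive noise floor. No wave simulation is attempted; the
point is to create the attenuation and texture contrasts the classifier
must learn, at desk scale.

**Tissue table.** At the default 5 µm axial pixel (chosen so that a
200-pixel crop spans ~1 mm; the scanner's true spacing is configuration,
not fact), `default_tissue_models()` sets, per class
(attenuation per pixel / entry reflectivity / border width px):
fibrous 0.010 / 1.00 / 1.5; lipid pool 0.032 / 1.25 / 6; fibrofatty
0.020 / 1.10 / 5; calcified lipid 0.007 / 0.40 / 1; calcified fibrous
0.006 / 0.45 / 1. These encode the field's qualitative contrasts:
calcium is weakly attenuating with a dark interior and sharp borders;
lipid pools attenuate fast (deep shadowing) behind a bright entry with
diffuse borders; fibrofatty sits between fibrous and lipid pool —
deliberately overlapping lipid pool so that the phantom reproduces the
lipid-pool/fibrofatty confusability that is the known hard case.
A consequence worth noting: the two calcified subtypes are nearly
identical optically (as their shared composition suggests), so
single-subtype calcium targets are close to ill-posed on phantoms and the
combined calcium group is the natural calcium detection target.

**Geometry and hierarchy.** Default frames are 504 A-lines × 976 depth
pixels. The lumen contour is an eccentric, low-order-harmonic perturbed
circle. `generate_dataset()` organizes frames as hearts → arteries →
frames and, per frame, samples each plaque class independently with its
configured prevalence (defaults 0.50 lipid pool, 0.25 calcified lipid,
0.40 fibrofatty, 0.45 calcified fibrous — calcium-enriched, as a calcium
study set would be), placing present classes as angularly disjoint
inclusions whose spans may wrap across the polar seam. `(config, seed)`
determines every output bit-identically.

**What the phantom does not emulate.** Guidewire shadows, catheter
reflections, NURD, blood residue, stents, cartesian acquisition. Passing
tests on phantoms therefore demonstrates that the pipeline's machinery is
correct and that the model family can recover known contrasts — not
clinical performance.

## Preprocessing

**Lumen detection** (`detect_lumen()`): per A-line, the first depth where
a *trailing* running mean (window 5) exceeds an adaptive threshold placed
15% of the way from the frame's 20th to its 98th intensity percentile.
The trailing window matters: a centered window crosses an ideal step
early, a trailing one crosses exactly at the step, so the detector is
exact on noise-free phantoms. Empty A-lines are interpolated circularly;
the contour is then despiked by a circular Hampel filter (window 11,
tolerance 3 px) — outliers are replaced by the local circular median,
in-band values pass through untouched, preserving exactness. On default
phantoms the mean absolute error against generator truth is well under
3 px.

**Flattening** (`flatten_frame()`): each A-line is shifted so the lumen
boundary lands at column 1 and the first 200 px (~1 mm, the useful OCT
penetration depth) are kept. Shifts are whole-pixel gathers, no
interpolation, making `unflatten_frame()` an exact inverse on the cropped
band — essential for scattering predicted masks back to the full polar
frame without label corruption. `polar_to_cartesian()` renders results
for viewing (nearest neighbour is mandatory for label maps so no label
values are invented); `log_display()` provides the standard `log(1+I)`
display transform.

**Attenuation boundary** (`estimate_attenuation_boundary()`): beyond some
depth the signal has decayed into noise and tissue is unreadable; those
pixels must not train or score. Per A-line the boundary is the first
depth at which the smoothed intensity falls below
`lo + 0.08 (hi − lo)` (2nd/98th frame percentiles) and stays below for
10 consecutive pixels. The annotation workflow this replaces was likely
manual; per-frame boundary files can be supplied instead through the
`boundary` argument of `prepare_training_samples()`.

## Masks and the label vocabulary

Label maps use a fixed palette (0 lumen, 1 fibrous, 2 lipid pool, 3
calcified lipid, 4 fibrofatty, 5 calcified fibrous). Combined groups pool
lipid pool + calcified lipid + fibrofatty (lipid analysis) and calcified
lipid + calcified fibrous (calcium analysis); calcified lipid belongs to
both. One model is trained per target class or group;
`combine_labels()` collapses the map to a binary target first.

`build_training_mask()` produces the three training categories with a
total precedence order: **exclusion** (inside the lumen or beyond the
attenuation boundary — even where an annotation extends past it) wins
over **target**, which wins over **background** (fibrous plus plaque
classes not currently trained). The loss and all metrics are computed
over non-exclusion pixels only, and the tests assert that perturbing
excluded pixels changes nothing, bit for bit.

## The network

A U-Net-type fully convolutional encoder–decoder
(`unet_config()`, default 4 levels, 16 base channels, ~1.8 M parameters):
double 3×3 convolution blocks, 2×2 max pooling, nearest-neighbour
upsampling with a 1×1 projection, skip concatenation, 1×1 + sigmoid head.
Three properties deserve comment.

* **Circular padding.** Every convolution pads the angular axis by
  wrapping (the polar seam is physically continuous); the depth axis pads
  with zeros (reflection available). The testable consequence: shifting
  the input rows by any multiple of the total stride shifts the output
  identically — seam continuity by construction, which the suite checks
  to 1e-4.
* **Attention gates** on the two deepest skip connections (the "middle
  layers"): additive attention with the decoder feature as query and the
  skip as key, `x · σ(ψ(ReLU(W_g g + W_x x)))`. A self-attention
  bottleneck was the other reading of the phrase; gates are the simpler
  mechanism and are exposed by the `attention` flag.
* **Instance normalization.** Each conv block is conv → IN → ReLU. This
  is a deliberate addition: without normalization the from-scratch
  network is unstable at phantom scale (validation Dice collapses after
  the first epochs). Instance norm is batch-size independent and its
  statistics are invariant to circular row shifts, so it preserves the
  seam-equivariance property exactly. Under IN the conv bias is inert and
  its gradient is identically zero; the learned IN gain/bias take its
  place.

Inputs are `log1p`-compressed and standardized with training-set
statistics stored on the model sidecar; the 200-px crop is
reflect-padded to 208 so both axes divide the stride, and predictions are
cropped back.

The numerics are single precision. The heavy kernels (im2col GEMM
convolutions, pooling, fused conv+IN+ReLU, and a whole-network
forward/backward) are compiled; an R layer-by-layer composition of the
same network is kept in the package as the independent reference, and the
test suite checks the two agree to float precision and that analytic
gradients match central finite differences.

## The objective

The Tversky focal loss `(1 − TI)^γ` with
`TI = (TP + s) / (TP + α FP + β FN + s)` over soft counts restricted to
valid pixels; `α = β = 0.5, γ = 1` recovers `1 −` soft-Dice, which the
tests verify to 1e-9. Parameters are per plaque type
(`default_loss_params()`; the rarer calcified subtypes and fibrofatty get
`α = 0.7, β = 0.3, γ = 4/3`, others soft-Dice), all overridable in the
experiment YAML — the procedure "optimize per type" is what the package
reproduces, since no published values exist. The index is computed over
the pooled batch and then exponentiated (the alternative, per-image
focal terms averaged, is a config-level change away in
`train_model()`'s loss closure); gradients are analytic.

## Training, splits, selection

`make_splits()` assigns whole arteries, never frames, to
train/validation/test (70/15/15 by default) — frames from one artery are
strongly correlated and splitting them would leak. `random_grouped`
shuffles arteries under the seed and fills the largest remaining
frame-count deficit; `stratified_grouped` additionally minimizes the
maximum per-class prevalence deviation across splits, processing
rarest-class arteries first, which spreads sparse subtypes across splits
when the artery layout permits. Realized proportions that miss the
request by more than the tolerance produce a warning, not an error,
because artery granularity can make exact ratios impossible.

`train_model()` runs the reference schedule — 60 epochs, Adam from
lr 1e-4, plateau reduction ×0.5 with patience 4 on validation loss —
with whole flattened frames in batches of 8 and label-safe circular
angular rolls as the only augmentation. After every epoch the validation
Dice (pixel-pooled at threshold 0.5) is logged; the returned weights are
those of the best epoch (and restart, when `n_runs > 1`) by validation
Dice. All randomness — init, batch order, rolls — derives from one seed,
and two identical invocations produce identical histories and weights.

## Evaluation

`dice_coefficient()` is the Sørensen-Dice overlap on valid pixels;
frames where prediction and truth are both empty are degenerate (a
correct all-negative frame scores 1 but is excluded from the frame-mean).
`evaluate_dataset()` reports frame-mean Dice as the headline with
pixel-pooled Dice logged alongside — the two differ exactly when
performance varies with target size, so both are kept. A-line metrics
reduce each mask to per-A-line labels (positive iff ≥ `min_pixels` valid
positive pixels, default 1 — the most permissive rule, since the
reduction itself is not standardized) and pool confusion counts over all
frames before computing sensitivity and specificity; fully excluded
A-lines are dropped, and empty denominators yield `NA`, never 0. A
brute-force per-row enumeration backs the vectorized implementation in
the tests.

## The scaled-down recovery experiment

The acceptance suite trains on phantoms at a reduced size chosen to keep
the whole protocol within a desktop CPU budget: 200 frames of
128 A-lines × 256 depth px (crop 200) from 20 arteries in 10 hearts,
split 80/20 by artery; targets combined calcium, lipid pool, and
fibrofatty; a depth-3 / base-8 instance of the architecture; soft-Dice
loss; 7 epochs of Adam at lr 3e-3 in batches of 4 (a higher rate and
more optimizer steps than the clinical-scale default, appropriate for
the smaller, cleaner task); 3 seeds, median of the frame-mean Dice
reported. Expected behaviour: calcium-group Dice ≥ 0.8, lipid-pool
Dice ≥ 0.7, and fibrofatty strictly below lipid pool — the phantom's
built-in confusability reproducing the field's fibrofatty failure mode
qualitatively. `scripts/acceptance.R` re-runs a one-seed version of the
same experiment from scratch.

## Numerical and degenerate-input choices

* Flattening: integer gather; contours violating
  `1 ≤ boundary ≤ depth − crop + 1` are an error naming the A-line.
* All-zero frames: `detect_lumen()` errors ("no lumen found"); an A-line
  at the frame's noise floor gets attenuation boundary 0.
* Empty valid mask: Tversky index 1 by the `s/s` convention, flagged
  degenerate; evaluation ratios with empty denominators are `NA`.
* Binarization threshold 0.5 everywhere, configurable; mask positives are
  non-increasing in the threshold.
* Max-pool ties break toward the first element in column-major order;
  ties are measure-zero under the phantom's continuous intensities.
* Overlapping inclusions of different classes error unless an explicit
  priority order is supplied.

## Known limitations

Phantom realism is deliberately limited (see above); detection thresholds
are tuned to the phantom's contrast regime and would need revisiting for
scanner data; the lumen detector assumes a visible interface on most
A-lines; training whole frames (no patching) bounds memory but couples
the angular extent to the architecture's stride; no GPU path exists, so
clinical-scale training (hundreds of 504×976 frames, 60 epochs) is
out of reach of this implementation's intended desk-scale use.
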