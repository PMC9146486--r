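---
title: "Methods: cascaded compressed U-Net segmentation of intraretinal layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded compressed U-Net segmentation of intraretinal layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Intraretinal layer thicknesses measured on macular OCT volumes are
noninvasive biomarkers of neurodegeneration and neuroinflammation (multiple
sclerosis, NMOSD, glaucoma). The layers of interest are thin (the outer
plexiform layer and myoid zone are ~30 µm, a few pixels at typical axial
sampling), tissue gradients are weak, and speckle noise is multiplicative,
so segmentation must be both accurate at the boundary level and cheap enough
to run without a GPU. `octlayers` implements a two-stage cascade of
*compressed* U-Nets: a retina-segmentation network (RS) first separates
vitreous / retina / sub-retinal space from a B-scan, and an intraretinal
network (IS) receives the image plus the RS map as a second channel and
produces a 9-class map — vitreous, the seven bands mRNFL, GCIPL, INL, OPL,
ONL, MZ, OL, and below Bruch's membrane — from which eight boundary surfaces
(ILM, RNFL-GCL, IPL-INL, INL-OPL, OPL-ONL, ELM, EZ-OS, BM) are extracted.

## Architecture and parameter budget

Both stages instantiate one template: a 4-stage encoder with two f×f
same-padded convolutions and ReLU per stage, channel depth doubling from a
base depth c while 2×2 max pooling halves the grid; dropout after stages 3
and 4; a decoder of 2×2 stride-2 transposed convolutions that halve the
channel depth, concatenation with the matching encoder skip, and two more
f×f convolutions; and a 1×1 output convolution with per-pixel softmax. No
batch normalization. The RS preset is f=5, c=4, n=1 input channel, o=3
classes (79,007 trainable parameters, "79K"); the IS preset is f=5, c=16,
n=2, o=9 (1,260,777, "1.2M"). The classic reference U-Net is the same
template with 5 stages, f=3, c=64 (31,030,723 for n=1, o=3, "31M"), making
the RS stage ~393× smaller. These choices are not free: with additive-skip
merging, parameter-free upsampling, or one convolution per stage, the
analytic layer-by-layer count no longer reproduces the published table of
variants (0.31M, 0.12M, 1.9M), which is how the template details were pinned
down. One published variant (f=3, c=16 printed as "48K") contradicts the
c² scaling law every other row obeys (the formula gives ≈0.49M); we treat it
as a typo and exclude it. The phrase that channel depth "increases up to
four times" is likewise inconsistent with the counts, which require strict
doubling over four stages.

`count_trainable_parameters()` sums the allocated arrays of a built model;
`count_params_analytic()` is an independent closed-form accounting. The test
suite requires them to agree exactly for every configuration.

## Why the engine is hand-built

No deep-learning framework is available in the target R environment, so the
package carries a minimal CNN engine (im2col convolutions running on BLAS
GEMM in single precision, hand-written backward passes, Adam). The engine is
validated three ways: convolution and pooling against naive R loop oracles,
the loss gradient against central finite differences (double precision, at
the logit level, within 1e-4 relative), and whole-network finite-difference
probes. Single precision in the convolutions costs nothing measurable in
training quality and doubles throughput on one CPU core.

## Loss

Class imbalance is severe: seven of nine classes each cover under 10% of the
training pixels. Training minimizes a focal loss; per pixel with true class
t, the contribution is −a·(1−p_t)^γ·log p_t with defaults α = 0.25, γ = 2.
The weighted form replaces α per class with w_t = 1 − n_f/n_t, the
complement of the class's pixel fraction pooled over the whole training set
(not per batch — pooling matches how the published frequency table is
global). Two printed details required interpretation. First, the published
formulas omit the leading minus sign; we implement the standard negated form
(non-negative, minimized), since the positive form would be maximized
away from the data. Second, a literal reading of the p_t definition ("1−p_c
otherwise") would add background terms for every class at every pixel, but
that contradicts both stated reductions — γ=0, α=1 must equal categorical
cross-entropy, and the single-pixel hand value 0.25·0.25·ln 2 — so only the
true-class term contributes, which is the standard multi-class focal loss.
Aggregation is mean over pixels within each class term, then sum over
classes, so per-class weights keep their meaning regardless of image size.
Probabilities are clipped to [1e-7, 1−1e-7]; clipped entries carry no
gradient.

## Training protocol

Adam with a fixed learning rate of 0.001, epoch cap 80, early stopping on
validation per-pixel accuracy with the best-epoch weights restored. Patience
(10 epochs) and batch size (8) are defaults the source protocol leaves open;
both are configurable. The IS stage is trained with teacher forcing — the
ground-truth 3-class map as channel 2 — and evaluated with the predicted RS
output, matching the cascade semantics at inference. The RS output enters
the IS stage as a hard label map encoded {0, 0.5, 1} rather than as
probabilities: the cascade's published diagram shows a hard-colored 3-class
map as the second input, and the encoding keeps both channels in [0,1].

## Postprocessing

The 9-class map is turned into eight clean surfaces in a fixed order:

1. **Adaptive hole filling.** Per class, with n_n nonzero and n_z zero
   pixels of the class mask, the divisor f starts at 2 for the outer classes
   and 10 for interior ones and grows until n_n/f < n_z; components of the
   mask or its complement smaller than T = n_n/f are removed or filled.
   Removed foreground islands are reassigned to the majority label of their
   border so the map remains a partition (the source describes removal only;
   a partition is required downstream).
2. **Boundary extraction**: topmost row of each region per column; absent
   regions yield missing values.
3. **Laplacian outlier rejection** on per-layer thickness maps (the literal
   reading of "Laplacian of the thickness values"; the alternative — surface
   heights — would also flag genuine foveal curvature). The 5-point stencil
   is evaluated per axis where both neighbors exist. The threshold τ = 20 µm
   is not specified by the source; it was chosen once as larger than
   speckle-induced thickness curvature and smaller than genuine segmentation
   spikes, and is configurable. Negative thicknesses (boundary crossings)
   are always flagged — anatomically impossible.
4. **PCHIP infill** along A-scans per B-scan (Fritsch–Butland slopes:
   passes through knots, reproduces linear spans exactly, preserves
   monotonicity), constant extrapolation beyond the outermost knots, and a
   nearest-B-scan copy for rows with fewer than two knots.
5. **3×3 box smoothing** over the (B-scan, A-scan) grid with edge
   replication. Box smoothing is a projection only on locally affine
   surfaces; on curved regions (the pit) it contracts curvature slightly, so
   strict chain idempotence holds on flat/affine surfaces and is tested
   there.
6. **Ordering constraint**: sequential top-down projection
   b_k ← max(b_k, b_{k−1}).

## The phantom: a stated world

The published training corpus (17,458 clinical B-scans) is private, so the
package generates synthetic B-scans with exact ground truth. The phantom
states, once, a world chosen to be realistic rather than convenient:

* geometry — 512×512 canvas at 3.87 µm/px axial and 11.7 µm/px lateral
  (typical Spectralis values), 25 B-scans 240 µm apart, ~6×6 mm field;
* layer thickness means (µm): mRNFL 35, GCIPL 70, INL 35, OPL 30, ONL 80,
  MZ 30, OL 60 — healthy macular averages, total ≈340 µm;
* a Gaussian foveal pit (depth 120 µm, σ 350 µm) implemented by pinching the
  four inner layers toward zero at the center, which is what produces the
  ILM dip over flat outer bands in real maculae;
* smooth low-frequency thickness and baseline variation (5 µm jitter) drawn
  once per volume so surfaces are smooth across B-scans;
* reflectivity bright for mRNFL/OPL/MZ/OL and dark for the nuclear layers;
  Gaussian blur (σ 1 px) then multiplicative gamma speckle (shape 8,
  mean 1, ≈35% coefficient of variation — a low-to-average-SNR scan);
* pathology hooks the training data is described to contain: a thin-RNFL
  flag (mRNFL scaled to 40%) and hyporeflective INL microcysts that darken
  the image without changing labels (graders count cysts as INL).

What the phantom does **not** emulate: vessel shadows, optic-nerve-head
remnants, motion/cut artifacts, AMD/DR structural pathology, and real
inter-grader label noise. A green benchmark therefore establishes that the
implementation learns and recovers the stated world end to end — not
clinical-grade performance, which the published clinical tables describe and
which cannot be reproduced without the private data.

## The scaled-down benchmark

The end-to-end check runs at desk scale: 128×128 phantoms with the pixel
scales enlarged fourfold (the field of view stays ~6×6 mm), 300/50/50
train/validation/test B-scans, RS at c=4 and IS at c=8. On one CPU core the
engine sustains roughly 80 s (RS) and 160 s (IS) per 300-image epoch, so the
benchmark trains with batch size 4 (75 optimizer steps per epoch — the
engine converges on this task in a few hundred steps) and at most 3 epochs
per stage with patience 2, well under the 20-epoch ceiling, keeping the full
benchmark near 12–14 minutes. Dropout is 0.25 in the benchmark
configuration (the preset default 0.5 is aimed at the full-size networks;
the scaled-down networks have a quarter of the channels). Thresholds: mean
9-class Dice ≥ 0.85, mean boundary error ≤ 2 px, and recovery of
ground-truth surfaces from maps corrupted with 1% random relabelings and
0.5% boundary spikes to ≤ 1 px MAE. About 0.5 px of the boundary error
budget is inherent quantization: class maps are integer-valued, so extracted
boundaries sit on pixel rows while the generating surfaces are continuous.

## Numerical and interface choices

* Rows are axial with row 1 at the top (R's 1-based convention; surfaces
  are 1-based sub-pixel row coordinates everywhere, including CSV output).
* The evaluation region for thickness parameters is a 5 mm **diameter**
  circle centered on the fovea (the convention of the authors' correction
  toolbox); the diameter is a parameter.
* ICC is ICC(1,1) from one-way ANOVA variance components with F-bound
  confidence intervals.
* Volumes are mean thickness × region area; on the uniform grids used this
  equals the per-sample Riemann sum.
* The fovea is located by per-B-scan least-squares parabola fits of the ILM
  row over the central half of the A-scans; only downward-opening fits
  (pit-shaped, in row coordinates) compete, by fitted vertex depth. If no
  B-scan produces a pit-shaped fit the deepest raw grid sample is used and
  flagged — raw samples and fitted depths are never compared against each
  other, because speckle spikes in the raw grid would always win.
* Proprietary device formats are not parsed; volumes are exchanged as PNG
  directories or HDF5 containers. PNG output is 8-bit (the available writer
  does not emit 16-bit); 16-bit PNGs are normalized correctly on read.

## Known limitations

The engine is CPU-bound and single-threaded beyond BLAS; full-size (512×512,
c=16) training is feasible but slow (hours, not minutes). The phantom's
speckle is spatially white, while real OCT speckle is correlated at the
point-spread-function scale, so the benchmark somewhat understates the
difficulty of boundary localization in real scans. The quality gate is a
pass-through hook: learned quality scoring is out of scope.
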