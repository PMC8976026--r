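---
title: "Methods: automated abdominal fat compartment segmentation and quantification"
author: "adiposeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated abdominal fat compartment segmentation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adiposeg)
```

## The problem

On T1-weighted abdominal MRI, adipose tissue is hyperintense. Two
compartments matter clinically: **subcutaneous adipose tissue (SAT)**, the
bright annulus between skin and abdominal muscle wall, and **visceral
adipose tissue (VAT)**, the bright blob-like fat surrounding the organs
inside the peritoneal cavity. Their volume ratio VAT/SAT is a body
composition biomarker: it shifts in catabolic neurodegenerative conditions
such as amyotrophic lateral sclerosis, where weight loss and metabolic
status predict survival. Quantifying the two compartments manually is slow
and poorly reproducible; this package automates the whole chain — from
multi-station volume stitching to group-level statistics — and validates it
on a synthetic phantom cohort with known ground truth, because clinical MRI
data of this kind are generally not redistributable.

## Processing chain

### Multi-station acquisition and stitching

Whole-body protocols acquire 6–8 overlapping 3-D stations (about 36 slices
of 6 mm at 1.25 × 1.25 mm² in-plane per station), with a 1–3 slice overlap
between consecutive stations. `registerStations()` estimates, per junction,
a 3-degree-of-freedom translational shift (x, y, z) by minimising the mean
squared intensity difference over the shared overlap slices. The optimiser
is a restarted Nelder–Mead simplex: a coarse scan over integer shifts first
places the simplex in the correct basin (the z cost profile is multi-modal
when only 1–3 slices overlap), then the simplex refines from the best
coarse point and from seeded perturbations of it. Fractional shifts are
evaluated with trilinear interpolation.

Two practical constraints are worth stating plainly:

* A z shift close to or larger than the overlap physically removes the
  shared content between stations — no registration method can recover it.
  Validation therefore injects z shifts strictly smaller than the overlap,
  while in-plane shifts go up to 3 voxels. This matches acquisition
  reality: the table position controls z, so inter-station motion is
  predominantly in-plane.
* `mergeStations()` resolves each overlap by keeping the superior station's
  slices ("superior wins"); averaging is available via `blend = "average"`.
  Overwriting is deterministic and avoids double-counting; with exact
  registration on clean data both options reproduce the source volume.

### Supersampling and filtering

`supersample()` resamples the anisotropic grid to 1.2 mm isotropic voxels
(trilinear for intensities; nearest-neighbour for label maps so classes
stay in {0, 1, 2}). Output dimensions are `round(dim * spacing / 1.2)`, so
36 slices at 6 mm become 180 slices, and resampling an already-isotropic
1.2 mm volume is the identity. `medianFilterVolume()` applies a 3×3×3
voxelwise median (reflected edges) to homogenise intensities; the kernel
size is configurable — 3 is the smallest isotropic choice.

### Body mask

`bodyMask()` thresholds at an intensity quantile (default 0.6), keeps the
largest connected component per axial slice and fills interior holes. The
largest-component rule automatically removes disconnected lateral
structures — the role that manual arm deletion plays in interactive
protocols. Phantoms are armless by construction, so this rule is exercised
with synthetic distractor blobs in the tests.

### Reference segmentation (intensity range + connectivity)

The reference method is a fully automatic surrogate of semi-automatic
intensity-driven protocols:

1. `estimateFatRange()` fits a kernel density to the intensity histogram
   inside the body mask. Fat, being hyperintense on T1w, forms the upper
   mode. The returned range is `[mode − k·(mode − valley), max]` with
   `k = 0.5`; a histogram without a resolvable second mode is an error that
   advises a manual range.
2. `segmentSAT()` selects in-range voxels within a morphological band
   (default 30 mm) inside the body surface whose 26-connected component
   touches the boundary layer.
3. `segmentVAT()` selects in-range voxels in the remaining cavity, grouped
   by 26-connectivity, dropping components below 5 voxels.

SAT and VAT are disjoint by construction. Bright bone rims inside the
cavity fall within the fat intensity range and are deliberately **not**
excluded: intensity-only methods misread hip bones as VAT, and the phantom
reproduces exactly this failure mode so the comparison between reference
and network segmentation is realistic.

### The encoder–decoder network

`buildUNet()` constructs a U-Net-like fully convolutional network: three
down-sampling steps with 16/32/64 feature channels in the contracting path
(two 3×3 same-padded convolutions with rectified-linear activation per
level, 2×2 max-pooling), a bottleneck, and an expanding path of 2×2-stride
transposed convolutions with skip concatenations, ending in a 1×1
convolution and per-pixel softmax over the three classes (background, SAT,
VAT). Input and output are 384 × 384 at full scale. Training
(`trainUNet()`) minimises categorical cross-entropy with adaptive moment
estimation (Adam), 15 epochs and batch size 16 at full scale, and is fully
seeded (weight initialisation, data order, dropout), so runs are
bit-reproducible. All layer primitives (im2col/GEMM convolution,
max-pooling, transposed convolution, with analytic backward passes verified
against central differences in the tests) are implemented in the package's
compiled code.

Choices the architecture description leaves open, fixed here once:

* **Bottleneck width 128**, continuing the channel-doubling pattern.
* **Same padding** everywhere — input and output share the 384 × 384 grid,
  which rules out valid-padding-and-crop.
* **Dropout rate 0.5 at the bottleneck only.**
* **Rectified linear** nonlinearity, standard for this architecture.
* **Per-volume min–max normalisation** of intensities to [0, 1] before
  training and inference; some normalisation is required for stable
  optimisation.
* **No data augmentation**, no early stopping (a fixed epoch count;
  validation loss is recorded but not used for model selection).
* Learning rate is exposed in `trainConfig()` (default `1e-3`, the common
  Adam default).

`splitDataset()` assigns whole subjects (never slices) to
train/validation/test at 50 % / 6 % / 44 %, stratified by age tertile ×
BMI tertile × group with a greedy largest-deficit rule, so global
fractions are exact up to rounding; strata with fewer than 3 subjects fall
back to a global assignment with a warning.

### Evaluation metrics

For reference mask $R$ and predicted mask $P$ of one class on one slice:

$$\mathrm{dice} = \frac{2\,|R \cap P|}{|R| + |P|}, \qquad
  E = 100 \cdot \frac{|R \,\triangle\, P|}{W \cdot H}\ \%$$

where $\triangle$ is the symmetric difference and $W \times H$ the image
size. The pixel error is implemented from its verbal definition — the
fraction of image pixels on which the two label maps disagree. (A
frequently reprinted closed form, $E = 1 - |RP|/(W\!\cdot\!H)$, evaluates
near 100 % for any sparse class and contradicts both the verbal definition
and the ~1–4 % values such tables report; it is noted here and not used.)
Metrics are averaged per class over all slices of all examinations
(`evaluateExamination()`, `aggregateGroupMetrics()`); slices where both
masks are empty for a class are excluded from that class's average rather
than scored 1.0 — the choice shifts means, so it is config-switchable
(`excludeEmpty`). A volumetric Dice per examination is available as a
secondary readout (`volumetricDice()`).

### Quantification and statistics

`fatVolumes()` converts voxel counts to millilitres via the voxel volume
(so 1000 voxels at 1.2 mm isotropic are exactly 1.728 mL), and the VAT/SAT
ratio is invariant under uniform spacing rescaling. Group comparisons use
the classical equal-variance two-tailed Student's t-test (Welch's form
behind a flag), significance at p < 0.05, error bars as SEM = SD/√n;
method agreement uses the Pearson correlation between reference and
predicted volumes per group (`cohortReport()`).

## The phantom generator

`phantomGroupConfig()` / `renderPhantom()` produce the synthetic study
conditions. Each subject is an elliptical body whose outermost band of
width `satThickness` is SAT; the interior holds organ-intensity tissue and
`nVatBlobs` bright ellipsoidal VAT blobs whose summed cross-section
targets `vatFraction` of the cavity volume (analytically calibrated;
monotone in `vatFraction` at fixed seed). Optional bone confounders — a
posterior midline spine on all slices and lateral "hip" ellipses on
inferior slices — have a dark core and a bright, deliberately fat-like rim
labelled background in the truth. Intensities (fat 200, organ 100,
background 0, bone core 40 / rim 180, arbitrary units) are then modulated
by a random 2nd-order polynomial multiplicative bias field (amplitude 0.10
by default) and corrupted by Rician noise (σ = 3 % of the fat intensity),
the noise model of magnitude MRI. The label map is the noise-free ground
truth.

Group defaults encode the intended cohort contrast: controls with SAT
thickness 18 ± 3 mm and VAT fraction 0.14 ± 0.04, patients with 14 ± 3 mm
and 0.30 ± 0.07 (age 60 ± 13 years in both; BMI 26 ± 4 vs 24 ± 4
kg/m²) — relatively more visceral and less subcutaneous fat in patients,
hence an elevated ground-truth VAT/SAT ratio. These values were fixed when
the generator was written and are not tuned against test outcomes.

**What the phantom does not emulate** — and therefore what passing tests do
not demonstrate about clinical data: real organ anatomy and its intensity
heterogeneity, chemical-shift and motion artifacts, partial-volume mixing
at fat boundaries, arms, and the inter-scanner variability of intensity
scales. The phantom validates the machinery (geometry handling,
optimisation, metrics, statistics) and the qualitative failure modes
(bone–fat confusion, bias-field broadening of the histogram), not clinical
accuracy.

## Scaled experiment sizes

Desk-scale runs keep every architectural and optimisation choice but
shrink the problem: 16 + 16 subjects of 10 slices at 128 × 128
(1.25 × 1.25 × 6 mm voxels), encoder channels 8/16/32 with bottleneck 64,
10 epochs at batch 16. At this scale the optimiser takes only ~100 steps,
two orders of magnitude fewer than a full-scale training, so two
parameters are set accordingly and documented here: learning rate
5 × 10⁻³ (Adam converges too slowly at 1e-3 within ~100 steps) and
per-class loss weights (1, 2, 8) for background/SAT/VAT — VAT is ~2 % of
pixels and is otherwise ignored by the unweighted loss at this step
budget. With these, held-out performance reproduces the characteristic
ordering of fat segmentation networks: SAT Dice near 0.97–0.98, VAT Dice
near 0.75–0.80, SAT ≫ VAT — visceral fat, fragmented and confusable with
bone rims, is the harder class.

The cohort-level readout (34 + 34 subjects per seed, 20 seeds) runs the
generation → median filter → reference segmentation → quantification →
t-test chain at 56 × 56 × 5 (3 × 3 × 6 mm) geometry. Phantoms for this
experiment are rendered as single stations: stitching is validated
separately with injected known shifts, and the ratio contrast is
independent of it. Training a network per seed is deliberately avoided;
the network route is exercised end-to-end once in the scaled segmentation
experiment, and the reference route — which the volumes of both groups
pass through identically — carries the per-seed statistics.

## Numerical choices and degenerate inputs

* Dice of two empty masks is undefined (`NA`), never 0 or 1 silently.
* `vatSatRatio()` errors on zero SAT volume rather than returning Inf.
* The t-test refuses zero pooled variance and groups of n < 2; Pearson
  refuses constant input and n < 3.
* Mask codec: class values outside {0, 1, 2} and pixel values outside
  {0, 127, 255} are errors naming the offending value; the codec is exact,
  so encode/decode roundtrips are identities.
* Resampling aligns voxel centres at `index × spacing` with edge
  replication outside the field of view; argmax ties in prediction break
  toward the lower class index (background first).
* Registration reports best-so-far shifts with `converged = FALSE` when
  the iteration cap is hit; candidate z shifts that empty the comparison
  domain receive a large finite penalty instead of NaN.

## Known limitations

* The reference surrogate is intentionally simple (range + connectivity);
  it reproduces the workflow and its bone-confusion failure mode, not any
  specific proprietary implementation.
* Registration is 3-DOF translation only — no rotation, no deformation.
* The compiled network primitives are CPU-only and double-precision;
  full-scale (384 × 384, 16/32/64, 15 epochs, tens of thousands of slices)
  training is possible but slow on a single CPU; the package's validation
  uses the scaled configuration above.
* Phantom realism limits are listed above; clinical performance claims
  require clinical data.
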