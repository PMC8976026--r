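# adiposeg

Automated discrimination and quantification of abdominal body-fat
compartments — subcutaneous adipose tissue (**SAT**) and visceral adipose
tissue (**VAT**) — on T1-weighted-like MRI volumes, in R.

On T1-weighted images fat is hyperintense: SAT forms a bright annulus
between skin and the abdominal muscle wall, VAT the bright blobs around the
organs inside the cavity. Their volume ratio VAT/SAT is a body-composition
biomarker used in neurodegenerative disease research, where catabolism
shifts fat from the subcutaneous to the visceral compartment. The package
is aimed at researchers who need a reproducible, fully scripted pipeline
from raw multi-station volumes to group statistics, plus a synthetic
phantom cohort with known ground truth to validate every stage when
clinical data cannot be shared.

## What it implements

* **Preprocessing** — 3-degree-of-freedom translational registration of
  overlapping acquisition stations (restarted Nelder–Mead simplex on the
  mean squared overlap difference), station merging, supersampling to
  1.2 mm isotropic voxels, 3×3×3 median filtering, and automatic body-mask
  extraction (`registerStations`, `mergeStations`, `supersample`,
  `medianFilterVolume`, `bodyMask`).
* **Reference segmentation** — a fully automatic intensity-range +
  26-connectivity method: the fat range is read off the upper mode of the
  body-intensity histogram; SAT is surface-connected in-range tissue, VAT
  is range-connected tissue in the cavity (`referenceSegment`).
* **Encoder–decoder network** — a U-Net-like CNN (three down-sampling
  steps, 16/32/64 encoder channels, skip concatenations, transposed-conv
  upsampling, bottleneck dropout, per-pixel 3-class softmax), trained with
  categorical cross-entropy and Adam, batch 16 — implemented from compiled
  primitives in the package, fully seeded and CPU-reproducible
  (`buildUNet`, `trainUNet`, `predictVolume`).
* **Evaluation** — per-slice Dice `2|R∩P|/(|R|+|P|)` and pixel error
  `100·|R△P|/(W·H)` %, aggregated per examination and group
  (`evaluateExamination`, `aggregateGroupMetrics`).
* **Quantification & statistics** — voxel volumetry in mL, VAT/SAT ratio,
  two-tailed Student's t-test, Pearson agreement between reference and
  predicted volumes (`fatVolumes`, `tTestTwoTailed`, `cohortReport`).
* **Phantom cohort generator** — seeded multi-station abdominal phantoms
  with a bright SAT annulus, VAT blobs, fat-like bone confounders,
  polynomial bias field and Rician noise, plus ground-truth masks and a
  two-group cohort carrying a VAT/SAT effect (`phantomGroupConfig`,
  `renderPhantom`, `generateCohort`).

Masks use the file convention background = 0, SAT = 255, VAT = 127 in
8-bit images (`encodeMask`/`decodeMask`); volumes are NIfTI-1.

## Worked example

A small end-to-end run: simulate a cohort, train the scaled network,
evaluate against ground truth, and compare the groups.

```r
library(adiposeg)

cfg <- defaultRunConfig(seed = 5, outDir = "run")
res <- runPipeline(cfg)   # ~1 min on one CPU: 8+8 subjects, 64x64, 12 epochs
res$metrics
#>     group compartment     metric      mean         sd  n
#> 1 control         SAT       dice 0.9701451 0.01754472 30
#> 2 control         SAT pixelError 1.2019857 0.66220295 30
#> 3 control         VAT       dice 0.5728549 0.28843280 30
#> 4 control         VAT pixelError 0.5631510 0.25077966 30
#> 5 patient         SAT       dice 0.9532471 0.02742524 40
#> 6 patient         SAT pixelError 1.2640381 0.64324399 40
#> 7 patient         VAT       dice 0.8330135 0.19758776 40
#> 8 patient         VAT pixelError 0.9484863 0.59923393 40
```

Each row is the mean ± SD over all test-set slices of one group: even at
this miniature scale the network segments the subcutaneous annulus
reliably (SAT Dice ≈ 0.95–0.97, pixel error ≈ 1.2 %), while visceral
fat — fragmented, rare and confusable with bright bone rims — is the
harder class, the characteristic SAT > VAT ordering of fat-segmentation
networks. The full scaled experiment in the acceptance script (128 × 128,
16 + 16 subjects) reaches mean SAT Dice ≈ 0.98 and VAT Dice ≈ 0.80 on
held-out subjects.

Volumetry on one subject's ground truth:

```r
ph <- renderPhantom(
  sampleSubject(phantomGroupConfig("patient", nSubjects = 1), index = 1),
  dims = c(128, 128, 12), spacing = c(1.25, 1.25, 6))
fatVolumes(ph$truth, "pat001", "ground_truth")
#>   subjectID       source sat_ml   vat_ml     ratio
#> 1    pat001 ground_truth 391.05 33.53437 0.0857547
```

SAT and VAT volumes are in millilitres (voxel count × voxel volume); the
ratio is the downstream biomarker that the cohort statistics compare
between groups.

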