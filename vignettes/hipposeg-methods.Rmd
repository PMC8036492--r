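---
title: "Atlas-guided hippocampus segmentation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided hippocampus segmentation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The hippocampus is a small, bilateral gray-matter structure of the medial
temporal lobe whose atrophy is one of the earliest structural markers of
Alzheimer's disease and other dementias. Measuring that atrophy from
T1-weighted MRI requires a segmentation that is both *accurate* (close to
an expert's manual delineation) and *precise* (stable when the same brain
is scanned twice). Intensity alone cannot solve the problem: the
hippocampus has ordinary gray-matter intensity and directly abuts the
amygdala, which looks exactly the same — the boundary is defined by
anatomy, not contrast.

`hipposeg` implements a two-stage answer:

1. **Atlas stage.** A reference brain with probabilistic left/right
   hippocampus maps is registered to the subject (affine, then an
   optional non-linear refinement, cross-correlation driven). The warped
   probability map is binarised ("every non-zero voxel"), dilated by two
   voxels with the full 3×3×3 structuring element, and the image is
   cropped to the mask's bounding box expanded by a two-voxel safety
   margin on every face. One crop per side. This guarantees the
   hippocampus is inside the crop while shrinking the problem from
   millions of voxels to a few tens of thousands, which also improves
   the foreground/background class balance the classifier sees.
2. **Classification stage.** A 3D fully-convolutional network — nine
   unpadded 3×3×3 convolution + ReLU layers with feature maps growing
   20, 25, …, 60, then a pointwise (1×1×1) softmax classifier, no
   pooling or striding — labels every voxel of the crop as hippocampus
   or background. The receptive field is 19³; dense inference
   reflect-pads the crop by 9 voxels so the output grid equals the crop
   grid. Voxels outside the dilated atlas mask are background by
   definition, and the final mask is `p(foreground) > 0.5` (ties to
   background) intersected with the dilated mask.

## Pre-processing

Inputs are brain-extracted T1-weighted volumes. Each volume is resampled
to 1 mm isotropic resolution (cubic Keys interpolation; nearest-neighbour
for label maps, which therefore can never gain new label values) and
standardised to zero mean, unit population standard deviation. The
normalisation statistics are computed over the *non-zero* voxels by
default: brain extraction precedes the pipeline, so zero marks
background air, and including it would make the statistics depend on
the field of view. An explicit all-ones mask recovers whole-volume
statistics when wanted. The resampling grid keeps the input's world
origin and derives the new shape as `round(shape × spacing / target)`.

The pipeline itself passes a stricter region: the non-zero support
*eroded by two voxels*. The reason is the test-retest protocol, which
segments a rigidly co-registered scan: resampling blends a
partial-volume shell of intermediate intensities around the brain
boundary, and under the plain non-zero rule that shell would enter the
statistics of the warped scan but not of the native one, shifting the
two scans' z-score scales against each other (in our phantom study this
alone cost ~0.08 retest Dice). Eroding the support removes the shell
identically for native and resampled inputs.

## Training

Training minimises voxel-wise cross-entropy plus `l1·‖W‖₁ + l2·‖W‖₂²`
(defaults 1e-6 and 1e-4) over patches sampled from the ROI crops with
ground truth attached (truth outside the dilated mask is forced to
background first). Patches are class-balanced: each one is centred on a
foreground or a background voxel with probability ½. Input patches have
side `receptive field + o − 1`, where the training output side `o`
defaults to 9 (27³ inputs for the nine-layer network); patches never
read outside the crop (reflect padding). Batches hold 20 patches; the
default schedule is 10 epochs with the learning rate starting at 0.006
and halved whenever the validation Dice fails to improve by more than
1e-3 for two consecutive epochs; the returned weights are those of the
best-validation-Dice epoch. Dropout (rate 0.5) acts on the last two
hidden layers during training only, with inverted scaling so inference
needs no correction. Every training volume additionally contributes one
Gaussian-blurred copy per σ ∈ {0.5, 1.0} mm, tripling the training set;
labels are untouched.

Both momentum SGD (momentum 0.9) and Adam are implemented behind
`train_config(optimizer=)`. For the phantom study shipped with the
package we use Adam at the same initial rate: on the scaled-down
configuration it reaches a given validation Dice in roughly a third of
the updates plain SGD needs, which matters on a single CPU. All
randomness — patch sampling, dropout masks, weight initialisation —
flows from `train_config(seed=)`, so a rerun reproduces the training log
bit for bit.

## Registration engine

No registration library is assumed: the engine is part of the package.
It maximises the normalised cross-correlation (NCC) of the moving image
warped onto head voxels of the fixed image, over a translation /
rigid / affine parameter hierarchy, coarse to fine (4 mm Nelder–Mead,
then 2 mm — and for the rigid variant also a strided 1 mm level — using
BFGS with the *analytic* NCC gradient obtained by differentiating the
C1 Keys cubic interpolant, followed by a short monotone backtracking
polish). Working images are pre-blurred with σ = half the level spacing
(1 mm at the finest rigid level), which suppresses the noise-induced
displacement of the NCC optimum without erasing the edges that carry
the rotational information. The rigid refinement starts from the 2 mm
level directly: on near-symmetric objects a heavily smoothed 4 mm level
can actively prefer a translation-compensated wrong rotation, and
starting the gradient stages from identity avoids that basin.

The non-linear step is a demons-style iteration on a 2 mm grid:
intensity-difference forces projected on the warped-image gradient,
capped at one level-voxel per iteration, with Gaussian regularisation
(σ = 1.5 level voxels) of the accumulated field, upsampled to the fixed
grid afterwards. If the refined field fails to improve NCC over the
affine alone it is replaced by a zero field with a warning, so the
composite transform never degrades the affine result. Transforms map
fixed-image world points to moving-image world points (the resampling
convention); the affine part serialises as a plain-text 4×4, the field
as a 3-component NIfTI.

The same contract would be met by any external registration engine with
these invariants (similarity never decreases; known synthetic motions
recovered to sub-voxel accuracy); the tests pin the contract, not the
implementation.

## The phantom generator

Real training corpora (harmonised-protocol hippocampus datasets) cannot
be redistributed, so the package ships a generator whose output exercises
every stage of the pipeline with known ground truth:

* **Anatomy.** An ellipsoidal, already brain-extracted "brain" (white
  matter core, gray-matter shell, two CSF ventricles), with two mirrored
  hippocampus-like curved tubes — a quadratic Bézier centreline through
  three control points with a sinusoidally tapering radius profile, head
  and tail thinner than the body — and, critically, an *amygdala-like
  confuser*: a gray-matter sphere abutting the anterior end of each
  tube, carved so it overlaps zero labelled voxels. The confuser makes
  the anterior boundary invisible to intensity, as in real anatomy.
  All geometry is expressed in fractions of the half field-of-view, so
  any grid size from 64³ up produces a geometrically similar phantom; at
  the default 96³ each hippocampus encloses ≈ 4.6 mL, at the 72³ used in
  the validation study ≈ 2.0 mL — within the plausible adult range.
* **Imaging physics, simplified.** A multiplicative low-order polynomial
  bias field (amplitude 0.1) and additive Gaussian noise (SD 6 on tissue
  means 40/90/140) — Gaussian rather than Rician for simplicity, and no
  k-space or relaxometry simulation.
* **Population variability.** Each subject applies a random affine to
  the canonical anatomy: translation ≤ 4 mm, rotation ≤ 5°, per-axis
  scale 0.9–1.1. Anatomy and labels are evaluated *analytically* at the
  transformed coordinates, so the ground-truth label map and the
  ground-truth transform are exact, not resampled.
* **Retest pairs.** Scan 2 is scan 1's noiseless anatomy seen through a
  small rigid motion (≤ 3 mm, ≤ 3°) plus an independent noise draw —
  same subject, repositioned. The generator refuses any draw whose
  anatomy would touch the volume boundary: a clipped brain is no longer
  a rigid transform of its canonical self, which would silently corrupt
  both registration ground truth and the retest protocol.
* **Toy atlas.** The canonical noise-free phantom is the atlas
  reference; the probabilistic maps average the true labels of 20
  jittered subjects (fixed internal seed), so they peak at 1 in the
  structure core and their support covers a conforming subject's truth
  after correct registration.

What the phantom deliberately does **not** model: real tissue texture,
sulcal/gyral geometry, partial-volume mixtures, Rician noise, scanner-
specific artefacts, or pathology. A pipeline that passes on phantoms is
therefore *mechanically correct and statistically stable*, but the
phantom results say nothing quantitative about accuracy on clinical
MRI — that requires the real, non-redistributable datasets.

## The validation study (what the tests and `scripts/acceptance.R` run)

All problem sizes were chosen once for the study and are stated here as
the package's own design: phantoms at 72³ (1 mm); a cohort of 25
subjects split 17 train / 3 validation / 5 test; the scaled-down network
(5 hidden layers, feature maps 8–24, 27³ input patches, output side 17,
10 epochs, Adam); 10 affine and 10 rigid registration probes; 20
simulated retest pairs segmented through the full pipeline with the
affine-only ROI stage (the non-linear refinement is available but adds
nothing measurable on affine-generated phantoms). The quantities
reported are: the architecture parameter count (closed form = direct
enumeration = 373,622 for the production configuration), exact agreement
of dilation / Dice / rank-sum against brute-force oracles, worst-case
registration recovery errors, ROI ground-truth containment (the
dilate-2-then-margin-2 guarantee), held-out mean Dice of the trained
network, per-side retest mean Dice and absolute volume difference, and
byte-level determinism of simulate/train/segment under fixed seeds.

## Numerical choices and degenerate inputs

* Population (divide-by-N) standard deviation in the normalisation, so
  a two-value image {−1, +1} is an exact fixed point; constant images
  and empty masks are errors, not NaNs.
* Binarisation of warped probability maps treats values below 1e-6 as
  zero: cubic interpolation leaves a tiny ringing halo around the
  support, and a literal "non-zero" rule would make the ROI grow with
  grid resolution.
* Bounding boxes are 0-based and half-open; boxes clip silently at the
  volume boundary (the safety margin is best-effort at the edge).
* Probability ties at exactly 0.5 go to background (strict inequality).
* The segmentation threshold, dilation radius (2), safety margin (2),
  and structuring element (26-connected) are all configurable through
  `roi_config()` / `net_config()` but default to the values above.
* Both-empty-mask Dice is reported as `NA` (missing), never 1: an
  undefined ratio must not inflate agreement statistics.
* Left/right crops are processed independently and merged by
  `restore_to_full()`; if both sides ever claimed a voxel the left label
  wins with a warning — unreachable for atlases with disjoint supports,
  which the `atlas()` constructor enforces.
* The rank-sum comparison uses exact enumeration for `n + m ≤ 12`
  without ties and the tie-corrected normal approximation otherwise; a
  paired signed-rank variant sits behind `paired = TRUE` because
  method-comparison samples are per-subject paired, even though the
  unpaired test is the published convention this package defaults to.

## Known limitations

* CPU-only; training the production 9-layer configuration on a real
  cohort is feasible but slow (hours, not minutes).
* The registration engine is tuned for brain-extracted images with
  zero background; it re-zeroes a constant background internally but
  does not model skull or field-of-view truncation.
* Phantom realism limits, as listed above.
* The learning-rate policy ("halve on validation-Dice plateau,
  patience 2, min-delta 1e-3") is one concrete reading of "steadily
  diminished until the validation accuracy plateaued"; other readings
  (step decay, cosine) are not implemented.
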