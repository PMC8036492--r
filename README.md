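# hipposeg

Automatic segmentation of the left and right hippocampus from 3D
T1-weighted MRI, for neuroimaging researchers who need hippocampal
volumes (an early atrophy marker in dementia) without manual tracing.

The tool is a two-stage pipeline:

1. **Atlas localisation.** A reference brain carrying probabilistic
   left/right hippocampus maps is registered to the subject (affine +
   optional non-linear refinement, maximising normalised
   cross-correlation). Each warped map is binarised (every non-zero
   voxel), dilated by 2 voxels with the full 3×3×3 structuring element,
   and the subject image is cropped to the mask's bounding box expanded
   by a 2-voxel safety margin — one region of interest (ROI) per side,
   guaranteed to contain the structure.
2. **Voxel classification.** A 3D fully-convolutional network — nine
   unpadded 3×3×3 conv + ReLU layers with feature maps 20, 25, …, 60 and
   a pointwise softmax classifier (373,622 parameters, 19³ receptive
   field, no pooling) — labels every ROI voxel as hippocampus or
   background. Dense inference reflect-pads the crop so the output grid
   equals the crop grid; the final mask is
   `p(fg) > 0.5 ∧ voxel ∈ dilated atlas mask`.

Training minimises voxel-wise cross-entropy +
`1e-6·‖W‖₁ + 1e-4·‖W‖₂²` over class-balanced 27³ patches (batch 20,
10 epochs, learning rate 0.006 halved on validation-Dice plateau,
dropout 0.5 on the last two hidden layers, Gaussian-blur augmentation
σ ∈ {0.5, 1} mm). Evaluation ships with the package: Dice overlap,
volumes in mL, a rigid-registration test-retest precision protocol, and
Wilcoxon rank-sum method comparison (exact for n+m ≤ 12 without ties).

Because the clinical training corpora cannot be redistributed, the
package includes a synthetic brain-phantom generator (curved-tube
hippocampi with ground-truth labels, an adjacent same-intensity
amygdala-like confuser, bias field, noise, per-subject affine
variability, retest pairs, and a matching toy atlas) that exercises the
full pipeline end to end.

## Worked example

```r
library(hipposeg)

spec  <- phantom_spec(shape = c(72, 72, 72))   # 1 mm isotropic phantoms
atlas <- generate_atlas(spec)

# train a scaled-down network on 8 synthetic subjects
cohort <- generate_cohort(spec, 10, seed = 500)
crops <- lapply(cohort, function(s)
  roi_crops_with_truth(s$image, s$labels, atlas))
model <- train_network(
  net_config(5, c(8, 12, 16, 20, 24)),
  do.call(c, crops[1:8]), do.call(c, crops[9:10]),
  train_config(epochs = 10, out_side = 17, optimizer = "adam",
               patches_per_crop = 6, seed = 1))
model
#> <hipposeg_model> trained
#>   5 hidden 3^3 conv layers, feature maps: 8,12,16,20,24
#>   receptive field 11^3, 29,722 parameters
#>   best validation Dice 0.959 at epoch 10

# segment a new subject and compare with its ground truth
subject <- generate_phantom(spec, 999)
res <- segment_volume(subject$image, atlas, model, nonlinear = FALSE)
dice_coefficient(res$labels$data == 1, subject$labels$data == 1)
#> [1] 0.9574329
volume_ml(res$labels$data == 1, res$labels$spacing)
#> [1] 1.496
```

The printed numbers mean: the model kept the epoch-10 weights (best
validation Dice 0.96 over the two held-out training-domain subjects);
on an unseen phantom the left-hippocampus segmentation overlaps the
ground truth with Dice 0.957 and measures a 1.50 mL structure against
the phantom's true 1.56 mL left hippocampus at this field of view.

A thin command-line driver with `simulate` / `train` / `segment` /
`retest` subcommands is installed at `inst/cli/hipposeg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hipposeg.R", package="hipposeg"))')" \
    simulate --out fixtures --n 25 --shape 72 --seed 0
```

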