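test_that("phantom generation is deterministic given (spec, seed)", {
  spec <- test_spec(48)
  p1 <- generate_phantom(spec, 61)
  p2 <- generate_phantom(spec, 61)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$labels$data, p2$labels$data)
  p3 <- generate_phantom(spec, 62)
  expect_gt(max(abs(p3$image$data - p1$image$data)), 0)
})

test_that("noiseless, bias-free phantoms are piecewise constant at the tissue means", {
  spec <- test_spec(48, noise_sd = 0, bias_amplitude = 0)
  ph <- generate_phantom(spec, 63)
  gm <- spec$intensities[["gm"]]
  expect_equal(unique(ph$image$data[ph$labels$data == 1L]), gm)
  expect_equal(unique(ph$image$data[ph$labels$data == 2L]), gm)
  expect_true(all(ph$image$data %in% c(0, spec$intensities)))
})

test_that("default-scale hippocampi fall in the plausible volume range", {
  ph <- generate_phantom(phantom_spec(), 64)  # default 96^3
  for (lab in 1:2) {
    ml <- volume_ml(ph$labels$data == lab, ph$labels$spacing)
    expect_gte(ml, 1.5)
    expect_lte(ml, 5.0)
  }
})

test_that("labels and volumes share grid metadata; sides are disjoint", {
  spec <- test_spec(48)
  ph <- generate_phantom(spec, 65)
  expect_equal(dim(ph$labels$data), dim(ph$image$data))
  expect_equal(ph$labels$spacing, ph$image$spacing)
  expect_setequal(unique(as.integer(ph$labels$data)), c(0L, 1L, 2L))
})

test_that("the confuser blob is GM-intensity tissue that overlaps no label", {
  spec <- test_spec(48, noise_sd = 0, bias_amplitude = 0)
  # canonical render exposes the confuser exactly at the GM mean
  ph <- generate_phantom(test_spec(48, noise_sd = 0, bias_amplitude = 0,
                                   affine_translation = 0, affine_rotation = 0,
                                   affine_scale = c(1, 1)), 66)
  gm_vox <- ph$image$data == spec$intensities[["gm"]] & ph$labels$data == 0L
  # GM voxels outside the labels exist (cortex ribbon + confuser) ...
  expect_gt(sum(gm_vox), 0)
  # ... and some of them touch the labelled tubes (the abutting confuser)
  lab_d <- binarize_and_dilate(array(as.integer(ph$labels$data != 0),
                                     dim(ph$labels$data)),
                               roi_config(dilation_voxels = 1))
  expect_gt(sum(gm_vox & lab_d == 1L), 0)
})

test_that("atlas probability maps peak at 1 with disjoint left/right support", {
  # the core-overlap guarantee is a property of the default field of
  # view, where the tube radius comfortably exceeds the jitter range
  spec <- phantom_spec()
  atl <- generate_atlas(spec)
  expect_equal(max(atl$prob_left$data), 1)
  expect_equal(max(atl$prob_right$data), 1)
  expect_true(all(atl$prob_left$data >= 0 & atl$prob_left$data <= 1))
  expect_false(any(atl$prob_left$data > 0 & atl$prob_right$data > 0))
  # support covers a conforming subject's truth (after perfect alignment
  # the truth sits within the jitter envelope plus dilation margin)
  spec <- test_spec(64)
  atl <- generate_atlas(spec)
  ph <- generate_phantom(spec, 67)
  warped <- warp_probability_map(atl$prob_left,
                                 spatial_transform(ph$meta$expected_registration),
                                 ph$image)
  mask <- binarize_and_dilate(warped, roi_config())
  inside <- mask[ph$labels$data == 1L]
  expect_gte(mean(inside), 0.999)
})

test_that("cohort splits follow the floor-then-remainder-to-test rule", {
  sp <- split_cohort(25, c(0.8, 0.1, 0.1))
  expect_length(sp$train, 20)
  expect_length(sp$val, 2)
  expect_length(sp$test, 3)
  all_ix <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_ix, 1:25)
  expect_equal(anyDuplicated(all_ix), 0L)
})

test_that("cohorts are reproducible and subjects differ", {
  spec <- test_spec(48)
  c1 <- generate_cohort(spec, 3, seed = 68)
  c2 <- generate_cohort(spec, 3, seed = 68)
  expect_identical(c1[[2]]$image$data, c2[[2]]$image$data)
  expect_gt(max(abs(c1[[1]]$image$data - c1[[2]]$image$data)), 0)
  c3 <- generate_cohort(spec, 3, seed = 69)
  expect_gt(max(abs(c1[[1]]$image$data - c3[[1]]$image$data)), 0)
})

test_that("retest pairs share anatomy and record the applied motion", {
  spec <- test_spec(48)
  rp <- generate_retest_pair(spec, 70)
  # same anatomy: label counts agree up to voxelisation of the moved grid
  n1 <- sum(rp$labels$data != 0L); n2 <- sum(rp$meta$labels2 != 0L)
  expect_lt(abs(n1 - n2) / n1, 0.02)
  # recorded motion is exactly invertible bookkeeping
  expect_equal(rp$meta$motion_world %*% rp$meta$expected_rigid, diag(4),
               tolerance = 1e-12)
  # zero motion and zero noise give identical scans
  spec0 <- test_spec(48, noise_sd = 0, retest_translation = 0,
                     retest_rotation = 0)
  rp0 <- generate_retest_pair(spec0, 71)
  expect_equal(rp0$scan1$data, rp0$scan2$data, tolerance = 1e-9)
})

test_that("fixture sets round-trip through the manifest directory", {
  spec <- test_spec(48)
  coh <- generate_cohort(spec, 2, seed = 72)
  dir <- tempfile()
  write_fixture_set(coh, dir, split = list(train = 1L, val = 2L,
                                           test = integer(0)), seed = 72)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$n, 2L)
  img <- read_volume(file.path(dir, man$subjects[[1]]$image))
  expect_equal(img$data, coh[[1]]$image$data)
  lab <- read_label_map(file.path(dir, man$subjects[[2]]$labels))
  expect_identical(lab$data, coh[[2]]$labels$data)
})
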