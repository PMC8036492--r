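test_that("binarize_and_dilate matches the brute-force dilation oracle", {
  set.seed(11)
  for (rep in 1:6) {
    mask <- array(0, c(12, 12, 12))
    mask[sample(12^3, 8)] <- runif(8, 0.01, 1)  # sparse probabilities
    iters <- sample(0:2, 1)
    got <- binarize_and_dilate(mask, roi_config(dilation_voxels = iters))
    want <- dilate_oracle(mask, iters)
    expect_identical(got == 1L, want)
  }
})

test_that("dilation special cases behave as specified", {
  # single centre voxel, 2 dilations -> 5^3 cube of 125 ones
  m <- array(0, c(9, 9, 9)); m[5, 5, 5] <- 1
  out <- binarize_and_dilate(m, roi_config(dilation_voxels = 2))
  expect_equal(sum(out), 125)
  expect_true(all(out[3:7, 3:7, 3:7] == 1L))
  # all-ones fixed point
  ones <- array(1L, c(5, 5, 5))
  expect_identical(binarize_and_dilate(ones, roi_config()), ones)
  # zero dilations = binarization only
  p <- array(c(0, 0.3), c(4, 4, 4))
  expect_identical(binarize_and_dilate(p, roi_config(dilation_voxels = 0)),
                   array(as.integer(p != 0), c(4, 4, 4)))
  expect_error(binarize_and_dilate(array(0, c(3, 3, 3))), "empty")
  expect_error(binarize_and_dilate(array(-1, c(3, 3, 3))), "negative")
})

test_that("dilation is monotone in the iteration count", {
  set.seed(12)
  mask <- array(0, c(14, 14, 14)); mask[sample(14^3, 5)] <- 1
  prev <- binarize_and_dilate(mask, roi_config(dilation_voxels = 0))
  for (k in 1:3) {
    cur <- binarize_and_dilate(mask, roi_config(dilation_voxels = k))
    expect_true(all(cur[prev == 1L] == 1L))  # superset
    prev <- cur
  }
})

test_that("extract_roi applies the tight-box-plus-margin rule", {
  img <- tiny_volume(c(64, 64, 64))
  mask <- array(0L, c(64, 64, 64))
  mask[11:20, 11:20, 11:20] <- 1L  # voxels [10,20) in 0-based terms
  crop <- extract_roi(img, mask, roi_config(margin_voxels = 2), "left")
  expect_equal(crop$bbox_lo, c(8L, 8L, 8L))
  expect_equal(dim(crop$image$data), c(14L, 14L, 14L))
  expect_equal(crop$image$data,
               img$data[9:22, 9:22, 9:22])
  # margin 0 gives the tight box
  crop0 <- extract_roi(img, mask, roi_config(margin_voxels = 0), "left")
  expect_equal(crop0$bbox_lo, c(10L, 10L, 10L))
  expect_equal(dim(crop0$image$data), c(10L, 10L, 10L))
  # mask touching the edge clips without error
  mask2 <- array(0L, c(64, 64, 64)); mask2[1:3, 62:64, 1:3] <- 1L
  crop2 <- extract_roi(img, mask2, roi_config(margin_voxels = 2), "right")
  expect_equal(crop2$bbox_lo, c(0L, 59L, 0L))
  expect_equal(dim(crop2$image$data), c(5L, 5L, 5L))
  expect_error(extract_roi(img, array(0L, c(64, 64, 64)), roi_config(), "left"),
               "empty")
})

test_that("restore_to_full inverts cropping and relabels by side", {
  img <- tiny_volume(c(32, 32, 32))
  mask <- array(0L, c(32, 32, 32)); mask[10:15, 12:18, 9:14] <- 1L
  for (side in c("left", "right")) {
    crop <- extract_roi(img, mask, roi_config(), side)
    full <- restore_to_full(crop$dilated_mask, crop)
    lab <- if (side == "left") 1L else 2L
    expect_identical(full$data == lab, mask == 1L)
    expect_s3_class(full, "label_map")
  }
  crop <- extract_roi(img, mask, roi_config(), "left")
  zero <- restore_to_full(array(0L, dim(crop$image$data)), crop)
  expect_equal(sum(zero$data), 0)
  expect_error(restore_to_full(array(0L, c(2, 2, 2)), crop), "shape")
})

test_that("atlas bundles round-trip through the directory format", {
  ref <- tiny_volume(c(10, 10, 10))
  pl <- volume(array(0, c(10, 10, 10))); pl$data[2:4, 2:4, 2:4] <- 0.8
  pr <- volume(array(0, c(10, 10, 10))); pr$data[7:9, 7:9, 7:9] <- 0.6
  a <- atlas(ref, pl, pr)
  dir <- tempfile()
  write_atlas(a, dir)
  a2 <- read_atlas(dir)
  expect_equal(a2$reference$data, ref$data)
  expect_equal(a2$prob_left$data, pl$data, tolerance = 1e-12)
  # overlapping supports violate the atlas invariant
  expect_error(atlas(ref, pl, pl), "disjoint")
  pbad <- volume(array(2, c(10, 10, 10)))
  expect_error(atlas(ref, pbad, pr), "0,1|\\[0,1\\]")
})
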