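test_that("NIfTI round trip preserves data and geometry", {
  v <- tiny_volume(spacing = c(1.5, 2, 2.5))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$xform, v$xform, tolerance = 1e-6)

  # labels round-trip as unsigned 8-bit integers
  lab <- label_map(volume(array(sample(0:2, 64, TRUE), c(4, 4, 4))))
  lpath <- tempfile(fileext = ".nii.gz")
  write_volume(lab, lpath)
  expect_identical(read_label_map(lpath)$data, lab$data)
})

test_that("reading a non-3D image fails with a descriptive error", {
  path <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "expected 3D volume")
  expect_error(read_volume(tempfile(fileext = ".nii")), "cannot read")
})

test_that("volume invariants are enforced", {
  expect_error(volume(matrix(0, 2, 2)), "3D")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)), "spacing")
  expect_error(volume(array(0, c(2, 2, 2)), xform = matrix(0, 4, 4)),
               "invertible")
  expect_error(label_map(volume(array(5L, c(2, 2, 2)))), "values")
})

test_that("intensity normalization matches hand-computed z-scores", {
  # {1,2,3} with population SD sqrt(2/3)
  v <- volume(array(c(1, 2, 3, 1, 2, 3, 1, 2), c(2, 2, 2)))
  out <- normalize_intensity(v, mask = array(1, c(2, 2, 2)))
  reg <- out$data
  expect_equal(mean(reg), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(reg^2)), 1, tolerance = 1e-12)
  v3 <- volume(array(rep(c(1, 2, 3), length.out = 27), c(3, 3, 3)))
  z <- normalize_intensity(v3, mask = array(1, c(3, 3, 3)))$data
  want <- (c(1, 2, 3) - 2) / sqrt(2 / 3)   # -1.2247, 0, +1.2247
  expect_equal(z, array(rep(want, length.out = 27), c(3, 3, 3)),
               tolerance = 1e-4)
})

test_that("normalization region defaults to non-zero voxels and errors are raised", {
  arr <- array(0, c(4, 4, 4)); arr[2:3, 2:3, 2:3] <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v <- volume(arr)
  out <- normalize_intensity(v)
  sel <- arr != 0
  expect_equal(mean(out$data[sel]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(out$data[sel]^2)), 1, tolerance = 1e-9)
  expect_error(normalize_intensity(volume(array(7, c(3, 3, 3)))), "constant")
  expect_error(normalize_intensity(v, mask = array(0, c(4, 4, 4))), "empty")
  expect_error(normalize_intensity(v, mask = array(1, c(2, 2, 2))), "aligned")
})

test_that("normalization is a fixed point / idempotent", {
  v <- volume(array(c(-1, 1), c(2, 2, 2)))
  m <- array(1, c(2, 2, 2))
  expect_equal(normalize_intensity(v, m)$data, v$data, tolerance = 1e-12)
  v2 <- tiny_volume(seed = 3)
  once <- normalize_intensity(v2, m1 <- array(1, c(8, 8, 8)))
  twice <- normalize_intensity(once, m1)
  expect_equal(twice$data, once$data, tolerance = 1e-6)
})

test_that("isotropic resampling follows the round(shape*spacing/target) rule", {
  set.seed(4)
  v <- volume(array(rnorm(1000), c(10, 10, 10)), spacing = c(2, 2, 2))
  out <- resample_isotropic(v, 1.0, order = 1L)
  expect_equal(dim(out$data), c(20L, 20L, 20L))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_equal(out$xform[1:3, 4], v$xform[1:3, 4])  # origin preserved

  # identity at native spacing
  u <- tiny_volume()
  expect_equal(resample_isotropic(u, 1.0, order = 3L)$data, u$data,
               tolerance = 1e-9)
  # constants are preserved by interpolation
  cv <- volume(array(3.5, c(6, 6, 6)), spacing = c(1.7, 1.7, 1.7))
  out2 <- resample_isotropic(cv, 1.0, order = 3L)
  expect_equal(range(out2$data), c(3.5, 3.5), tolerance = 1e-9)
  expect_error(resample_isotropic(u, -1), "target_spacing")
})

test_that("label maps resample with nearest neighbour and gain no new labels", {
  set.seed(5)
  for (rep in 1:5) {
    arr <- array(sample(c(0L, 0L, 1L, 2L), 5^3, TRUE), c(5, 5, 5))
    lab <- label_map(volume(arr, spacing = c(1.3, 1.7, 2.1)))
    out <- resample_isotropic(lab, 1.0, order = 3L)  # order forced to 0
    expect_true(all(unique(as.integer(out$data)) %in% unique(as.integer(arr))))
    expect_s3_class(out, "label_map")
  }
})

test_that("gaussian blur augmentation preserves constants and kernel mass", {
  cv <- volume(array(2, c(9, 9, 9)))
  for (b in augment_blur(cv, c(0.5, 1.0)))
    expect_equal(range(b$data), c(2, 2), tolerance = 1e-9)
  # unit impulse: centre equals the central weight of the separable kernel
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  out <- augment_blur(volume(imp), 1.0)[[1]]
  g <- dnorm(-6:6); g <- g / sum(g)  # truncation past 4 sigma is negligible
  expect_equal(out$data[8, 8, 8], max(g)^3, tolerance = 1e-3)
  expect_equal(sum(out$data), 1, tolerance = 1e-6)  # mass preserved
  expect_length(augment_blur(tiny_volume(), c(0.5, 1.0)), 2L)
})
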