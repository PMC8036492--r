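# Registration tests run on small (48^3) phantoms to stay fast; the
# full-size recovery study lives in the acceptance suite.

test_that("self-registration recovers the identity", {
  spec <- test_spec(48)
  ph <- generate_phantom(spec, 51)
  v <- normalize_intensity(ph$image)
  tr <- suppressWarnings(register_affine(moving = v, fixed = v))
  expect_lt(max(abs(tr$affine[1:3, 4])), 0.1)          # translation < 0.1 mm
  expect_lt(max(abs(tr$affine[1:3, 1:3] - diag(3))), 0.01)
  trr <- suppressWarnings(rigid_register(moving = v, fixed = v))
  expect_lt(max(abs(trr$affine[1:3, 4])), 0.1)
})

test_that("a known translation is recovered within half a voxel", {
  spec <- test_spec(48)
  rp <- generate_retest_pair(spec, 52)
  tr <- suppressWarnings(rigid_register(moving = rp$scan2, fixed = rp$scan1))
  ctr <- rep((48 - 1) / 2, 3)
  E <- tr$affine %*% solve(rp$meta$expected_rigid)
  expect_lt(max(abs((E %*% c(ctr, 1))[1:3] - ctr)), 0.5)
})

test_that("rigid transforms have no scale or shear", {
  spec <- test_spec(48)
  rp <- generate_retest_pair(spec, 53)
  tr <- suppressWarnings(rigid_register(moving = rp$scan2, fixed = rp$scan1))
  sv <- svd(tr$affine[1:3, 1:3])$d
  expect_equal(sv, c(1, 1, 1), tolerance = 1e-6)
})

test_that("degenerate (constant) images are rejected", {
  cv <- volume(array(1, c(16, 16, 16)))
  expect_error(register_affine(cv, cv), "constant")
  expect_error(rigid_register(cv, cv), "constant")
})

test_that("warping through the identity transform reproduces the input", {
  v <- tiny_volume(c(12, 12, 12))
  t_id <- spatial_transform(diag(4))
  out <- warp_volume(v, t_id, v, order = 1L)
  expect_equal(out$data, v$data, tolerance = 1e-9)
  # probability maps: identity warp, zero maps, clamping
  p <- volume(array(runif(12^3), c(12, 12, 12)))
  expect_equal(warp_probability_map(p, t_id, p)$data, p$data,
               tolerance = 1e-6)
  z <- volume(array(0, c(12, 12, 12)))
  expect_equal(sum(warp_probability_map(z, t_id, z)$data), 0)
  expect_error(warp_probability_map(volume(array(2, c(4, 4, 4))), t_id, z),
               "\\[0, 1\\]")
})

test_that("integer-voxel translations equal a direct array shift", {
  set.seed(54)
  arr <- array(0, c(16, 16, 16))
  arr[5:12, 5:12, 5:12] <- runif(8^3)
  sm <- augment_blur(volume(arr), 1.0)[[1]]  # smooth so cubic halo is tame
  shift <- c(3, -2, 1)
  A <- diag(4); A[1:3, 4] <- shift
  warped <- warp_volume(sm, spatial_transform(A), sm, order = 3L)
  # fixed voxel i reads moving at i + shift
  expect_equal(warped$data[1:10, 5:16, 1:14],
               sm$data[(1:10) + 3, (5:16) - 2, (1:14) + 1],
               tolerance = 1e-3)
})

test_that("nonlinear refinement stays near zero when the affine already fits", {
  spec <- test_spec(48, noise_sd = 3)
  ph <- generate_phantom(spec, 55)
  v <- normalize_intensity(ph$image)
  atl <- generate_atlas(spec)
  ref <- normalize_intensity(atl$reference)
  aff <- suppressWarnings(register_affine(moving = ref, fixed = v))
  nl <- suppressWarnings(register_nonlinear(moving = ref, fixed = v, init = aff))
  mags <- sqrt(rowSums(matrix(nl$displacement, ncol = 3)^2))
  brain <- as.vector(v$data != 0)
  expect_lt(mean(mags[brain]), 0.5)          # mean |d| < 0.5 mm
  # regularization keeps noise-driven deformation small
  expect_lt(unname(quantile(mags[brain], 0.95)), 1.5)
})

test_that("nonlinear refinement recovers a synthetic smooth bump", {
  spec <- test_spec(48, noise_sd = 2)
  atl <- generate_atlas(spec)
  ref <- normalize_intensity(atl$reference)
  # deform the reference by a known smooth radial bump (amplitude 3 mm)
  d <- dim(ref$data)
  idx <- hipposeg:::grid_index(d)
  ctr <- (d - 1) / 2
  rel <- sweep(idx, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  amp <- 3 * exp(-((r - 10) / 8)^2)
  disp_true <- rel / pmax(r, 1e-9) * amp     # radial, in mm
  src <- idx + disp_true
  warped <- hipposeg:::cpp_interp3(as.double(ref$data), d, src, 1L, 0)
  fixed <- volume(array(warped, d), id = "bumped")
  aff <- spatial_transform(diag(4))          # true affine is identity
  nl <- suppressWarnings(register_nonlinear(moving = ref, fixed = fixed,
                                            init = aff, iters = 40))
  est <- matrix(nl$displacement, ncol = 3)
  brain <- as.vector(fixed$data != 0) & r < 20
  resid_aff <- sqrt(rowSums(disp_true^2))
  resid_nl <- sqrt(rowSums((disp_true - est)^2))
  # at least half of the mean in-brain displacement must be explained
  expect_lt(mean(resid_nl[brain]), 0.5 * mean(resid_aff[brain]))
})
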