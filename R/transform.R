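#' Spatial transforms
#'
#' A `spatial_transform` maps points of the *fixed* image's world frame to
#' the *moving* image's world frame (the resampling convention: to pull
#' moving-image values onto the fixed grid, each fixed-grid point is
#' mapped through the transform and the moving image is interpolated
#' there). It consists of a 4x4 world-space affine and, optionally, a
#' dense displacement field (mm, on the fixed grid) added after the
#' affine. So for the atlas stage, registering the atlas (moving) to a
#' subject (fixed) yields the transform used to warp atlas-space maps
#' onto the subject grid.
#'
#' @param affine 4x4 invertible world-space affine.
#' @param displacement optional 4D array `c(dim(fixed), 3)` of world-space
#'   displacements in mm, defined on the fixed grid.
#' @param fixed_geom geometry (a [volume], data ignored) of the fixed grid
#'   the displacement lives on; required when `displacement` is given.
#' @return An object of class `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), displacement = NULL,
                              fixed_geom = NULL) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (!is.null(displacement)) {
    if (is.null(fixed_geom))
      stop("a displacement field requires its fixed-grid geometry")
    dd <- dim(displacement)
    if (length(dd) != 4L || dd[4] != 3L ||
        !all(dd[1:3] == dim(fixed_geom$data)))
      stop("displacement must be c(dim(fixed), 3) and grid-aligned")
  }
  structure(list(affine = affine, displacement = displacement,
                 fixed_geom = fixed_geom),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("<spatial_transform> fixed-world -> moving-world\n")
  cat("  affine:\n")
  print(round(x$affine, 4))
  if (!is.null(x$displacement)) {
    m <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
    cat(sprintf("  dense displacement: mean |d| = %.3f mm, max = %.3f mm\n",
                mean(m), max(m)))
  }
  invisible(x)
}

# apply transform to fixed-world points (n x 3); if the transform carries a
# displacement field, `fixed_idx` (0-based voxel indices into the fixed
# grid, n x 3 integer) selects the displacement vectors.
apply_transform <- function(t, pts, fixed_idx = NULL) {
  out <- cbind(pts, 1) %*% t(t$affine)
  out <- out[, 1:3, drop = FALSE]
  if (!is.null(t$displacement)) {
    if (is.null(fixed_idx))
      stop("displacement transforms need fixed-grid indices")
    d <- dim(t$displacement)[1:3]
    lin <- 1L + fixed_idx[, 1] + d[1] * (fixed_idx[, 2] + d[2] * fixed_idx[, 3])
    n <- prod(d)
    out <- out + cbind(t$displacement[lin], t$displacement[n + lin],
                       t$displacement[2 * n + lin])
  }
  out
}

#' Warp a moving volume onto a target grid
#'
#' Pulls `moving`-image values onto the grid of `target` through a
#' [spatial_transform] (fixed-world to moving-world).
#'
#' @param moving the [volume] to resample.
#' @param t a [spatial_transform] whose fixed frame is `target`'s.
#' @param target a [volume] defining the output grid.
#' @param order interpolation order (0, 1 or 3).
#' @param fill value for points mapping outside `moving`.
#' @return A [volume] on `target`'s grid.
#' @export
warp_volume <- function(moving, t, target, order = 1L, fill = 0) {
  stopifnot(inherits(moving, "volume"), inherits(target, "volume"),
            inherits(t, "spatial_transform"))
  if (!is.null(t$displacement) && !same_grid(t$fixed_geom, target))
    stop("transform displacement grid does not match the target grid")
  idx <- grid_index(dim(target$data))
  wpts <- vox_to_world(target, idx)
  mpts <- apply_transform(t, wpts, fixed_idx = if (is.null(t$displacement)) NULL else idx)
  mvox <- world_to_vox(moving, mpts)
  vals <- cpp_interp3(as.double(moving$data), dim(moving$data), mvox,
                      as.integer(order), fill)
  volume(array(vals, dim(target$data)), spacing = target$spacing,
         xform = target$xform, id = moving$id)
}

#' Warp a probabilistic atlas map to a subject grid
#'
#' Applies the atlas-to-subject registration result to a probabilistic
#' structure map with cubic (spline-like) interpolation, clamps the result
#' to [0, 1], and zeroes the tiny interpolation halo (values below 1e-6)
#' so that the later "every non-zero voxel" binarisation is not inflated
#' by interpolation ringing.
#'
#' @param prob probabilistic [volume] on the atlas grid, values in [0,1].
#' @param t [spatial_transform] from registering the atlas to the subject.
#' @param target subject [volume] defining the output grid.
#' @return Probability [volume] on the subject grid.
#' @export
warp_probability_map <- function(prob, t, target) {
  if (min(prob$data) < 0 || max(prob$data) > 1)
    stop("probability map values must lie in [0, 1]")
  out <- warp_volume(prob, t, target, order = 3L, fill = 0)
  out$data[out$data < 1e-6] <- 0
  out$data[out$data > 1] <- 1
  out
}

#' Serialise transforms
#'
#' The affine part is written as a plain-text 4x4 matrix; a displacement
#' field, when present, as a 3-component NIfTI next to it.
#'
#' @param t a [spatial_transform].
#' @param path output path for the affine text file; a displacement field
#'   goes to `<path>_disp.nii.gz`.
#' @export
write_transform <- function(t, path) {
  write(t(t$affine), file = path, ncolumns = 4)
  if (!is.null(t$displacement)) {
    d <- dim(t$displacement)
    img <- RNifti::asNifti(t$displacement)
    RNifti::pixdim(img) <- c(t$fixed_geom$spacing, 1)
    RNifti::writeNifti(img, paste0(path, "_disp.nii.gz"), datatype = "double")
  }
  invisible(path)
}

#' @rdname write_transform
#' @param fixed_geom fixed-grid geometry, needed to reattach a
#'   displacement field.
#' @export
read_transform <- function(path, fixed_geom = NULL) {
  aff <- matrix(scan(path, quiet = TRUE), 4, 4, byrow = TRUE)
  dpath <- paste0(path, "_disp.nii.gz")
  disp <- NULL
  if (file.exists(dpath)) {
    img <- RNifti::readNifti(dpath)
    disp <- as.array(img)
    attributes(disp) <- list(dim = dim(img))
  }
  spatial_transform(aff, disp, fixed_geom)
}

# --- parameterised affines --------------------------------------------
# params: t (mm, 3), r (radians, 3), log-scale (3), shear (3); the map is
# x -> c + R S H (x - c) + t about a world-space centre c.
params_to_affine <- function(par, center) {
  tr <- par[1:3]; r <- par[4:6]
  sc <- if (length(par) >= 9) exp(par[7:9]) else c(1, 1, 1)
  sh <- if (length(par) >= 12) par[10:12] else c(0, 0, 0)
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3)
  H <- diag(3); H[1, 2] <- sh[1]; H[1, 3] <- sh[2]; H[2, 3] <- sh[3]
  M <- Rz %*% Ry %*% Rx %*% diag(sc, 3) %*% H
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- center - M %*% center + tr
  A
}

# world-space centre of a volume's grid
grid_center <- function(v) {
  as.numeric(vox_to_world(v, matrix((dim(v$data) - 1) / 2, 1)))
}
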