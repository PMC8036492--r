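#' Intensity standardisation
#'
#' Rescales a volume to zero mean and unit population standard deviation
#' (divide by N) over a normalisation region. Multi-centre T1-weighted
#' scans have arbitrary, scanner-dependent intensity scales; the network
#' only ever sees standardised intensities. When no mask is supplied the
#' statistics are taken over the non-zero voxels, matching the convention
#' that inputs are brain-extracted (background exactly zero); pass an
#' all-ones mask for whole-volume statistics.
#'
#' @param v a [volume].
#' @param mask optional binary array on the same grid selecting the
#'   normalisation region.
#' @return A [volume] with mean 0 and population SD 1 over the region.
#' @export
normalize_intensity <- function(v, mask = NULL) {
  stopifnot(inherits(v, "volume"))
  if (is.null(mask)) {
    sel <- v$data != 0
    if (!any(sel)) sel <- array(TRUE, dim(v$data))  # nothing to exclude
  } else {
    if (!all(dim(mask) == dim(v$data)))
      stop("mask is not grid-aligned with the volume")
    sel <- mask != 0
    if (!any(sel)) stop("empty normalization mask")
  }
  x <- v$data[sel]
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # population SD
  if (sdev <= 0)
    stop("cannot normalize a constant image (zero variance over the region)")
  out <- v
  out$data <- (v$data - mu) / sdev
  out
}

#' Isotropic resampling
#'
#' Resamples a volume onto an isotropic grid (default 1 mm), the working
#' resolution of the whole pipeline. The output grid shares the input's
#' world origin; the new shape per axis is
#' `round(shape * spacing / target)` (minimum 1).
#'
#' @param v a [volume] (or [label_map]).
#' @param target_spacing target voxel size in mm (> 0).
#' @param order interpolation order: 0 nearest (always used for label
#'   maps), 1 trilinear, 3 cubic.
#' @return Resampled [volume] (class preserved for label maps).
#' @export
resample_isotropic <- function(v, target_spacing = 1.0, order = 3L) {
  stopifnot(inherits(v, "volume"))
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be > 0")
  if (!order %in% c(0L, 1L, 3L)) stop("order must be 0, 1 or 3")
  is_label <- inherits(v, "label_map")
  if (is_label) order <- 0L

  d <- dim(v$data)
  if (all(abs(v$spacing - target_spacing) < 1e-12)) return(v)
  nd <- pmax(1L, as.integer(round(d * v$spacing / target_spacing)))

  # output voxel-to-world: same rotation/origin, rescaled columns
  dirs <- sweep(v$xform[1:3, 1:3], 2, v$spacing, "/")  # unit direction cols
  xf_out <- diag(4)
  xf_out[1:3, 1:3] <- dirs * target_spacing
  xf_out[1:3, 4] <- v$xform[1:3, 4]

  idx <- grid_index(nd)
  world <- cbind(idx, 1) %*% t(xf_out)
  src <- cbind(world[, 1:3], 1) %*% t(solve(v$xform))
  src <- src[, 1:3, drop = FALSE]
  # the round() rule can push the last output sample marginally past the
  # input domain; clamp to the edge so constants stay constant
  for (ax in 1:3) src[, ax] <- pmin(pmax(src[, ax], 0), d[ax] - 1)
  vals <- cpp_interp3(as.double(v$data), dim(v$data),
                      src, as.integer(order), 0)
  out <- volume(array(vals, nd), spacing = rep(target_spacing, 3),
                xform = xf_out, id = v$id)
  if (is_label) out <- label_map(out)
  out
}

#' Gaussian-blur augmentation
#'
#' Returns one blurred copy of the volume per standard deviation (mm);
#' used to augment the training set (labels are left untouched and the
#' originals are retained alongside the blurred copies, so two sigmas
#' triple the training data).
#'
#' @param v a [volume].
#' @param sigmas positive standard deviations in mm.
#' @return List of blurred [volume]s, one per sigma.
#' @export
augment_blur <- function(v, sigmas = c(0.5, 1.0)) {
  stopifnot(inherits(v, "volume"), all(sigmas > 0))
  lapply(sigmas, function(s) {
    out <- v
    out$data <- array(cpp_gauss_blur3(as.double(v$data), dim(v$data),
                                      s / v$spacing), dim(v$data))
    out$id <- sprintf("%s+blur%.2g", v$id, s)
    out
  })
}
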