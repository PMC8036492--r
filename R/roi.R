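#' ROI extraction configuration
#'
#' The warped probabilistic hippocampus map is binarised (every non-zero
#' voxel set to 1), dilated by `dilation_voxels` iterations of the full
#' 3x3x3 structuring element, and the crop bounding box is the tight box
#' of the dilated mask expanded by `margin_voxels` per face (the safety
#' margin), clipped to the volume. Bounding boxes are axis-aligned in the
#' subject voxel grid, 0-based and half-open.
#'
#' @param dilation_voxels non-negative integer, default 2.
#' @param margin_voxels non-negative integer, default 2.
#' @return A list of class `roi_config`.
#' @export
roi_config <- function(dilation_voxels = 2L, margin_voxels = 2L) {
  stopifnot(dilation_voxels >= 0, margin_voxels >= 0)
  structure(list(dilation_voxels = as.integer(dilation_voxels),
                 margin_voxels = as.integer(margin_voxels),
                 binarize_threshold = "non-zero"),
            class = "roi_config")
}

#' Binarise and dilate a warped probability map
#'
#' Every non-zero voxel of the probability map becomes 1, then the mask
#' is dilated by `cfg$dilation_voxels` iterations of the 26-connected
#' 3x3x3 element (a Chebyshev ball), guaranteeing the ROI covers the full
#' hippocampus even where the atlas prior is slightly off.
#'
#' @param prob probability [volume] (or plain array), values >= 0.
#' @param cfg a [roi_config].
#' @return Integer 0/1 array of the same shape.
#' @export
binarize_and_dilate <- function(prob, cfg = roi_config()) {
  arr <- if (inherits(prob, "volume")) prob$data else prob
  if (min(arr) < 0) stop("probability map has negative values")
  bin <- as.integer(arr != 0)
  if (!any(bin == 1L))
    stop("atlas registration produced empty hippocampus map")
  out <- if (cfg$dilation_voxels > 0)
    cpp_dilate26(bin, dim(arr), cfg$dilation_voxels) else bin
  array(as.integer(out), dim(arr))
}

#' Crop a region of interest around a dilated mask
#'
#' @param image subject [volume].
#' @param dilated_mask binary array on `image`'s grid (from
#'   [binarize_and_dilate]).
#' @param cfg a [roi_config] (supplies the safety margin).
#' @param side `"left"` or `"right"`.
#' @return An object of class `roi_crop`: the cropped image, the mask on
#'   the crop grid, the 0-based bounding-box offset `bbox_lo`, the parent
#'   shape and the side.
#' @export
extract_roi <- function(image, dilated_mask, cfg = roi_config(),
                        side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(image, "volume"))
  d <- dim(image$data)
  if (!all(dim(dilated_mask) == d))
    stop("mask is not grid-aligned with the image")
  w <- which(dilated_mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty ROI mask")
  lo <- pmax(apply(w, 2, min) - 1L - cfg$margin_voxels, 0L)       # 0-based
  hi <- pmin(apply(w, 2, max) + cfg$margin_voxels, d)             # half-open
  sub <- function(a) a[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                       (lo[3] + 1):hi[3], drop = FALSE]
  img <- image
  img$data <- sub(image$data)
  # crop-grid voxel-to-world keeps world coordinates consistent
  img$xform[1:3, 4] <- image$xform[1:3, 4] +
    image$xform[1:3, 1:3] %*% lo
  structure(list(image = img,
                 dilated_mask = array(as.integer(sub(dilated_mask)),
                                      dim(img$data)),
                 bbox_lo = as.integer(lo),
                 parent_shape = as.integer(d),
                 parent_xform = image$xform,
                 side = side),
            class = "roi_crop")
}

#' @export
print.roi_crop <- function(x, ...) {
  cat(sprintf("<roi_crop> side=%s bbox_lo=(%s) shape=(%s) in parent (%s)\n",
              x$side, paste(x$bbox_lo, collapse = ","),
              paste(dim(x$image$data), collapse = ","),
              paste(x$parent_shape, collapse = ",")))
  invisible(x)
}

#' Restore a crop-grid segmentation to the full volume
#'
#' Places a binary segmentation computed on the crop grid back into the
#' parent grid, relabelling foreground as 1 (left) or 2 (right) by the
#' crop's side; everything outside the bounding box is background.
#'
#' @param seg binary array on the crop grid.
#' @param crop the [extract_roi] result the segmentation came from.
#' @return A [label_map] on the parent grid.
#' @export
restore_to_full <- function(seg, crop) {
  stopifnot(inherits(crop, "roi_crop"))
  if (!all(dim(seg) == dim(crop$image$data)))
    stop("segmentation shape does not match the crop")
  full <- array(0L, crop$parent_shape)
  lab <- if (crop$side == "left") 1L else 2L
  lo <- crop$bbox_lo
  hi <- lo + dim(seg)
  full[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <-
    as.integer(seg != 0) * lab
  parent <- volume(full,
                   spacing = crop$image$spacing,
                   xform = crop$parent_xform,
                   id = paste0(crop$image$id, ":", crop$side))
  label_map(parent)
}

#' Atlas bundles
#'
#' An atlas is a reference T1-like volume plus left/right probabilistic
#' hippocampus maps on the same grid, stored on disk as a directory of
#' three NIfTI files with a YAML manifest.
#'
#' @param reference atlas-space reference [volume].
#' @param prob_left,prob_right probabilistic [volume]s in [0,1], same
#'   grid as `reference`, with disjoint supports.
#' @return An object of class `atlas`.
#' @export
atlas <- function(reference, prob_left, prob_right) {
  for (p in list(prob_left, prob_right)) {
    if (!same_grid(p, reference)) stop("probability maps must share the reference grid")
    if (min(p$data) < 0 || max(p$data) > 1) stop("probabilities must lie in [0,1]")
  }
  if (any(prob_left$data > 0 & prob_right$data > 0))
    stop("left and right probabilistic maps must have disjoint supports")
  structure(list(reference = reference, prob_left = prob_left,
                 prob_right = prob_right),
            class = "atlas")
}

#' @rdname atlas
#' @param a an `atlas`; `dir` a directory path.
#' @export
write_atlas <- function(a, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(reference = "reference.nii.gz",
                prob_left = "hippo_left.nii.gz",
                prob_right = "hippo_right.nii.gz")
  for (nm in names(files)) write_volume(a[[nm]], file.path(dir, files[[nm]]))
  yaml::write_yaml(files, file.path(dir, "atlas.yaml"))
  invisible(dir)
}

#' @rdname atlas
#' @param dir directory holding an atlas bundle.
#' @export
read_atlas <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "atlas.yaml"))
  atlas(read_volume(file.path(dir, man$reference)),
        read_volume(file.path(dir, man$prob_left)),
        read_volume(file.path(dir, man$prob_right)))
}
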