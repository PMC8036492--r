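#' 3D scalar volume with grid geometry
#'
#' A `volume` is the currency of the pipeline: a 3D numeric array together
#' with voxel spacing (mm) and a 4x4 voxel-to-world affine (`xform`,
#' 0-based voxel indices). Label maps are volumes whose data is integer
#' with values in \{0 background, 1 left hippocampus, 2 right hippocampus\}.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param xform optional 4x4 voxel-to-world affine; defaults to a diagonal
#'   map built from `spacing` with the origin at voxel (0,0,0).
#' @param id free-text provenance string.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), xform = NULL, id = "") {
  if (length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " axes")
  if (any(dim(data) < 1L)) stop("every axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (is.null(xform)) {
    xform <- diag(c(spacing, 1))
  } else {
    xform <- as.matrix(xform)
    if (!all(dim(xform) == c(4L, 4L))) stop("xform must be 4x4")
    if (abs(det(xform)) < 1e-12) stop("voxel-to-world map is not invertible")
  }
  structure(list(data = data, spacing = spacing, xform = xform, id = id),
            class = "volume")
}

#' @rdname volume
#' @param v a `volume` whose data holds integer labels in \{0,1,2\}.
#' @export
label_map <- function(v) {
  if (!inherits(v, "volume")) v <- volume(v$data, v$spacing, v$xform, v$id)
  u <- unique(as.integer(v$data))
  if (!all(u %in% 0:2))
    stop("label map values must be in {0,1,2}, found: ",
         paste(setdiff(u, 0:2), collapse = ", "))
  storage.mode(v$data) <- "integer"
  class(v) <- c("label_map", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s\n", paste(class(x), collapse = "/"),
              if (nzchar(x$id)) x$id else "(unnamed)"))
  cat("  dim    :", paste(dim(x$data), collapse = " x "), "\n")
  cat("  spacing:", paste(format(x$spacing, digits = 4), collapse = " x "),
      "mm\n")
  rng <- range(x$data)
  cat("  range  :", format(rng[1], digits = 4), "..",
      format(rng[2], digits = 4), "\n")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

# voxel (0-based) -> world coordinates; idx is an n x 3 matrix
vox_to_world <- function(geom, idx) {
  h <- cbind(idx, 1) %*% t(geom$xform)
  h[, 1:3, drop = FALSE]
}

world_to_vox <- function(geom, pts) {
  h <- cbind(pts, 1) %*% t(solve(geom$xform))
  h[, 1:3, drop = FALSE]
}

# full 0-based index grid of a volume, n x 3 (x fastest, R array order)
grid_index <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$xform - b$xform) < tol)
}

#' Read / write volumes as NIfTI-1
#'
#' Volumes are written as double-precision NIfTI (labels as unsigned
#' 8-bit), so a write/read round trip preserves the data bit-exactly and
#' the geometry to well within 1e-6 mm.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return `read_volume`: a [volume]; `read_label_map`: a [label_map].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), " axes: ", path)
  px <- attr(img, "pixdim")[1:3]
  if (any(!is.finite(px)) || any(px <= 0))
    stop("missing or invalid voxel spacing in ", path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  volume(arr, spacing = abs(px), xform = unclass(xf)[1:4, 1:4],
         id = basename(path))
}

#' @rdname read_volume
#' @param v volume (or label map) to write.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  is_label <- inherits(v, "label_map")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(v$xform, code = 2L))
  img <- RNifti::`qform<-`(img, structure(v$xform, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_label) "uint8" else "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_label_map <- function(path) label_map(read_volume(path))
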