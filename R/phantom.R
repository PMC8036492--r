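# Synthetic brain phantoms: brain-extracted T1-like volumes with two
# mirrored curved-tube hippocampi (ground-truth labelled), an adjacent
# unlabelled amygdala-like confuser of identical intensity, smooth
# multiplicative bias, additive Gaussian noise, per-subject affine
# variability, and same-anatomy retest pairs under small rigid motion.

#' Phantom specification
#'
#' The whole anatomy is defined in fractions of the half field-of-view
#' about the volume centre, so any grid size yields a geometrically
#' similar, never-clipped phantom; at the default 96^3 at 1 mm each
#' hippocampus tube encloses roughly 3.5 mL. Tissue classes use
#' arbitrary T1-like units (CSF < GM < WM); the hippocampus and the
#' confuser share the GM mean, which is exactly what makes the
#' segmentation non-trivial on intensity alone.
#'
#' @param shape grid shape (default 96^3 at 1 mm).
#' @param spacing voxel size in mm.
#' @param intensities named vector with `csf`, `gm`, `wm` means.
#' @param noise_sd additive Gaussian noise SD (image units).
#' @param bias_amplitude relative amplitude of the multiplicative
#'   low-order polynomial bias field.
#' @param affine_translation,affine_rotation,affine_scale per-subject
#'   variability bounds: |t| <= 4 mm per axis, |angle| <= 5 degrees per
#'   axis, per-axis scale in [0.9, 1.1].
#' @param retest_translation,retest_rotation rigid retest motion bounds
#'   (<= 3 mm, <= 3 degrees).
#' @param atlas_jitter_n,atlas_seed number of jittered subjects averaged
#'   into the probabilistic atlas maps and the fixed seed used for them.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                         intensities = c(csf = 40, gm = 90, wm = 140),
                         noise_sd = 6, bias_amplitude = 0.1,
                         affine_translation = 4, affine_rotation = 5,
                         affine_scale = c(0.9, 1.1),
                         retest_translation = 3, retest_rotation = 3,
                         atlas_jitter_n = 20L, atlas_seed = 42L) {
  stopifnot(length(shape) == 3, all(shape >= 32), all(spacing > 0),
            all(c("csf", "gm", "wm") %in% names(intensities)),
            noise_sd >= 0, bias_amplitude >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 intensities = intensities, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 affine_translation = affine_translation,
                 affine_rotation = affine_rotation,
                 affine_scale = affine_scale,
                 retest_translation = retest_translation,
                 retest_rotation = retest_rotation,
                 atlas_jitter_n = as.integer(atlas_jitter_n),
                 atlas_seed = as.integer(atlas_seed),
                 # anatomy in fractions of the half field-of-view h, about
                 # the volume centre; x < 0 is "left". Sized so that the
                 # brain plus worst-case subject affine and retest motion
                 # always stays inside the grid (no clipping, which would
                 # break the rigid-retest construction).
                 hippo_p0 = c(0.275, -0.35, -0.15),
                 hippo_p1 = c(0.45, 0, -0.25),
                 hippo_p2 = c(0.30, 0.325, -0.05),
                 hippo_radius = function(t) 0.085 + 0.055 * sin(pi * t),
                 confuser_offset = c(0.025, 0.20, 0.05),
                 confuser_radius = 0.1375,
                 brain_frac = c(0.68, 0.70, 0.62),
                 gm_shell = 0.90,
                 vent_center = c(0.18, 0.12, 0.20),
                 vent_radius = c(0.14, 0.34, 0.18)),
            class = "phantom_spec")
}

# centred world coordinates (mm) of every voxel, n x 3
.centered_coords <- function(spec) {
  idx <- grid_index(spec$shape)
  ctr <- (spec$shape - 1) / 2 * spec$spacing
  sweep(idx %*% diag(spec$spacing), 2, ctr, "-")
}

# world-frame 4x4 for a transform defined about the volume centre
.about_center <- function(spec, A_centered) {
  ctr <- (spec$shape - 1) / 2 * spec$spacing
  Tc <- diag(4); Tc[1:3, 4] <- ctr
  Tci <- diag(4); Tci[1:3, 4] <- -ctr
  Tc %*% A_centered %*% Tci
}

# half field-of-view (mm): the unit all anatomy fractions refer to
.half_fov <- function(spec) min(spec$shape * spec$spacing) / 2

# signed distance-like membership of one hippocampus tube; `pts` are
# centred coords, `sgn` +1 right / -1 left. Returns logical inside flag.
.in_hippo <- function(spec, pts, sgn, nsamp = 64L) {
  h <- .half_fov(spec)
  p0 <- spec$hippo_p0 * h * c(sgn, 1, 1)
  p1 <- spec$hippo_p1 * h * c(sgn, 1, 1)
  p2 <- spec$hippo_p2 * h * c(sgn, 1, 1)
  rmax <- h * max(spec$hippo_radius(seq(0, 1, length.out = 65)))
  lo <- pmin(p0, p1, p2) - rmax - 1
  hi <- pmax(p0, p1, p2) + rmax + 1
  cand <- which(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
                pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
                pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
  inside <- logical(nrow(pts))
  if (!length(cand)) return(inside)
  sub <- pts[cand, , drop = FALSE]
  best <- rep(Inf, nrow(sub))
  ts <- seq(0, 1, length.out = nsamp)
  for (t in ts) {
    p <- (1 - t)^2 * p0 + 2 * (1 - t) * t * p1 + t^2 * p2
    dd <- sqrt((sub[, 1] - p[1])^2 + (sub[, 2] - p[2])^2 +
               (sub[, 3] - p[3])^2) - h * spec$hippo_radius(t)
    best <- pmin(best, dd)
  }
  inside[cand] <- best <= 0
  inside
}

# tissue template and labels evaluated at centred coords `pts`
.anatomy_at <- function(spec, pts) {
  h <- .half_fov(spec)
  br <- spec$brain_frac * h
  rho2 <- (pts[, 1] / br[1])^2 + (pts[, 2] / br[2])^2 + (pts[, 3] / br[3])^2
  tissue <- numeric(nrow(pts))
  inten <- spec$intensities
  inbrain <- rho2 <= 1
  tissue[inbrain] <- inten["wm"]
  tissue[inbrain & rho2 > spec$gm_shell^2] <- inten["gm"]
  # ventricles (CSF), mirrored
  vc <- spec$vent_center * h
  vr <- spec$vent_radius * h
  for (sgn in c(-1, 1)) {
    v2 <- ((pts[, 1] - sgn * vc[1]) / vr[1])^2 +
      ((pts[, 2] - vc[2]) / vr[2])^2 + ((pts[, 3] - vc[3]) / vr[3])^2
    tissue[inbrain & v2 <= 1] <- inten["csf"]
  }
  label <- integer(nrow(pts))
  in_l <- .in_hippo(spec, pts, -1)
  in_r <- .in_hippo(spec, pts, +1)
  # amygdala-like confuser: GM sphere abutting the anterior tube end,
  # carved so it never overlaps a labelled voxel
  for (sgn in c(-1, 1)) {
    cc <- (spec$hippo_p2 + spec$confuser_offset) * h * c(sgn, 1, 1)
    c2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2 + (pts[, 3] - cc[3])^2
    conf <- inbrain & c2 <= (spec$confuser_radius * h)^2 & !in_l & !in_r
    tissue[conf] <- inten["gm"]
  }
  tissue[in_l | in_r] <- inten["gm"]
  label[in_l & inbrain] <- 1L
  label[in_r & inbrain] <- 2L
  # tubes must stay inside the rendered brain
  if (any((in_l | in_r) & !inbrain))
    stop("hippocampus tube extends outside the brain envelope")
  tissue[!inbrain] <- 0
  list(tissue = tissue, label = label)
}

# random affine/rigid parameter draws (centred frame)
.draw_subject_affine <- function(spec) {
  t <- stats::runif(3, -spec$affine_translation, spec$affine_translation)
  r <- stats::runif(3, -spec$affine_rotation, spec$affine_rotation) * pi / 180
  s <- stats::runif(3, spec$affine_scale[1], spec$affine_scale[2])
  params_to_affine(c(t, r, log(s)), center = c(0, 0, 0))
}

.draw_rigid_motion <- function(spec) {
  t <- stats::runif(3, -spec$retest_translation, spec$retest_translation)
  r <- stats::runif(3, -spec$retest_rotation, spec$retest_rotation) * pi / 180
  params_to_affine(c(t, r), center = c(0, 0, 0))
}

# render a phantom: anatomy seen through `map` (centred coords), bias
# through `bias_map`; returns data arrays
.render <- function(spec, map = diag(4), bias_coef = NULL,
                    bias_map = diag(4), noise = NULL) {
  pts <- .centered_coords(spec)
  h <- cbind(pts, 1) %*% t(map)
  an <- .anatomy_at(spec, h[, 1:3, drop = FALSE])
  img <- an$tissue
  if (!is.null(bias_coef) && spec$bias_amplitude > 0) {
    hb <- cbind(pts, 1) %*% t(bias_map)
    u <- sweep(hb[, 1:3, drop = FALSE], 2, spec$shape * spec$spacing / 2, "/")
    f <- cbind(u, u^2) %*% bias_coef
    f <- f / max(abs(f))
    img <- img * (1 + spec$bias_amplitude * as.numeric(f))
  }
  if (!is.null(noise)) img <- img + noise
  img[an$tissue == 0] <- 0  # brain-extracted: background exactly zero
  img <- array(img, spec$shape)
  lab <- array(an$label, spec$shape)
  # the anatomy must stay strictly inside the field of view: a clipped
  # brain is no longer a rigid/affine transform of its canonical self
  d <- spec$shape
  if (any(img[c(1, d[1]), , ] != 0) || any(img[, c(1, d[2]), ] != 0) ||
      any(img[, , c(1, d[3])] != 0))
    stop("anatomy leaves the field of view; use a larger grid or smaller variability")
  list(image = img, label = lab)
}

#' Generate one phantom subject
#'
#' Deterministic given `(spec, seed)`: a per-subject random affine is
#' applied to the canonical anatomy, a random low-order polynomial bias
#' field multiplies the tissue template, Gaussian noise is added inside
#' the brain, and the background stays exactly zero (brain-extracted).
#' The ground-truth label map marks the two hippocampus tubes (1 left,
#' 2 right); the confuser blob shares their intensity but is unlabelled.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed.
#' @return List with `image` ([volume]), `labels` ([label_map]) and
#'   `meta` (the subject affine in the centred frame, its world-frame
#'   4x4, and the transform an atlas-to-subject registration should
#'   recover).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 0L) {
  set.seed(seed)
  A <- .draw_subject_affine(spec)
  bias_coef <- stats::rnorm(6)
  noise <- if (spec$noise_sd > 0)
    stats::rnorm(prod(spec$shape), sd = spec$noise_sd) else NULL
  r <- .render(spec, map = solve(A), bias_coef = bias_coef, noise = noise)
  A_world <- .about_center(spec, A)
  id <- sprintf("phantom_seed%d", seed)
  list(image = volume(r$image, spec$spacing, id = id),
       labels = label_map(volume(r$label, spec$spacing, id = paste0(id, "_labels"))),
       meta = list(seed = seed, affine_centered = A, affine_world = A_world,
                   expected_registration = solve(A_world)))
}

#' Generate the toy atlas matching a phantom spec
#'
#' The atlas reference is the canonical (zero-variability, zero-noise,
#' zero-bias) phantom; the probabilistic maps average the true labels of
#' `spec$atlas_jitter_n` jittered subjects, so values lie in [0,1], peak
#' at 1 in the structure core, and the support covers any conforming
#' subject's truth after correct registration.
#'
#' @param spec a [phantom_spec].
#' @return An [atlas].
#' @export
generate_atlas <- function(spec = phantom_spec()) {
  ref <- .render(spec)
  pts <- .centered_coords(spec)
  accL <- accR <- numeric(prod(spec$shape))
  set.seed(spec$atlas_seed)
  jit <- replicate(spec$atlas_jitter_n, .draw_subject_affine(spec),
                   simplify = FALSE)
  for (J in jit) {
    h <- cbind(pts, 1) %*% t(solve(J))
    an <- .anatomy_at(spec, h[, 1:3, drop = FALSE])
    accL <- accL + (an$label == 1L)
    accR <- accR + (an$label == 2L)
  }
  n <- spec$atlas_jitter_n
  atlas(volume(ref$image, spec$spacing, id = "atlas_reference"),
        volume(array(accL / n, spec$shape), spec$spacing, id = "atlas_prob_left"),
        volume(array(accR / n, spec$shape), spec$spacing, id = "atlas_prob_right"))
}

#' Generate a cohort of independent phantoms
#'
#' Per-subject seeds are drawn from one stream seeded with `seed`, so the
#' whole cohort is reproducible from `(spec, n, seed)`.
#'
#' @param spec a [phantom_spec].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return List of [generate_phantom] results.
#' @export
generate_cohort <- function(spec = phantom_spec(), n, seed = 0L) {
  stopifnot(n >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seeds, function(s) generate_phantom(spec, s))
}

#' Deterministic train/validation/test split
#'
#' Train and validation sizes are floors of the requested fractions; the
#' remainder goes to the test split (25 subjects at 0.8/0.1/0.1 gives
#' 20/2/3).
#'
#' @param n cohort size.
#' @param fractions length-3 positive fractions summing to 1.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(n, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  list(train = seq_len(n_train),
       val = n_train + seq_len(n_val),
       test = if (n_train + n_val < n) (n_train + n_val + 1):n else integer(0))
}

#' Generate a same-session retest pair
#'
#' Scan 2 is scan 1's noiseless anatomy (subject affine and bias
#' included) seen through a small rigid motion, plus an independent
#' noise draw — the same anatomy imaged twice with repositioning. The
#' applied motion is recorded, along with the transform a rigid
#' registration of scan 2 onto scan 1 should recover (its inverse).
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed.
#' @return List with `scan1`, `scan2` ([volume]s), `labels`
#'   ([label_map], scan-1 frame) and `meta` (subject affine, applied
#'   motion, expected rigid recovery, scan-2 frame labels).
#' @export
generate_retest_pair <- function(spec = phantom_spec(), seed = 0L) {
  set.seed(seed)
  A <- .draw_subject_affine(spec)
  bias_coef <- stats::rnorm(6)
  M <- .draw_rigid_motion(spec)
  n1 <- if (spec$noise_sd > 0)
    stats::rnorm(prod(spec$shape), sd = spec$noise_sd) else NULL
  n2 <- if (spec$noise_sd > 0)
    stats::rnorm(prod(spec$shape), sd = spec$noise_sd) else NULL
  r1 <- .render(spec, map = solve(A), bias_coef = bias_coef, noise = n1)
  r2 <- .render(spec, map = solve(A) %*% M, bias_coef = bias_coef,
                bias_map = M, noise = n2)
  M_world <- .about_center(spec, M)
  id <- sprintf("retest_seed%d", seed)
  list(scan1 = volume(r1$image, spec$spacing, id = paste0(id, "_s1")),
       scan2 = volume(r2$image, spec$spacing, id = paste0(id, "_s2")),
       labels = label_map(volume(r1$label, spec$spacing,
                                 id = paste0(id, "_labels"))),
       meta = list(seed = seed, affine_centered = A, motion_world = M_world,
                   expected_rigid = solve(M_world),
                   labels2 = array(r2$label, spec$shape)))
}

#' Write a phantom fixture set to disk
#'
#' A directory of NIfTI image/label pairs plus a YAML manifest recording
#' the spec, the seed and the split.
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory.
#' @param split optional [split_cohort] result.
#' @param seed the seed the cohort was generated with (recorded).
#' @export
write_fixture_set <- function(cohort, dir, split = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(cohort)) {
    im <- sprintf("subject%03d.nii.gz", i)
    lb <- sprintf("subject%03d_labels.nii.gz", i)
    write_volume(cohort[[i]]$image, file.path(dir, im))
    write_volume(cohort[[i]]$labels, file.path(dir, lb))
    entries[[i]] <- list(image = im, labels = lb,
                         seed = cohort[[i]]$meta$seed)
  }
  yaml::write_yaml(list(n = length(cohort), seed = seed,
                        split = lapply(split, as.integer),
                        subjects = entries),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
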