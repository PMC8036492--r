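# Normalisation region used by the pipeline: the non-zero (brain) support
# eroded by two voxels. Resampling a co-registered scan blends a
# partial-volume shell of intermediate intensities around the brain
# boundary; including that shell in the statistics would shift the
# z-scores of a warped scan relative to a native one and break the
# comparability the test-retest protocol relies on. Erosion removes the
# shell for native and resampled inputs alike.
.norm_region <- function(v, iters = 2L) {
  bg <- cpp_dilate26(as.integer(v$data == 0), dim(v$data), iters)
  m <- array(1L - as.integer(bg), dim(v$data))
  if (!any(m != 0)) m <- array(as.integer(v$data != 0), dim(v$data))
  m
}

#' Segment one volume with the full two-stage pipeline
#'
#' Stage order: isotropic resampling and intensity standardisation;
#' affine then (optionally) non-linear registration of the atlas
#' reference to the subject; warping of each probabilistic hippocampus
#' map; binarisation and dilation; bounding-box crop with safety margin
#' (one independent crop per side); dense network inference inside each
#' crop; in-mask thresholding; restoration to the full grid and merging
#' of the two sides. If both sides ever claimed a voxel (impossible for
#' atlases with disjoint supports), the left label wins with a warning.
#'
#' @param vol subject [volume] (T1-weighted, brain-extracted).
#' @param atl an [atlas].
#' @param model a trained `hipposeg_model`.
#' @param cfg a [roi_config].
#' @param nonlinear run the demons refinement after the affine stage.
#' @param verbose print per-stage timings to stderr.
#' @return List: `labels` ([label_map] on the 1 mm working grid),
#'   `crops` (left/right [extract_roi] results), `probs` (per-side
#'   probability arrays), `transform` (the atlas registration).
#' @export
segment_volume <- function(vol, atl, model, cfg = roi_config(),
                           nonlinear = TRUE, verbose = FALSE) {
  stopifnot(inherits(atl, "atlas"), inherits(model, "hipposeg_model"))
  say <- function(stage, t0) if (verbose)
    message(sprintf("  [%s] %.2fs", stage, (proc.time() - t0)[["elapsed"]]))

  t0 <- proc.time()
  v <- resample_isotropic(vol, 1.0, order = 3L)
  v <- normalize_intensity(v, mask = .norm_region(v))
  ref <- normalize_intensity(atl$reference, mask = .norm_region(atl$reference))
  say("preprocess", t0)

  t0 <- proc.time()
  tr <- register_affine(moving = ref, fixed = v)
  if (nonlinear) tr <- register_nonlinear(moving = ref, fixed = v, init = tr)
  say("register", t0)

  crops <- list(); probs <- list(); maps <- list()
  for (side in c("left", "right")) {
    t0 <- proc.time()
    pm <- if (side == "left") atl$prob_left else atl$prob_right
    warped <- warp_probability_map(pm, tr, v)
    mask <- binarize_and_dilate(warped, cfg)
    crop <- extract_roi(v, mask, cfg, side)
    prob <- predict_roi(model, crop)
    seg <- finalize_segmentation(prob, crop)
    maps[[side]] <- restore_to_full(seg, crop)
    crops[[side]] <- crop
    probs[[side]] <- prob
    say(paste0("segment_", side), t0)
  }

  merged <- maps$left$data
  clash <- merged != 0L & maps$right$data != 0L
  if (any(clash))
    warning(sum(clash), " voxels claimed by both sides; keeping left")
  merged[merged == 0L] <- maps$right$data[merged == 0L]
  out <- label_map(volume(merged, v$spacing, v$xform,
                          id = paste0(vol$id, ":segmentation")))
  list(labels = out, crops = crops, probs = probs, transform = tr,
       preprocessed = v)
}

#' Batch segmentation over NIfTI files
#'
#' Thin file-level driver around [segment_volume]: reads each input,
#' segments it, writes `<name>_seg.nii.gz`, and (when ground-truth label
#' files are supplied) reports per-side Dice. A failure in one subject
#' aborts that subject only; the summary lists failures.
#'
#' @param inputs character vector of NIfTI paths.
#' @param atlas_dir atlas bundle directory (see [write_atlas]).
#' @param checkpoint model checkpoint path (see [save_checkpoint]).
#' @param out_dir output directory.
#' @param truths optional character vector of label-map paths matching
#'   `inputs`.
#' @param cfg a [roi_config].
#' @param nonlinear,verbose passed to [segment_volume].
#' @return Data frame summary (one row per subject and side).
#' @export
run_segment <- function(inputs, atlas_dir, checkpoint, out_dir,
                        truths = NULL, cfg = roi_config(),
                        nonlinear = TRUE, verbose = FALSE) {
  if (!file.exists(checkpoint)) stop("checkpoint not found: ", checkpoint)
  model <- load_checkpoint(checkpoint)
  atl <- read_atlas(atlas_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      vol <- read_volume(inputs[i])
      r <- segment_volume(vol, atl, model, cfg, nonlinear, verbose)
      out <- file.path(out_dir, sub("\\.nii(\\.gz)?$", "_seg.nii.gz",
                                    basename(inputs[i])))
      write_volume(r$labels, out)
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", inputs[i], " failed: ", conditionMessage(res))
      rows[[length(rows) + 1]] <- data.frame(
        input = inputs[i], side = NA, dice = NA_real_, status = "failed")
      next
    }
    for (side in c("left", "right")) {
      lab <- if (side == "left") 1L else 2L
      d <- NA_real_
      if (!is.null(truths)) {
        tru <- read_label_map(truths[i])
        tru <- resample_isotropic(tru, 1.0)
        d <- dice_coefficient(res$labels$data == lab, tru$data == lab)
      }
      rows[[length(rows) + 1]] <- data.frame(
        input = inputs[i], side = side, dice = d, status = "ok")
    }
  }
  do.call(rbind, rows)
}

#' Train from a phantom fixture directory
#'
#' Reads a [write_fixture_set] manifest, builds ROI crops for every
#' train/validation subject with the supplied atlas, trains the network
#' and writes a checkpoint plus the training-log CSV.
#'
#' @param cohort_dir fixture directory with `manifest.yaml`.
#' @param atlas_dir atlas bundle directory.
#' @param checkpoint output checkpoint path.
#' @param net_cfg a [net_config].
#' @param cfg a [train_config].
#' @param roi_cfg a [roi_config].
#' @param nonlinear use non-linear registration for ROI localisation.
#' @return The trained model, invisibly.
#' @export
run_train <- function(cohort_dir, atlas_dir, checkpoint,
                      net_cfg = net_config(), cfg = train_config(),
                      roi_cfg = roi_config(), nonlinear = FALSE) {
  man <- yaml::read_yaml(file.path(cohort_dir, "manifest.yaml"))
  if (is.null(man$split) || !length(man$split$train) || !length(man$split$val))
    stop("manifest must provide non-empty train and val splits")
  atl <- read_atlas(atlas_dir)
  load_crops <- function(ids) {
    out <- list()
    for (i in ids) {
      img <- read_volume(file.path(cohort_dir, man$subjects[[i]]$image))
      tru <- read_label_map(file.path(cohort_dir, man$subjects[[i]]$labels))
      out <- c(out, roi_crops_with_truth(img, tru, atl, roi_cfg, nonlinear))
    }
    out
  }
  tr <- load_crops(man$split$train)
  va <- load_crops(man$split$val)
  set.seed(cfg$seed)
  model <- build_network(net_cfg)
  model <- train_network(model, tr, va, cfg)
  save_checkpoint(model, checkpoint)
  invisible(model)
}

#' Build per-side training crops for one subject
#'
#' Runs the atlas-ROI stage on a subject and attaches the ground truth
#' to the left and right crops (truth outside the dilated mask becomes
#' background).
#'
#' @param vol subject [volume].
#' @param truth matching [label_map].
#' @param atl an [atlas].
#' @param cfg a [roi_config].
#' @param nonlinear use the demons refinement.
#' @return List of two crops (left, right) carrying `truth` arrays.
#' @export
roi_crops_with_truth <- function(vol, truth, atl, cfg = roi_config(),
                                 nonlinear = FALSE) {
  v <- resample_isotropic(vol, 1.0, order = 3L)
  v <- normalize_intensity(v, mask = .norm_region(v))
  tru <- resample_isotropic(truth, 1.0)
  ref <- normalize_intensity(atl$reference, mask = .norm_region(atl$reference))
  tr <- register_affine(moving = ref, fixed = v)
  if (nonlinear) tr <- register_nonlinear(moving = ref, fixed = v, init = tr)
  lapply(c("left", "right"), function(side) {
    pm <- if (side == "left") atl$prob_left else atl$prob_right
    mask <- binarize_and_dilate(warp_probability_map(pm, tr, v), cfg)
    training_crop(extract_roi(v, mask, cfg, side), tru)
  })
}

#' Test-retest evaluation over a directory of pairs
#'
#' @param pairs list of `list(scan1, scan2)` [volume] pairs (e.g. from
#'   [generate_retest_pair]).
#' @param atlas_dir atlas bundle directory.
#' @param checkpoint trained checkpoint path.
#' @param out_csv,out_yaml optional report paths.
#' @param cfg a [roi_config].
#' @param nonlinear passed to [segment_volume].
#' @return The [test_retest_precision] data frame.
#' @export
run_retest <- function(pairs, atlas_dir, checkpoint, out_csv = NULL,
                       out_yaml = NULL, cfg = roi_config(),
                       nonlinear = FALSE) {
  if (!file.exists(checkpoint)) stop("checkpoint not found: ", checkpoint)
  model <- load_checkpoint(checkpoint)
  atl <- read_atlas(atlas_dir)
  segmenter <- function(v)
    segment_volume(v, atl, model, cfg, nonlinear = nonlinear)$labels
  rep <- test_retest_precision(pairs, segmenter)
  if (!is.null(out_csv))
    write_report(rep, summarize_retest(rep), out_csv, out_yaml)
  rep
}
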