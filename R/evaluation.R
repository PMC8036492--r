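#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A|+|B|)` between two binary masks on the same grid; 1 is
#' perfect overlap, 0 none. When both masks are empty the ratio is
#' undefined and `NA` is returned (rather than 1, which would silently
#' inflate agreement).
#'
#' @param a,b binary arrays (or [volume]s) on the same grid.
#' @return Dice fraction in [0,1], or `NA` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- if (inherits(a, "volume")) a$data else a
  b <- if (inherits(b, "volume")) b$data else b
  if (!all(dim(a) == dim(b))) stop("masks are not on the same grid")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Mask volume in millilitres
#'
#' @param m binary array (or [volume]).
#' @param spacing voxel size in mm (taken from `m` if it is a volume).
#' @return `count(m) * voxel volume / 1000` in mL.
#' @export
volume_ml <- function(m, spacing = NULL) {
  if (inherits(m, "volume")) {
    if (is.null(spacing)) spacing <- m$spacing
    m <- m$data
  }
  stopifnot(!is.null(spacing), all(spacing > 0))
  sum(m != 0) * prod(spacing) / 1000
}

#' Test-retest precision protocol
#'
#' For each same-session scan pair, the second scan is rigidly registered
#' to the first (normalised cross-correlation, linear interpolation), both
#' co-registered images are then segmented independently by the supplied
#' segmenter, and per-side Dice overlap and absolute volume difference
#' are reported. A registration failure drops that session with a
#' warning.
#'
#' @param pairs list of `list(scan1, scan2)` [volume] pairs.
#' @param segmenter function mapping a [volume] to a [label_map] (the
#'   full pipeline; see [segment_volume]).
#' @return A data frame with one row per session and side: `session`,
#'   `side`, `dice`, `vol1_ml`, `vol2_ml`, `abs_dv_ml`.
#' @export
test_retest_precision <- function(pairs, segmenter) {
  rows <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    t <- tryCatch(rigid_register(moving = p[[2]], fixed = p[[1]]),
                  error = function(e) {
                    warning("session ", i, ": rigid registration failed (",
                            conditionMessage(e), "); skipped")
                    NULL
                  })
    if (is.null(t)) next
    scan2_co <- warp_volume(p[[2]], t, p[[1]], order = 1L)
    seg1 <- segmenter(p[[1]])
    seg2 <- segmenter(scan2_co)
    for (side in c("left", "right")) {
      lab <- if (side == "left") 1L else 2L
      m1 <- seg1$data == lab
      m2 <- seg2$data == lab
      v1 <- volume_ml(m1, seg1$spacing)
      v2 <- volume_ml(m2, seg2$spacing)
      rows[[length(rows) + 1]] <- data.frame(
        session = i, side = side,
        dice = dice_coefficient(m1, m2),
        vol1_ml = v1, vol2_ml = v2, abs_dv_ml = abs(v1 - v2))
    }
  }
  do.call(rbind, rows)
}

#' Summarise a test-retest report
#'
#' @param report data frame from [test_retest_precision].
#' @return List of per-side means and SDs of Dice and |dV|.
#' @export
summarize_retest <- function(report) {
  out <- list()
  for (side in unique(report$side)) {
    r <- report[report$side == side, ]
    out[[side]] <- list(mean_dice = mean(r$dice, na.rm = TRUE),
                        sd_dice = stats::sd(r$dice),
                        mean_abs_dv_ml = mean(r$abs_dv_ml),
                        sd_abs_dv_ml = stats::sd(r$abs_dv_ml))
  }
  out
}

#' Compare two methods' metric samples
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two samples of
#' a quality metric (e.g. per-subject Dice of two segmentation methods):
#' exact enumeration when `n + m <= 12` and there are no ties, the
#' tie-corrected normal approximation otherwise. An unpaired rank-sum
#' test is the published convention for this comparison even when
#' observations are paired per subject; set `paired = TRUE` for the
#' signed-rank variant.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param paired use the Wilcoxon signed-rank test instead.
#' @return Two-sided p-value.
#' @export
compare_methods <- function(sample_a, sample_b, paired = FALSE) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (length(unique(c(sample_a, sample_b))) == 1L) return(1)
  if (paired)
    return(stats::wilcox.test(sample_a, sample_b, paired = TRUE,
                              exact = FALSE, correct = TRUE)$p.value)
  ties <- any(duplicated(c(sample_a, sample_b)))
  n <- length(sample_a) + length(sample_b)
  if (!ties && n <= 12)
    stats::wilcox.test(sample_a, sample_b, exact = TRUE)$p.value
  else
    suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                         correct = TRUE)$p.value)
}

#' Write evaluation reports
#'
#' One CSV row per subject/session/side/method plus a YAML summary of
#' means, SDs and p-values.
#'
#' @param report a data frame (e.g. from [test_retest_precision]).
#' @param summary named list of summary statistics.
#' @param csv_path,yaml_path output paths.
#' @export
write_report <- function(report, summary, csv_path, yaml_path = NULL) {
  write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(yaml_path)) yaml::write_yaml(summary, yaml_path)
  invisible(csv_path)
}
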