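#' Network architecture configuration
#'
#' The voxel classifier is a plain feed-forward stack of unpadded
#' (valid) 3x3x3 convolutions with ReLU activations and no pooling or
#' striding, followed by a pointwise 1x1x1 classification layer with a
#' per-voxel softmax over \{background, hippocampus\}. The default is the
#' production configuration: nine hidden layers whose feature maps grow
#' from 20 in steps of 5 up to 60 (a "funnel" shape), giving a 19^3
#' receptive field. Dropout (rate 0.5 by default) is applied after the
#' last two hidden layers during training.
#'
#' @param n_hidden_layers number of 3x3x3 hidden layers.
#' @param feature_maps integer vector, one per hidden layer,
#'   non-decreasing.
#' @param kernel per-axis kernel size of hidden layers (cubic; only the
#'   first element is used and must be odd).
#' @param dropout_rate dropout probability during training.
#' @param dropout_layers indices of hidden layers carrying dropout
#'   (default: the last two).
#' @param n_classes number of output classes.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_hidden_layers = 9L,
                       feature_maps = seq(20L, 60L, by = 5L),
                       kernel = c(3L, 3L, 3L),
                       dropout_rate = 0.5,
                       dropout_layers = NULL,
                       n_classes = 2L) {
  n_hidden_layers <- as.integer(n_hidden_layers)
  feature_maps <- as.integer(feature_maps)
  if (length(feature_maps) != n_hidden_layers)
    stop("feature_maps must have one entry per hidden layer (",
         n_hidden_layers, "), got ", length(feature_maps))
  if (n_hidden_layers > 0 && any(diff(feature_maps) < 0))
    stop("feature_maps must be non-decreasing (funnel shape)")
  k <- as.integer(kernel[1])
  if (k %% 2L != 1L || k < 1L) stop("kernel size must be odd and positive")
  if (is.null(dropout_layers))
    dropout_layers <- if (n_hidden_layers >= 2)
      c(n_hidden_layers - 1L, n_hidden_layers) else integer(0)
  structure(list(n_hidden_layers = n_hidden_layers,
                 feature_maps = feature_maps,
                 kernel = rep(k, 3L),
                 classifier_kernel = c(1L, 1L, 1L),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 dropout_layers = as.integer(dropout_layers)),
            class = "net_config")
}

#' Receptive field of the convolution stack
#'
#' One output voxel sees `1 + sum(kernel - 1)` input voxels per axis; an
#' input patch of exactly this side yields a 1x1x1 output.
#'
#' @param cfg a [net_config].
#' @return Integer receptive-field side length.
#' @export
receptive_field <- function(cfg) {
  1L + cfg$n_hidden_layers * (cfg$kernel[1] - 1L)
}

# layer sizes as (cin, cout, k) triples, classifier last
layer_shapes <- function(cfg) {
  chans <- c(1L, cfg$feature_maps, cfg$n_classes)
  k <- c(rep(cfg$kernel[1], cfg$n_hidden_layers), 1L)
  lapply(seq_len(cfg$n_hidden_layers + 1L), function(l)
    list(cin = chans[l], cout = chans[l + 1], k = k[l]))
}

#' Number of trainable parameters
#'
#' @param cfg a [net_config].
#' @return Total count of weights and biases,
#'   `sum_l (k^3 c_{l-1} c_l + c_l) + (c_last n_classes + n_classes)`.
#' @export
n_parameters <- function(cfg) {
  sum(vapply(layer_shapes(cfg),
             function(s) s$k^3 * s$cin * s$cout + s$cout, numeric(1)))
}

#' Build an untrained model
#'
#' Initialises the convolution stack with He-scaled Gaussian weights
#' (SD `sqrt(2 / fan_in)`) and zero biases, using the current RNG state.
#'
#' @param cfg a [net_config].
#' @return An object of class `hipposeg_model` (untrained).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  shapes <- layer_shapes(cfg)
  W <- lapply(shapes, function(s) {
    fan_in <- s$k^3 * s$cin
    matrix(stats::rnorm(fan_in * s$cout, sd = sqrt(2 / fan_in)),
           nrow = fan_in, ncol = s$cout)
  })
  b <- lapply(shapes, function(s) numeric(s$cout))
  structure(list(config = cfg,
                 weights = list(W = W, b = b),
                 train_config = NULL,
                 training_log = NULL,
                 best_epoch = NA_integer_,
                 trained = FALSE),
            class = "hipposeg_model")
}

# kernel size vector passed to the C++ stack
.kern_vec <- function(cfg) c(rep(cfg$kernel[1], cfg$n_hidden_layers), 1L)

# reflect-pad index vector: 0-based positions `pos` folded into [0, n-1]
# by mirroring about the edge voxels (period 2n - 2)
reflect_index <- function(pos, n) {
  if (n == 1L) return(rep(0L, length(pos)))
  p <- 2L * (n - 1L)
  q <- pos %% p
  q[q < 0] <- q[q < 0] + p
  ifelse(q > n - 1L, p - q, q) + 1L  # return 1-based
}

# extract a reflect-padded cube of side `s` centred at 1-based `center`
extract_patch <- function(arr, center, s) {
  h <- (s - 1L) %/% 2L
  d <- dim(arr)
  if (any(s > 2L * d - 1L))
    stop("crop is smaller than the patch even after reflect padding")
  ix <- reflect_index((center[1] - 1L - h):(center[1] - 1L + h), d[1])
  iy <- reflect_index((center[2] - 1L - h):(center[2] - 1L + h), d[2])
  iz <- reflect_index((center[3] - 1L - h):(center[3] - 1L + h), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

#' Dense in-ROI inference
#'
#' Runs the fully-convolutional network over a whole ROI crop. The crop
#' is reflect-padded by half the receptive field so the output grid
#' equals the crop grid; dropout is disabled.
#'
#' @param model a trained (or at least built) `hipposeg_model`.
#' @param crop an [extract_roi] result, or a bare 3D array.
#' @return 3D array of foreground probabilities on the crop grid.
#' @export
predict_roi <- function(model, crop) {
  stopifnot(inherits(model, "hipposeg_model"))
  arr <- if (inherits(crop, "roi_crop")) crop$image$data else crop
  cfg <- model$config
  .check_weights(model)
  rf <- receptive_field(cfg)
  h <- (rf - 1L) %/% 2L
  d <- dim(arr)
  ix <- reflect_index((-h):(d[1] - 1L + h), d[1])
  iy <- reflect_index((-h):(d[2] - 1L + h), d[2])
  iz <- reflect_index((-h):(d[3] - 1L + h), d[3])
  padded <- arr[ix, iy, iz, drop = FALSE]
  res <- cpp_net_apply(as.double(padded), c(dim(padded), 1L),
                       model$weights$W, model$weights$b,
                       .kern_vec(cfg), vector("list", cfg$n_hidden_layers),
                       NULL)
  stopifnot(all(res$odim == d))
  array(res$prob[, 2L], d)
}

.check_weights <- function(model) {
  shapes <- layer_shapes(model$config)
  W <- model$weights$W
  if (length(W) != length(shapes))
    stop("weights do not match the network configuration")
  for (l in seq_along(shapes)) {
    s <- shapes[[l]]
    if (!all(dim(W[[l]]) == c(s$k^3 * s$cin, s$cout)))
      stop("weights do not match the network configuration (layer ", l, ")")
  }
  invisible(TRUE)
}

#' Final in-mask thresholding
#'
#' Foreground where the predicted foreground probability strictly exceeds
#' 0.5 *and* the voxel lies inside the dilated atlas mask; every voxel
#' outside the mask (but inside the bounding box) is background by
#' definition, and probability ties go to background.
#'
#' @param prob foreground-probability array from [predict_roi].
#' @param crop the corresponding [extract_roi] result.
#' @return Integer 0/1 array on the crop grid.
#' @export
finalize_segmentation <- function(prob, crop) {
  stopifnot(inherits(crop, "roi_crop"),
            all(dim(prob) == dim(crop$dilated_mask)))
  array(as.integer(prob > 0.5 & crop$dilated_mask != 0), dim(prob))
}
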