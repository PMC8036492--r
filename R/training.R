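#' Training configuration
#'
#' Defaults follow the production recipe: mini-batches of 20 patches for
#' 10 epochs of voxel-wise cross-entropy, initial learning rate 0.006
#' halved whenever the validation Dice fails to improve by more than
#' `lr_min_delta` for `lr_patience` consecutive epochs, L1 weight penalty
#' 1e-6 and L2 penalty 1e-4, SGD with momentum 0.9 (set
#' `optimizer = "adam"` for Adam), and Gaussian-blur augmentation with
#' SDs 0.5 and 1.0 mm. Patches are class-balanced: each one is centred on
#' a foreground or a background voxel with probability 1/2. `out_side`
#' is the cubic side of the training target; input patches have side
#' `receptive_field + out_side - 1` (27 for the default nine-layer
#' network with `out_side = 9`).
#'
#' @param batch_size patches per optimisation step.
#' @param epochs full passes over the training crops.
#' @param lr_init initial learning rate.
#' @param l1,l2 regularisation weights on the convolution weights
#'   (penalty `l1*||W||_1 + l2*||W||_2^2`).
#' @param momentum SGD momentum.
#' @param optimizer `"sgd"` (momentum SGD) or `"adam"`.
#' @param out_side training output cube side.
#' @param patches_per_crop patches drawn per crop per epoch.
#' @param augment_sigmas Gaussian-blur augmentation SDs in mm (NULL or
#'   empty disables augmentation).
#' @param lr_patience,lr_min_delta plateau rule for halving the rate.
#' @param seed RNG seed for sampling, dropout and initial shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 20L, epochs = 10L, lr_init = 0.006,
                         l1 = 1e-6, l2 = 1e-4, momentum = 0.9,
                         optimizer = c("sgd", "adam"),
                         out_side = 9L, patches_per_crop = 2L,
                         augment_sigmas = c(0.5, 1.0),
                         lr_patience = 2L, lr_min_delta = 1e-3,
                         seed = 0L) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, epochs >= 1, lr_init > 0,
            out_side >= 1, out_side %% 2 == 1,
            is.null(augment_sigmas) || all(augment_sigmas > 0))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_init = lr_init,
                 l1 = l1, l2 = l2, momentum = momentum,
                 optimizer = optimizer,
                 out_side = as.integer(out_side),
                 patches_per_crop = as.integer(patches_per_crop),
                 augment_sigmas = augment_sigmas,
                 lr_patience = as.integer(lr_patience),
                 lr_min_delta = lr_min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

# attach ground truth to a crop: truth voxels outside the dilated mask are
# background by definition
training_crop <- function(crop, truth_full) {
  stopifnot(inherits(crop, "roi_crop"))
  lo <- crop$bbox_lo
  hi <- lo + dim(crop$image$data)
  t_arr <- if (inherits(truth_full, "volume")) truth_full$data else truth_full
  lab <- if (crop$side == "left") 1L else 2L
  sub <- t_arr[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
               drop = FALSE]
  tr <- array(as.integer(sub == lab & crop$dilated_mask != 0), dim(sub))
  crop$truth <- tr
  crop
}

#' Sample a class-balanced training batch
#'
#' Draws `cfg$batch_size` patch pairs from the supplied training crops.
#' Each patch is centred on a uniformly drawn foreground voxel or
#' background voxel of a uniformly drawn crop, with probability 1/2 each
#' (crops without foreground always contribute background patches).
#' Input patches have side `receptive_field + out_side - 1` and are
#' reflect-padded at crop borders; targets are the matching
#' `out_side`^3 truth cubes. Uses the current RNG state, so a fixed seed
#' reproduces the batch sequence exactly.
#'
#' @param crops list of crops carrying a `truth` array (see
#'   [train_network]; truth outside the dilated mask is forced to
#'   background).
#' @param net_cfg a [net_config].
#' @param cfg a [train_config].
#' @return List of `list(x, y)` pairs: `x` the input patch, `y` the
#'   integer target cube.
#' @export
sample_training_batch <- function(crops, net_cfg, cfg) {
  rf <- receptive_field(net_cfg)
  s_in <- rf + cfg$out_side - 1L
  lapply(seq_len(cfg$batch_size), function(i) {
    cr <- crops[[sample.int(length(crops), 1L)]]
    d <- dim(cr$image$data)
    fg <- cr$fg_idx
    if (is.null(fg)) fg <- which(cr$truth != 0)
    want_fg <- stats::runif(1) < 0.5 && length(fg) > 0
    lin <- if (want_fg) fg[sample.int(length(fg), 1L)]
           else {
             bg <- cr$bg_idx
             if (is.null(bg)) bg <- which(cr$truth == 0)
             bg[sample.int(length(bg), 1L)]
           }
    ctr <- arrayInd(lin, d)[1, ]
    list(x = extract_patch(cr$image$data, ctr, s_in),
         y = extract_patch(cr$truth, ctr, cfg$out_side),
         foreground_centered = want_fg)
  })
}

# dropout masks (inverted dropout) for one sample; NULL entries disable
.drop_masks <- function(net_cfg, out_dims_per_layer) {
  L <- net_cfg$n_hidden_layers
  masks <- vector("list", L)
  if (net_cfg$dropout_rate <= 0) return(masks)
  keep <- 1 - net_cfg$dropout_rate
  for (l in net_cfg$dropout_layers) {
    n <- out_dims_per_layer[[l]]
    masks[[l]] <- (stats::runif(n) < keep) / keep
  }
  masks
}

# per-layer activation lengths for a cubic input of side s_in
.act_lengths <- function(net_cfg, s_in) {
  k <- net_cfg$kernel[1]
  s <- s_in
  lapply(seq_len(net_cfg$n_hidden_layers), function(l) {
    s <<- s - (k - 1L)
    s^3 * net_cfg$feature_maps[l]
  })
}

#' Train the voxel-classification network
#'
#' Minimises voxel-wise cross-entropy plus `l1*||W||_1 + l2*||W||_2^2`
#' over class-balanced patches sampled from the training crops, halving
#' the learning rate whenever the validation Dice plateaus, and returns
#' the weights of the epoch with the best validation Dice. Gaussian-blur
#' augmentation (when enabled) adds one blurred copy of every training
#' crop per sigma before sampling. All randomness (shuffling, patch
#' sampling, dropout) flows from `cfg$seed`, so a rerun with the same
#' seed and data reproduces the training log bit-exactly.
#'
#' @param model an untrained model from [build_network] (its weights are
#'   the initialisation; `build_network` is called under `cfg$seed` if
#'   `model` is a bare [net_config]).
#' @param train_crops list of `list(crop, truth)` pairs or crops already
#'   carrying truth.
#' @param val_crops like `train_crops`; drives model selection.
#' @param cfg a [train_config].
#' @return A trained `hipposeg_model` with a populated `training_log`
#'   (epoch, train_loss, val_dice, lr).
#' @export
train_network <- function(model, train_crops, val_crops, cfg = train_config()) {
  if (length(train_crops) == 0 || length(val_crops) == 0)
    stop("training and validation sets must be non-empty")
  set.seed(cfg$seed)
  if (inherits(model, "net_config")) model <- build_network(model)
  net_cfg <- model$config

  prep <- function(x) {
    if (inherits(x, "roi_crop") && !is.null(x$truth)) x
    else training_crop(x$crop, x$truth)
  }
  tr <- lapply(train_crops, prep)
  va <- lapply(val_crops, prep)

  if (length(cfg$augment_sigmas)) {
    aug <- list()
    for (cr in tr) for (s in cfg$augment_sigmas) {
      cb <- cr
      cb$image <- augment_blur(cr$image, s)[[1]]
      aug <- c(aug, list(cb))
    }
    tr <- c(tr, aug)
  }
  # cache foreground/background indices once
  tr <- lapply(tr, function(cr) {
    cr$fg_idx <- which(cr$truth != 0)
    cr$bg_idx <- which(cr$truth == 0)
    cr
  })

  W <- model$weights$W; b <- model$weights$b
  vel_W <- lapply(W, function(w) w * 0); vel_b <- lapply(b, function(x) x * 0)
  mW <- vW <- lapply(W, function(w) w * 0)
  mb <- vb <- lapply(b, function(x) x * 0)
  adam_t <- 0

  kern <- .kern_vec(net_cfg)
  rf <- receptive_field(net_cfg)
  s_in <- rf + cfg$out_side - 1L
  act_len <- .act_lengths(net_cfg, s_in)
  n_batches <- max(1L, ceiling(length(tr) * cfg$patches_per_crop /
                                 cfg$batch_size))

  lr <- cfg$lr_init
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric(), lr = numeric())
  best <- list(dice = -Inf, W = W, b = b, epoch = NA_integer_)
  stall <- 0L

  val_dice <- function(W, b) {
    m <- model; m$weights <- list(W = W, b = b)
    ds <- vapply(va, function(cr) {
      p <- predict_roi(m, cr)
      seg <- array(as.integer(p > 0.5 & cr$dilated_mask != 0), dim(p))
      na <- sum(seg); nb <- sum(cr$truth)
      if (na + nb == 0) return(NA_real_)
      2 * sum(seg & cr$truth) / (na + nb)
    }, numeric(1))
    mean(ds, na.rm = TRUE)
  }

  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0
    for (bt in seq_len(n_batches)) {
      batch <- sample_training_batch(tr, net_cfg, cfg)
      gW <- lapply(W, function(w) w * 0); gb <- lapply(b, function(x) x * 0)
      bl <- 0
      for (sm in batch) {
        dm <- .drop_masks(net_cfg, act_len)
        res <- cpp_net_apply(as.double(sm$x), c(dim(sm$x), 1L), W, b, kern,
                             dm, as.integer(sm$y))
        if (!is.finite(res$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        bl <- bl + res$loss
        for (l in seq_along(W)) {
          gW[[l]] <- gW[[l]] + res$gW[[l]]
          gb[[l]] <- gb[[l]] + as.numeric(res$gb[[l]])
        }
      }
      nb <- length(batch)
      bl <- bl / nb
      for (l in seq_along(W)) {
        g <- gW[[l]] / nb + cfg$l1 * sign(W[[l]]) + 2 * cfg$l2 * W[[l]]
        gbv <- gb[[l]] / nb
        if (cfg$optimizer == "sgd") {
          vel_W[[l]] <- cfg$momentum * vel_W[[l]] - lr * g
          vel_b[[l]] <- cfg$momentum * vel_b[[l]] - lr * gbv
          W[[l]] <- W[[l]] + vel_W[[l]]
          b[[l]] <- b[[l]] + vel_b[[l]]
        } else {
          if (l == 1) adam_t <- adam_t + 1
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gbv
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gbv^2
          mhW <- mW[[l]] / (1 - b1^adam_t); vhW <- vW[[l]] / (1 - b2^adam_t)
          mhb <- mb[[l]] / (1 - b1^adam_t); vhb <- vb[[l]] / (1 - b2^adam_t)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / n_batches
    vd <- val_dice(W, b)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                 val_dice = vd, lr = lr))
    if (!is.finite(vd)) {
      # validation Dice undefined (e.g. empty truth and empty prediction):
      # keep the latest weights and leave the learning rate alone
      best <- list(dice = best$dice, W = W, b = b, epoch = ep)
    } else if (vd > best$dice + cfg$lr_min_delta) {
      best <- list(dice = vd, W = W, b = b, epoch = ep)
      stall <- 0L
    } else {
      if (vd > best$dice)
        best <- list(dice = vd, W = W, b = b, epoch = ep)
      stall <- stall + 1L
      if (stall >= cfg$lr_patience) {
        lr <- lr / 2
        stall <- 0L
      }
    }
  }

  model$weights <- list(W = best$W, b = best$b)
  model$n_train_crops <- length(tr)
  model$train_config <- cfg
  model$training_log <- log
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' @export
print.hipposeg_model <- function(x, ...) {
  cfg <- x$config
  cat("<hipposeg_model>", if (x$trained) "trained" else "untrained", "\n")
  cat(sprintf("  %d hidden 3^3 conv layers, feature maps: %s\n",
              cfg$n_hidden_layers, paste(cfg$feature_maps, collapse = ",")))
  cat(sprintf("  receptive field %d^3, %s parameters\n",
              receptive_field(cfg),
              format(n_parameters(cfg), big.mark = ",")))
  if (x$trained)
    cat(sprintf("  best validation Dice %.3f at epoch %d\n",
                max(x$training_log$val_dice, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.hipposeg_model <- function(object, ...) {
  print(object)
  if (!is.null(object$training_log)) {
    cat("training log:\n")
    print(object$training_log, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.hipposeg_model <- function(object, ...) object$weights

#' @export
plot.hipposeg_model <- function(x, ...) {
  if (is.null(x$training_log)) stop("model has no training log")
  lg <- x$training_log
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(lg$epoch, lg$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(lg$epoch, lg$val_dice, type = "b", xlab = "epoch",
       ylab = "validation Dice", main = "validation Dice", ...)
  invisible(x)
}

#' @export
predict.hipposeg_model <- function(object, newdata,
                                   type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- predict_roi(object, newdata)
  if (type == "prob") return(p)
  if (!inherits(newdata, "roi_crop"))
    stop("type = \"label\" needs an roi_crop (for its dilated mask)")
  finalize_segmentation(p, newdata)
}

#' Model checkpoints
#'
#' A checkpoint is a single RDS archive holding the architecture and
#' training configurations, the weights and the training log; the
#' training log is additionally exported as CSV next to it.
#'
#' @param model a `hipposeg_model`.
#' @param path output `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hipposeg_model"))
  saveRDS(model[c("config", "train_config", "weights", "training_log",
                  "best_epoch", "trained")], path)
  if (!is.null(model$training_log))
    write.csv(model$training_log,
              sub("\\.rds$", "_log.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  structure(obj, class = "hipposeg_model")
}
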