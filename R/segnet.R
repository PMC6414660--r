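#' Segmentation network configuration
#'
#' Architecture of the modified 3D U-net used for renal parenchyma
#' segmentation: five-level contraction and expansion paths built from
#' leaky-ReLU pre-activation residual blocks of 3x3x3 convolutions, 2x2x2
#' strided convolutions for down-sampling with element-wise sum junctions
#' forwarding feature maps between stages, 2x2x2 transposed convolutions
#' for up-sampling, symmetric copy-and-concatenate skip connections, 3D
#' spatial dropout (whole feature-map channels, rate 0.3), and an
#' element-wise sum of the last three expansion-path convolution outputs
#' (after 1x1x1 projection to one channel) immediately before the sigmoid.
#'
#' The three `use_*` flags reproduce the ablation arms of the architecture
#' study: each removes its structural element (and its parameters).
#' Channel widths double per level from `base_channels`.
#'
#' @param levels resolution levels per path (default 5; the input shape
#'   must be divisible by `2^(levels - 1)` along every axis).
#' @param base_channels channels at the finest level (default 32; the
#'   desk-scale configuration uses 8).
#' @param leaky_slope negative slope of the leaky ReLU (default 0.01).
#' @param spatial_dropout_rate 3D spatial dropout rate in `[0, 1)`.
#' @param use_residual_blocks,use_elementwise_sum,use_skip_connections
#'   ablation flags (all TRUE for the full network).
#' @param dice_eps smoothing constant of the soft-Dice loss (see
#'   [soft_dice_loss()]).
#' @return A `segnet_config` list.
#' @export
segnet_config <- function(levels = 5L, base_channels = 32L, leaky_slope = 0.01,
                          spatial_dropout_rate = 0.3,
                          use_residual_blocks = TRUE,
                          use_elementwise_sum = TRUE,
                          use_skip_connections = TRUE,
                          dice_eps = 1) {
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (spatial_dropout_rate < 0 || spatial_dropout_rate >= 1)
    stop("spatial_dropout_rate must be in [0, 1)", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope,
                 spatial_dropout_rate = spatial_dropout_rate,
                 use_residual_blocks = isTRUE(use_residual_blocks),
                 use_elementwise_sum = isTRUE(use_elementwise_sum),
                 use_skip_connections = isTRUE(use_skip_connections),
                 dice_eps = dice_eps),
            class = "segnet_config")
}

#' Desk-scale network configuration
#'
#' Three levels, 8 base channels: the configuration used for CPU-scale
#' training on 48^3 phantom windows. The spatial dropout rate is scaled
#' down to 0.15: dropping whole channels at the full-scale rate of 0.3
#' removes a third of an 8-channel feature map per layer, which
#' over-regularizes the narrow desk-scale network.
#' @param ... overrides passed to [segnet_config()].
#' @return A `segnet_config`.
#' @export
segnet_config_test <- function(...) {
  modifyList(segnet_config(levels = 3L, base_channels = 8L,
                           spatial_dropout_rate = 0.15), list(...))
}

#' Training schedule configuration
#'
#' ADAM with exponential decay rates 0.9 / 0.999 and epsilon zero, initial
#' learning rate 5e-4 halved when the training loss has not improved for
#' `plateau_patience_epochs` epochs, batch size 1 (spatial dropout in place
#' of batch normalization). The full-scale schedule is 80 epochs of 272
#' iterations.
#'
#' @param learning_rate initial learning rate.
#' @param adam_beta1,adam_beta2,adam_epsilon ADAM moment decay rates and
#'   epsilon (epsilon 0: updates with exactly zero second moment are
#'   skipped).
#' @param epochs,iterations_per_epoch schedule length.
#' @param plateau_patience_epochs epochs without improvement before the
#'   learning rate is halved.
#' @param lr_halving_factor multiplicative factor at a plateau (default 0.5).
#' @param plateau_tol relative loss decrease below which an epoch does not
#'   count as an improvement (default 1e-4).
#' @param batch_size fixed at 1.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 0,
                         epochs = 80L, iterations_per_epoch = 272L,
                         plateau_patience_epochs = 10L,
                         lr_halving_factor = 0.5, plateau_tol = 1e-4,
                         batch_size = 1L, seed = 1L) {
  if (plateau_patience_epochs < 1) stop("patience must be >= 1", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1 || lr_halving_factor <= 0 ||
      lr_halving_factor > 1)
    stop("rates must lie in (0, 1]", call. = FALSE)
  if (batch_size != 1L) stop("only batch_size = 1 is supported", call. = FALSE)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
                 epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 lr_halving_factor = lr_halving_factor,
                 plateau_tol = plateau_tol, batch_size = 1L,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) segmentation network
#'
#' Instantiates the network of [segnet_config()] with He-initialized
#' weights. Initialization consumes the R random number stream, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param cfg a [segnet_config()].
#' @return A `segmenter` object.
#' @export
build_segnet <- function(cfg = segnet_config()) {
  stopifnot(inherits(cfg, "segnet_config"))
  ptr <- unet_create(cfg$levels, cfg$base_channels, cfg$leaky_slope,
                     cfg$spatial_dropout_rate, cfg$use_residual_blocks,
                     cfg$use_elementwise_sum, cfg$use_skip_connections,
                     cfg$dice_eps)
  structure(list(ptr = ptr, config = cfg, train_config = NULL,
                 training_log = NULL), class = "segmenter")
}

#' @export
print.segmenter <- function(x, ...) {
  cat(sprintf("<segmenter> %d levels, base %d channels, %s params%s\n",
              x$config$levels, x$config$base_channels,
              format(n_params(x), big.mark = ","),
              if (is.null(x$training_log)) " (untrained)"
              else sprintf(", trained %d epochs (final loss %.4f)",
                           nrow(x$training_log),
                           x$training_log$mean_loss[nrow(x$training_log)])))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `segmenter`.
#' @return integer-valued scalar.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "segmenter"))
  unet_num_params(model$ptr)
}

#' Soft-Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' the relaxation of the Dice similarity coefficient used as the training
#' loss. `eps` (default 1, in voxel-count units) keeps the ratio defined
#' for empty masks and bounds the loss gradient.
#'
#' @param pred numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]` (up to eps-order effects).
#' @export
soft_dice_loss <- function(pred, target, eps = 1) {
  if (inherits(pred, "volume_grid")) pred <- pred$values
  if (inherits(target, "labeled_mask")) target <- target$grid$values
  if (inherits(target, "volume_grid")) target <- target$values
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ", call. = FALSE)
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Learning-rate trajectory of the plateau schedule
#'
#' Given a sequence of per-epoch losses, returns the learning rate in
#' force at each epoch under the reduce-on-plateau rule: if no epoch in
#' the last `patience` epochs improved on the best loss so far by a
#' relative `tol`, the rate is multiplied by `factor` (and the patience
#' window restarts).
#'
#' @param losses numeric vector of per-epoch losses.
#' @param initial_lr starting learning rate.
#' @param patience epochs without improvement before a reduction.
#' @param factor multiplicative reduction (default 0.5).
#' @param tol relative improvement threshold (default 1e-4).
#' @return numeric vector, the learning rate used at each epoch.
#' @export
lr_schedule_plateau <- function(losses, initial_lr, patience, factor = 0.5,
                                tol = 1e-4) {
  lr <- numeric(length(losses))
  cur <- initial_lr
  best <- Inf
  since <- 0L
  for (e in seq_along(losses)) {
    lr[e] <- cur
    if (losses[e] < best * (1 - tol) || !is.finite(best)) {
      best <- losses[e]
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        cur <- cur * factor
        since <- 0L
      }
    }
  }
  lr
}

# CT intensity normalization: clamp to a soft-tissue window and scale so
# parenchymal contrast is resolvable at the network input (the relevant
# HU differences on non-contrast CT are only a few units).
prepare_ct_input <- function(values, center = 40, lo = -100, hi = 200,
                             scale = 50) {
  v <- pmin(pmax(values, lo), hi)
  (v - center) / scale
}

as_window_array <- function(x) {
  if (inherits(x, "labeled_mask")) x <- x$grid
  if (inherits(x, "volume_grid")) x <- x$values
  x
}

#' Train the segmentation network
#'
#' Runs the soft-Dice / ADAM schedule of [train_config()] on paired
#' (CT window, parenchyma VOI window) volumes: per epoch,
#' `iterations_per_epoch` single-volume gradient steps over the reshuffled
#' cohort, learning rate halved on training-loss plateaus. Deterministic
#' given `tcfg$seed`.
#'
#' @param model a `segmenter` from [build_segnet()].
#' @param pairs list of `list(ct = , mask = )` pairs ([volume_grid()] /
#'   [labeled_mask()] or plain arrays), all of one shape divisible by
#'   `2^(levels-1)`.
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch loss lines.
#' @return The trained `segmenter` (training log in `$training_log`).
#' @export
train_segmenter <- function(model, pairs, tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "segmenter"), inherits(tcfg, "train_config"))
  if (length(pairs) < 1) stop("training cohort is empty", call. = FALSE)
  xs <- lapply(pairs, function(p) prepare_ct_input(as_window_array(p$ct)))
  ys <- lapply(pairs, function(p) as_window_array(p$mask))
  dm <- dim(xs[[1]])
  for (i in seq_along(xs))
    if (!identical(dim(xs[[i]]), dm) || !identical(dim(ys[[i]]), dm))
      stop("all training pairs must share one shape", call. = FALSE)
  set.seed(tcfg$seed)
  lr <- tcfg$learning_rate
  best <- Inf
  since <- 0L
  log <- vector("list", tcfg$epochs)
  order_pool <- integer(0)
  for (epoch in seq_len(tcfg$epochs)) {
    losses <- numeric(tcfg$iterations_per_epoch)
    for (it in seq_len(tcfg$iterations_per_epoch)) {
      if (length(order_pool) == 0) order_pool <- sample(length(xs))
      j <- order_pool[1]
      order_pool <- order_pool[-1]
      losses[it] <- unet_train_step(model$ptr, as.numeric(xs[[j]]),
                                    as.numeric(ys[[j]]), dm, lr,
                                    tcfg$adam_beta1, tcfg$adam_beta2,
                                    tcfg$adam_epsilon)
    }
    ml <- mean(losses)
    log[[epoch]] <- tibble::tibble(epoch = epoch, mean_loss = ml, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e", epoch, ml, lr))
    if (ml < best * (1 - tcfg$plateau_tol) || !is.finite(best)) {
      best <- ml
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= tcfg$plateau_patience_epochs) {
        lr <- lr * tcfg$lr_halving_factor
        since <- 0L
      }
    }
  }
  model$train_config <- tcfg
  model$training_log <- do.call(rbind, log)
  model
}

#' @method tidy segmenter
#' @export
tidy.segmenter <- function(x, ...) {
  if (is.null(x$training_log)) return(tibble::tibble(epoch = integer(),
                                                     mean_loss = numeric(),
                                                     lr = numeric()))
  x$training_log
}

#' @method glance segmenter
#' @export
glance.segmenter <- function(x, ...) {
  tibble::tibble(levels = x$config$levels,
                 base_channels = x$config$base_channels,
                 n_params = n_params(x),
                 epochs_trained = if (is.null(x$training_log)) 0L else nrow(x$training_log),
                 final_loss = if (is.null(x$training_log)) NA_real_
                              else x$training_log$mean_loss[nrow(x$training_log)])
}

#' Segment a CT window
#'
#' Forward pass, threshold at 0.5, retention of up to the two largest
#' connected components (at most two kidneys), laterality by component
#' centroid relative to the mid-sagittal plane. If the window carries
#' [crop_to_window()] metadata the mask is placed back on the uncropped
#' grid. An all-background prediction returns an empty mask with a warning
#' (single-kidney subjects can legitimately produce one or zero
#' components).
#'
#' @param model a trained `segmenter`.
#' @param ct_window a [volume_grid()] (HU) or array.
#' @param threshold probability cut (default 0.5, the sigmoid midpoint).
#' @return A [labeled_mask()]; the probability map is attached as the
#'   `"probability"` attribute (on the window grid).
#' @export
predict_mask <- function(model, ct_window, threshold = 0.5) {
  stopifnot(inherits(model, "segmenter"))
  is_grid <- inherits(ct_window, "volume_grid")
  vals <- as_window_array(ct_window)
  dm <- dim(vals)
  prob <- array(unet_forward(model$ptr, as.numeric(prepare_ct_input(vals)),
                             dm, FALSE), dim = dm)
  bin <- array(as.numeric(prob >= threshold), dim = dm)
  if (sum(bin) == 0) warning("all-background prediction: returning an empty mask")
  if (is_grid) {
    g <- volume_grid(bin, spacing_mm = ct_window$spacing_mm,
                     origin_mm = ct_window$origin_mm, units = "binary")
    ci <- attr(ct_window, "crop_info")
    if (!is.null(ci)) {
      g2 <- g
      attr(g2, "crop_info") <- ci
      g <- uncrop(g2)
    }
  } else {
    g <- volume_grid(bin, spacing_mm = c(1, 1, 1), units = "binary")
  }
  out <- labeled_mask(g, max_components = 2)
  attr(out, "probability") <- prob
  out
}

#' Random train/validation split
#'
#' Seed-reproducible disjoint, exhaustive split of cohort ids.
#'
#' @param ids vector of subject identifiers.
#' @param n_train number of training subjects, or a fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(ids, n_train, seed = 1L) {
  n <- length(ids)
  if (n_train > 0 && n_train < 1) n_train <- round(n_train * n)
  n_train <- as.integer(n_train)
  if (n_train > n) stop("n_train exceeds the cohort size", call. = FALSE)
  set.seed(as.integer(seed))
  tr <- sort(sample(n, n_train))
  list(train = ids[tr], validation = ids[setdiff(seq_len(n), tr)])
}

#' Save / load a trained segmenter
#'
#' Single-file checkpoint (R serialization, versioned schema) containing
#' the architecture, training configuration, weights and optimizer state;
#' reloading reproduces predictions bit-identically.
#'
#' @param model a `segmenter`.
#' @param path checkpoint file path.
#' @return `save_segmenter`: `path` invisibly; `load_segmenter`: the
#'   restored `segmenter`.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "segmenter"))
  saveRDS(list(schema = 1L, config = model$config,
               train_config = model$train_config,
               training_log = model$training_log,
               weights = unet_get_weights(model$ptr)),
          path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, 1L)) stop("unknown checkpoint schema", call. = FALSE)
  model <- build_segnet(ck$config)
  unet_set_weights(model$ptr, ck$weights)
  model$train_config <- ck$train_config
  model$training_log <- ck$training_log
  model
}
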