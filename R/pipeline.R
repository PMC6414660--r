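#' Extract the training window of a phantom
#'
#' Crops the phantom CT and ground-truth VOI to the fixed training window
#' about the grid center (the window is chosen large enough to include
#' both kidneys). The returned CT window carries [crop_to_window()]
#' metadata so predictions can be placed back on the uncropped grid.
#'
#' @param ph a `phantom_truth`.
#' @param window_shape integer triple (default the desk-scale 48^3
#'   window; the full-scale pipeline uses 192x128x96).
#' @return list with `ct` and `mask` window [volume_grid()]s.
#' @export
phantom_windows <- function(ph, window_shape = c(48L, 48L, 48L)) {
  stopifnot(inherits(ph, "phantom_truth"))
  list(ct = crop_to_window(ph$ct, window_shape, fill = -1000),
       mask = crop_to_window(ph$truth_mask$grid, window_shape, fill = 0))
}

#' Evaluate a trained segmenter on one phantom
#'
#' Segments the phantom's CT window, places the mask back on the CT grid,
#' and quantifies GFR with both the predicted and the ground-truth VOI
#' (each resampled to the SPECT grid).
#'
#' @param model a trained `segmenter`.
#' @param ph a `phantom_truth`.
#' @param window_shape training window shape.
#' @return tibble: one row per present kidney with `dice` (whole-mask,
#'   repeated per kidney row), `pid_reference`/`pid_test`,
#'   `gfr_reference`/`gfr_test`, `total_gfr_reference`/`total_gfr_test`
#'   and the kidney metadata.
#' @export
evaluate_phantom <- function(model, ph, window_shape = c(48L, 48L, 48L)) {
  w <- phantom_windows(ph, window_shape)
  pred <- suppressWarnings(predict_mask(model, w$ct))
  dice <- dice_coefficient(pred, ph$truth_mask)
  pred_spect <- labeled_mask(resample(pred$grid, ph$spect$spacing_mm,
                                      dim(ph$spect$values), mode = "mask"))
  q_ref <- suppressWarnings(quantify_subject(ph$spect, ph$truth_mask_spect,
                                             ph$subject))
  q_test <- suppressWarnings(quantify_subject(ph$spect, pred_spect, ph$subject))
  k <- ph$kidneys[ph$kidneys$present, , drop = FALSE]
  pick <- function(q, s, col) {
    i <- match(s, q$kidneys$side)
    ifelse(is.na(i), 0, q$kidneys[[col]][i])
  }
  k$dice <- dice
  k$pid_reference <- vapply(k$side, pick, numeric(1), q = q_ref, col = "pid")
  k$pid_test <- vapply(k$side, pick, numeric(1), q = q_test, col = "pid")
  k$gfr_reference <- vapply(k$side, pick, numeric(1), q = q_ref, col = "gfr")
  k$gfr_test <- vapply(k$side, pick, numeric(1), q = q_test, col = "gfr")
  k$total_gfr_reference <- q_ref$total_gfr
  k$total_gfr_test <- q_test$total_gfr
  k
}

#' Desk-scale end-to-end experiment
#'
#' Generates a synthetic cohort, trains the desk-scale network on the
#' training split's CT windows and ground-truth VOIs, segments the
#' held-out phantoms, quantifies GFR with predicted and ground-truth VOIs,
#' and summarizes segmentation and agreement performance. This is the
#' package's reference experiment: everything runs on one CPU in minutes.
#'
#' @param seed integer; drives phantom generation, the train/validation
#'   split, weight initialization, shuffling and dropout.
#' @param n_train,n_test cohort split sizes (defaults 20 and 5).
#' @param epochs,iterations_per_epoch training schedule. Each desk-scale
#'   epoch is one pass over the training cohort, so the default schedule is
#'   `epochs * n_train` single-volume gradient steps (60 x 20 = 1200).
#' @param window_shape training window (default 48^3).
#' @param net_cfg a [segnet_config()] (default [segnet_config_test()]).
#' @param phantom_cfg a [phantom_config()] (default
#'   [phantom_config_test()] with `seed`).
#' @param learning_rate initial ADAM learning rate.
#' @param verbose print per-epoch training losses.
#' @return list with `model`, `per_kidney` (evaluation tibble over the
#'   held-out phantoms), `dice_mean`, `agreement` (per-kidney GFR,
#'   reference vs automatic) and `split`.
#' @export
run_e2e <- function(seed = 7L, n_train = 20L, n_test = 5L, epochs = 60L,
                    iterations_per_epoch = NULL,
                    window_shape = c(48L, 48L, 48L),
                    net_cfg = segnet_config_test(),
                    phantom_cfg = NULL, learning_rate = 5e-4,
                    verbose = FALSE) {
  cfg <- phantom_cfg %||% phantom_config_test(seed = as.integer(seed))
  n <- n_train + n_test
  ids <- seq_len(n)
  split <- split_train_validation(ids, n_train, seed = seed)
  phantoms <- lapply(ids, function(i) generate_phantom(cfg, i))
  pairs <- lapply(phantoms[split$train], phantom_windows,
                  window_shape = window_shape)
  tcfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                       iterations_per_epoch = iterations_per_epoch %||% n_train,
                       seed = as.integer(seed))
  set.seed(as.integer(seed))
  model <- build_segnet(net_cfg)
  model <- train_segmenter(model, pairs, tcfg, verbose = verbose)
  per_kidney <- do.call(rbind, lapply(phantoms[split$validation],
                                      function(ph) evaluate_phantom(model, ph,
                                                                    window_shape)))
  per_subject <- unique(per_kidney[, c("subject", "total_gfr_reference",
                                       "total_gfr_test")])
  ag <- agreement(per_kidney$gfr_reference, per_kidney$gfr_test,
                  labels = paste(per_kidney$subject, per_kidney$side))
  list(model = model, per_kidney = per_kidney, per_subject = per_subject,
       dice_mean = mean(per_kidney$dice[!duplicated(per_kidney$subject)]),
       agreement = ag, split = split)
}
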