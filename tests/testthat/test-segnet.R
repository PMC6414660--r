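test_that("soft-Dice loss matches its closed forms", {
  m <- array(0, c(6, 6, 6)); m[2:4, 2:4, 2:4] <- 1
  expect_equal(soft_dice_loss(m, m), 0, tolerance = 1e-12)
  expect_equal(soft_dice_loss(array(0, c(6, 6, 6)), m),
               1 - 1 / (sum(m) + 1), tolerance = 1e-12)
  half <- array(0, c(6, 6, 6)); half[, , 1:3] <- 1
  expect_equal(soft_dice_loss(array(0.5, c(6, 6, 6)), half, eps = 0), 0.5,
               tolerance = 1e-12)
  expect_error(soft_dice_loss(array(0.5, c(4, 4, 4)), m), "differ")
})

test_that("network builds, preserves shape, and bounds its output", {
  set.seed(1)
  net <- build_segnet(segnet_config(levels = 2, base_channels = 2))
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  p <- array(renoquant:::unet_forward(net$ptr, as.numeric(x), dim(x), FALSE),
             dim = dim(x))
  expect_identical(dim(p), dim(x))
  expect_true(all(p > 0 & p < 1))
  expect_error(renoquant:::unet_forward(net$ptr, as.numeric(x[, , 1:7]),
                                        c(8L, 8L, 7L), FALSE), "divisible")
})

test_that("ablation flags strictly reduce the parameter count", {
  set.seed(2)
  full <- build_segnet(segnet_config(levels = 3, base_channels = 4))
  no_res <- build_segnet(segnet_config(levels = 3, base_channels = 4,
                                       use_residual_blocks = FALSE))
  no_sum <- build_segnet(segnet_config(levels = 3, base_channels = 4,
                                       use_elementwise_sum = FALSE))
  no_skip <- build_segnet(segnet_config(levels = 3, base_channels = 4,
                                        use_skip_connections = FALSE))
  expect_lt(n_params(no_res), n_params(full))
  expect_lt(n_params(no_sum), n_params(full))
  expect_lt(n_params(no_skip), n_params(full))
})

test_that("backpropagation matches finite differences along the gradient", {
  set.seed(3)
  net <- build_segnet(segnet_config(levels = 2, base_channels = 2,
                                    spatial_dropout_rate = 0))
  dm <- c(4L, 4L, 4L)
  x <- rnorm(prod(dm))
  y <- as.numeric(runif(prod(dm)) < 0.3)
  lg <- renoquant:::unet_loss_grads(net$ptr, x, y, dm)
  w <- renoquant:::unet_get_weights(net$ptr)
  nms <- grep("^(W|b)_", names(w), value = TRUE)
  gn <- sqrt(sum(unlist(lg$grads[nms])^2))
  dir <- lapply(lg$grads[nms], function(g) g / gn)
  h <- 0.005
  wp <- w; wm <- w
  for (nm in nms) {
    wp[[nm]] <- wp[[nm]] + h * dir[[nm]]
    wm[[nm]] <- wm[[nm]] - h * dir[[nm]]
  }
  renoquant:::unet_set_weights(net$ptr, wp)
  lp <- renoquant:::unet_eval_loss(net$ptr, x, y, dm)
  renoquant:::unet_set_weights(net$ptr, wm)
  lmn <- renoquant:::unet_eval_loss(net$ptr, x, y, dm)
  fd <- (lp - lmn) / (2 * h)
  expect_equal(fd, gn, tolerance = 0.01)
})

test_that("one ADAM step on a fixed batch decreases the loss", {
  set.seed(4)
  net <- build_segnet(segnet_config(levels = 2, base_channels = 4,
                                    spatial_dropout_rate = 0))
  dm <- c(8L, 8L, 8L)
  x <- rnorm(prod(dm))
  y <- array(0, dm); y[3:6, 3:6, 3:6] <- 1
  y <- as.numeric(y)
  l0 <- renoquant:::unet_eval_loss(net$ptr, x, y, dm)
  renoquant:::unet_train_step(net$ptr, x, y, dm, 1e-3, 0.9, 0.999, 0)
  l1 <- renoquant:::unet_eval_loss(net$ptr, x, y, dm)
  expect_lt(l1, l0)
})

test_that("the plateau schedule halves the rate every patience interval", {
  lr <- lr_schedule_plateau(rep(1, 30), initial_lr = 4e-4, patience = 10)
  expect_equal(lr[1:11], rep(4e-4, 11))
  expect_equal(lr[12:21], rep(2e-4, 10))
  expect_equal(lr[22:30], rep(1e-4, 9))
  # improving losses never trigger a reduction
  lr2 <- lr_schedule_plateau(seq(1, 0.5, length.out = 25), 4e-4, patience = 10)
  expect_equal(lr2, rep(4e-4, 25))
})

test_that("train/validation splits are disjoint, exhaustive, reproducible", {
  ids <- sprintf("P%03d", 1:393)
  sp <- split_train_validation(ids, 315, seed = 5)
  expect_length(sp$train, 315)
  expect_length(sp$validation, 78)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, split_train_validation(ids, 315, seed = 5))
  sp2 <- split_train_validation(1:10, 8, seed = 1)
  expect_length(sp2$train, 8)
  expect_length(sp2$validation, 2)
  expect_error(split_train_validation(1:5, 8, seed = 1), "exceeds")
})

test_that("short training reduces the loss and logs the schedule", {
  ph <- cached_phantom()
  w <- phantom_windows(ph, c(32L, 32L, 32L))
  set.seed(6)
  model <- build_segnet(segnet_config_test())
  model <- train_segmenter(model, list(w),
                           train_config(epochs = 3, iterations_per_epoch = 8,
                                        seed = 6))
  log <- tidy(model)
  expect_equal(nrow(log), 3)
  expect_lt(log$mean_loss[3], log$mean_loss[1])
  expect_true(all(c("epoch", "mean_loss", "lr") %in% names(log)))
  expect_gt(glance(model)$n_params, 0)
  expect_error(train_segmenter(model, list(), train_config()), "empty")
})

test_that("checkpoints restore bit-identical predictions", {
  ph <- cached_phantom()
  w <- phantom_windows(ph, c(32L, 32L, 32L))
  set.seed(8)
  model <- build_segnet(segnet_config_test())
  model <- train_segmenter(model, list(w),
                           train_config(epochs = 1, iterations_per_epoch = 4,
                                        seed = 8))
  f <- tempfile(fileext = ".ckpt")
  save_segmenter(model, f)
  model2 <- load_segmenter(f)
  x <- as.numeric(renoquant:::prepare_ct_input(w$ct$values))
  dm <- dim(w$ct$values)
  p1 <- renoquant:::unet_forward(model$ptr, x, dm, FALSE)
  p2 <- renoquant:::unet_forward(model2$ptr, x, dm, FALSE)
  expect_identical(p1, p2)
})

test_that("predict_mask thresholds, keeps two components, maps back", {
  ph <- cached_phantom()
  w <- phantom_windows(ph)
  set.seed(9)
  model <- build_segnet(segnet_config_test())
  pred <- suppressWarnings(predict_mask(model, w$ct))
  # placed back on the full uncropped CT grid
  expect_identical(dim(pred$grid$values), dim(ph$ct$values))
  expect_lte(length(pred$sides), 2)
  prob <- attr(pred, "probability")
  expect_identical(dim(prob), dim(w$ct$values))
  # single precision can saturate the sigmoid at exactly 0 or 1
  expect_true(all(prob >= 0 & prob <= 1))
})
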