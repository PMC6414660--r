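test_that("Dice coefficient matches closed forms and the brute-force oracle", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1, 1] <- 1; a[1:2, 2, 1] <- 1
  b <- array(0, c(4, 4, 4)); b[1:2, 1, 1] <- 1; b[3:4, 4, 4] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, array(0, c(4, 4, 4))), 0)
  expect_equal(dice_coefficient(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
  # |A| = |B| = 4, |A intersect B| = 2
  expect_equal(dice_coefficient(a, b), 0.5)

  set.seed(42)
  for (i in 1:25) {
    x <- array(as.numeric(runif(512) < 0.3), c(8, 8, 8))
    y <- array(as.numeric(runif(512) < 0.3), c(8, 8, 8))
    expect_equal(dice_coefficient(x, y), dice_bruteforce(x, y), tolerance = 1e-12)
    expect_equal(dice_coefficient(x, y), dice_coefficient(y, x))
  }
  expect_error(dice_coefficient(a, array(0, c(4, 4, 5))), "differ")
})

test_that("soft-Dice loss agrees with the Dice coefficient on binary input", {
  set.seed(7)
  x <- array(as.numeric(runif(512) < 0.4), c(8, 8, 8))
  y <- array(as.numeric(runif(512) < 0.4), c(8, 8, 8))
  expect_equal(1 - soft_dice_loss(x, y, eps = 0), dice_coefficient(x, y),
               tolerance = 1e-12)
})

test_that("MAPE: closed forms, scale invariance, contract", {
  expect_equal(mape(c(50, 60), c(50, 60))$mape_mean, 0)
  expect_equal(mape(50, 49)$mape_mean, 2)
  m1 <- mape(c(40, 55, 70), c(42, 50, 75))
  m2 <- mape(3.7 * c(40, 55, 70), 3.7 * c(42, 50, 75))
  expect_equal(m1$mape_mean, m2$mape_mean, tolerance = 1e-12)
  expect_equal(m1$mape_sd, m2$mape_sd, tolerance = 1e-12)
  expect_error(mape(c(50, 0), c(50, 50)), "positive")
  expect_error(mape(c(1, 2), c(1, 2, 3)), "equal-length")
})

test_that("agreement: degenerate exactness and affine shifts", {
  x <- c(40, 50, 60, 70, 80)
  a <- agreement(x, x)
  expect_equal(a$r_squared, 1, tolerance = 1e-12)
  expect_equal(a$bias, 0)
  expect_equal(a$loa_lower, 0)
  expect_equal(a$loa_upper, 0)
  expect_equal(a$mape_mean, 0)

  b <- agreement(x, x + 3)
  expect_equal(b$r_squared, 1, tolerance = 1e-12)
  expect_equal(b$bias, 3, tolerance = 1e-12)
  expect_equal(b$loa_lower, 3)
  expect_equal(b$loa_upper, 3)

  expect_error(agreement(c(1, 2), c(1, 2)), "n >= 3")
  g <- glance(b)
  expect_true(all(c("r_squared", "mape_mean", "bias", "loa_upper") %in% names(g)))
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(plot_bland_altman(b), "ggplot")
})

test_that("Bland-Altman limits recover the simulated noise level", {
  set.seed(123)
  sigma <- 4
  ref <- runif(3000, 40, 120)
  test <- ref + rnorm(3000, 0, sigma)
  a <- agreement(ref, test)
  half_width <- (a$loa_upper - a$loa_lower) / 2
  expect_equal(half_width, 1.96 * sigma, tolerance = 0.05)
  expect_lt(abs(a$bias), 0.3)
})

test_that("k-fold partitions obey the partition laws", {
  folds <- kfold_split(1:10, 5, seed = 3)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(duplicated(unlist(folds))), 0)
  expect_identical(folds, kfold_split(1:10, 5, seed = 3))
  # balanced within one for non-divisible sizes
  f11 <- kfold_split(1:11, 3, seed = 1)
  expect_lte(diff(range(lengths(f11))), 1)
  expect_error(kfold_split(1:3, 5, seed = 1), "k")
})

test_that("an oracle segmenter yields Dice 1 and MAPE 0 in every fold", {
  set.seed(5)
  truth <- tibble::tibble(id = 1:10, gfr = runif(10, 40, 90))
  rep <- kfold_harness(truth$id, 5, seed = 9,
    train_fn = function(train_ids) "oracle",
    eval_fn = function(model, test_ids) {
      tibble::tibble(dice = rep(1, length(test_ids)),
                     gfr_reference = truth$gfr[test_ids],
                     gfr_test = truth$gfr[test_ids])
    })
  expect_equal(nrow(rep$folds), 5)
  expect_true(all(rep$folds$dice_mean == 1))
  expect_true(all(rep$folds$mape_mean == 0))
  expect_length(rep$failed, 0)
  expect_equal(glance(rep)$dice_mean, 1)
})

test_that("a failing fold is recorded and the harness continues", {
  rep <- suppressWarnings(kfold_harness(1:8, 4, seed = 2,
    train_fn = function(train_ids) train_ids,
    eval_fn = function(model, test_ids) {
      if (1 %in% test_ids) stop("synthetic failure")
      tibble::tibble(dice = rep(0.9, length(test_ids)),
                     gfr_reference = c(50, 60), gfr_test = c(51, 59))
    }))
  expect_length(rep$failed, 1)
  expect_equal(nrow(rep$folds), 3)
})

test_that("kidney status classification implements the stone-size rule", {
  expect_equal(classify_kidney_status(TRUE, FALSE, 0), "normal")
  expect_equal(classify_kidney_status(FALSE, TRUE, 0), "symptomatic")
  expect_equal(classify_kidney_status(FALSE, FALSE, 12), "symptomatic")
  expect_equal(classify_kidney_status(FALSE, FALSE, 10), "asymptomatic")
  expect_equal(classify_kidney_status(FALSE, FALSE, 0), "asymptomatic")
})

test_that("group report orders constructed groups and delegates tests", {
  set.seed(21)
  n <- 40
  status <- rep(c("normal", "asymptomatic", "symptomatic"), length.out = n)
  base <- ifelse(status == "symptomatic", 48, 60) + rnorm(n, 0, 3)
  d <- tibble::tibble(status = status,
                      gfr_reference = base,
                      gfr_test = base + rnorm(n, 0, 1))
  rep <- group_report(d)
  g <- rep$groups
  for (m in c("gfr_reference", "gfr_test")) {
    expect_lt(g$mean[g$status == "symptomatic" & g$method == m],
              g$mean[g$status == "normal" & g$method == m])
  }
  expect_equal(sum(g$n[g$method == "gfr_reference"]), n)
  expect_true(all(rep$between_tests$anova_p < 0.05))
  expect_false(is.null(rep$paired_tests))

  # classification from metadata instead of a status column
  d2 <- tibble::tibble(donor = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       ureter_stone = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                       renal_stone_mm = c(0, 0, 0, 0, 14, 5),
                       gfr_reference = c(60, 62, 58, 45, 47, 59),
                       gfr_test = c(61, 61, 59, 44, 48, 60))
  rep2 <- group_report(d2)
  expect_setequal(unique(as.character(rep2$data$status)),
                  c("normal", "asymptomatic", "symptomatic"))

  # single-group cohort: between-group comparisons suppressed
  d3 <- tibble::tibble(status = rep("normal", 6),
                       gfr_reference = rnorm(6, 60, 2),
                       gfr_test = rnorm(6, 60, 2))
  rep3 <- group_report(d3)
  expect_null(rep3$between_tests)
  expect_error(group_report(d3[, c("gfr_reference", "gfr_test")]), "status")
})
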