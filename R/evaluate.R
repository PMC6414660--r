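#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two segmentations on one grid.
#' Two empty masks agree perfectly on absence and return 1.
#'
#' @param a,b [labeled_mask()]s, binary [volume_grid()]s or 0/1 arrays of
#'   one shape (grids must match when geometry is available).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  ga <- if (inherits(a, "labeled_mask")) a$grid else a
  gb <- if (inherits(b, "labeled_mask")) b$grid else b
  if (inherits(ga, "volume_grid") && inherits(gb, "volume_grid"))
    stopifnot_same_grid(ga, gb)
  va <- if (inherits(ga, "volume_grid")) ga$values else ga
  vb <- if (inherits(gb, "volume_grid")) gb$values else gb
  if (!identical(dim(va), dim(vb))) stop("mask shapes differ", call. = FALSE)
  na <- sum(va != 0)
  nb <- sum(vb != 0)
  if (na + nb == 0) return(1)
  2 * sum(va != 0 & vb != 0) / (na + nb)
}

#' Mean absolute percentage error
#'
#' Per-pair `100 * |test - reference| / reference`; returns the mean and
#' standard deviation. Invariant to a common positive rescaling of both
#' lists.
#'
#' @param reference,test equal-length numeric vectors; `reference` must be
#'   strictly positive.
#' @return tibble with `mape_mean` and `mape_sd` (percent).
#' @export
mape <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 1)
    stop("reference and test must be equal-length, non-empty", call. = FALSE)
  if (any(reference <= 0)) stop("reference values must be strictly positive",
                                call. = FALSE)
  ape <- 100 * abs(test - reference) / reference
  tibble::tibble(mape_mean = mean(ape),
                 mape_sd = if (length(ape) > 1) sd(ape) else 0)
}

#' Agreement statistics between two GFR measurements
#'
#' The method-comparison summary used to judge an automatic pipeline
#' against a manual reference: ordinary-least-squares R-squared of test on
#' reference, MAPE, and Bland-Altman bias with 1.96 SD limits of
#' agreement.
#'
#' @param reference,test paired numeric vectors, `n >= 3`.
#' @param labels optional subject labels for the per-subject table.
#' @return An `agreement_report`: per-method means/SDs, `r_squared`,
#'   `mape_mean`/`mape_sd`, `bias`, `loa_lower`, `loa_upper` and the
#'   per-subject `data` tibble.
#' @export
agreement <- function(reference, test, labels = NULL) {
  if (length(reference) != length(test)) stop("paired vectors required", call. = FALSE)
  n <- length(reference)
  if (n < 3) stop("agreement needs n >= 3 pairs", call. = FALSE)
  fit <- lm(test ~ reference)
  # summary.lm warns on an exactly perfect fit; identical inputs are legal here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  d <- test - reference
  bias <- mean(d)
  sdd <- sd(d)
  mp <- mape(reference, test)
  data <- tibble::tibble(subject = labels %||% seq_len(n),
                         reference = reference, test = test, diff = d,
                         mean = (reference + test) / 2,
                         ape = 100 * abs(d) / reference)
  structure(list(n = n,
                 reference_mean = mean(reference), reference_sd = sd(reference),
                 test_mean = mean(test), test_sd = sd(test),
                 r_squared = r2, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 mape_mean = mp$mape_mean, mape_sd = mp$mape_sd,
                 bias = bias, sd_diff = sdd,
                 loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
                 data = data),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  reference %.2f +/- %.2f; test %.2f +/- %.2f\n",
              x$reference_mean, x$reference_sd, x$test_mean, x$test_sd))
  cat(sprintf("  R^2 %.3f; MAPE %.2f +/- %.2f %%\n",
              x$r_squared, x$mape_mean, x$mape_sd))
  cat(sprintf("  Bland-Altman bias %.3f [%.3f, %.3f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$data

#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n = x$n, reference_mean = x$reference_mean,
                 reference_sd = x$reference_sd, test_mean = x$test_mean,
                 test_sd = x$test_sd, r_squared = x$r_squared,
                 mape_mean = x$mape_mean, mape_sd = x$mape_sd,
                 bias = x$bias, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper)
}

#' Scatter and Bland-Altman plots of an agreement report
#'
#' @param object an [agreement()] report.
#' @param type `"scatter"` (test vs reference with the identity and OLS
#'   lines) or `"bland_altman"` (difference vs mean with bias and limits).
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, type = c("scatter", "bland_altman"),
                                      ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "scatter") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$reference, y = .data$test)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "steelblue") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "reference GFR", y = "test GFR",
                    title = sprintf("R² = %.3f", object$r_squared)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
      ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                          linetype = 2, colour = "grey40") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "mean of methods", y = "test - reference",
                    title = sprintf("bias %.2f [%.2f, %.2f]", object$bias,
                                    object$loa_lower, object$loa_upper)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.agreement_report
#' @param report an [agreement()] report.
#' @export
plot_bland_altman <- function(report, ...) autoplot(report, type = "bland_altman", ...)

#' Seed-reproducible k-fold partition
#'
#' @param ids vector of subject ids.
#' @param k number of folds (>= 2, <= length(ids)).
#' @param seed integer seed.
#' @return list of `k` disjoint, exhaustive id vectors with sizes balanced
#'   within one.
#' @export
kfold_split <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (k < 2 || k > n) stop("need 2 <= k <= number of ids", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) ids[fold == f])
}

#' k-fold cross-validation harness
#'
#' Partitions the cohort into `k` seed-reproducible folds; per fold, calls
#' `train_fn(train_ids)` to obtain a model and `eval_fn(model, test_ids)`
#' for a per-kidney tibble with columns `dice`, `gfr_reference`,
#' `gfr_test` (and anything else), then aggregates a per-fold Dice summary
#' and [agreement()] report. A failing fold is recorded and skipped; the
#' harness continues and flags the failure in the result.
#'
#' @param ids cohort subject ids.
#' @param k number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param train_fn function(train_ids) -> model.
#' @param eval_fn function(model, test_ids) -> tibble with `dice`,
#'   `gfr_reference`, `gfr_test`.
#' @return A `kfold_report`: `folds` (per-fold tibble with mean dice, R2,
#'   MAPE), `details` (row-bound eval tibbles with a `fold` column),
#'   `failed` (integer vector of failed folds).
#' @export
kfold_harness <- function(ids, k, seed, train_fn, eval_fn) {
  folds <- kfold_split(ids, k, seed)
  per_fold <- vector("list", k)
  details <- vector("list", k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    res <- tryCatch({
      model <- train_fn(train_ids)
      ev <- eval_fn(model, test_ids)
      ev$fold <- f
      mp <- mape(ev$gfr_reference, ev$gfr_test)
      # R-squared needs >= 3 pairs; small folds report the other metrics
      r2 <- if (nrow(ev) >= 3)
        agreement(ev$gfr_reference, ev$gfr_test)$r_squared else NA_real_
      list(ev = ev,
           row = tibble::tibble(fold = f, n = nrow(ev),
                                dice_mean = mean(ev$dice),
                                dice_sd = if (nrow(ev) > 1) sd(ev$dice) else 0,
                                r_squared = r2,
                                mape_mean = mp$mape_mean,
                                mape_sd = mp$mape_sd,
                                bias = mean(ev$gfr_test - ev$gfr_reference)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("fold %d failed: %s", f, conditionMessage(res)))
      failed <- c(failed, f)
    } else {
      per_fold[[f]] <- res$row
      details[[f]] <- res$ev
    }
  }
  structure(list(folds = do.call(rbind, per_fold),
                 details = do.call(rbind, details),
                 assignments = folds, failed = failed),
            class = "kfold_report")
}

#' @export
print.kfold_report <- function(x, ...) {
  cat(sprintf("<kfold_report> %d folds%s\n",
              length(x$assignments),
              if (length(x$failed)) paste0(" (failed: ",
                                           paste(x$failed, collapse = ","), ")")
              else ""))
  print(x$folds)
  invisible(x)
}

#' @method tidy kfold_report
#' @export
tidy.kfold_report <- function(x, ...) x$folds

#' @method glance kfold_report
#' @export
glance.kfold_report <- function(x, ...) {
  tibble::tibble(k = length(x$assignments), n_failed = length(x$failed),
                 dice_mean = mean(x$folds$dice_mean),
                 r_squared_mean = mean(x$folds$r_squared),
                 mape_mean = mean(x$folds$mape_mean))
}

#' Kidney status classification
#'
#' The clinical grouping rule: donors' kidneys are `normal`; a kidney with
#' a ureter stone of any size or a renal stone with longest diameter
#' > 10 mm is `symptomatic`; a kidney with a small renal stone (<= 10 mm)
#' or the stone-free contralateral kidney of a urolithiasis patient is
#' `asymptomatic`.
#'
#' @param donor logical, kidney belongs to a kidney donor.
#' @param ureter_stone logical, ureter stone present (any size).
#' @param renal_stone_mm longest renal stone diameter in mm (0 = none).
#' @return character vector in `{normal, asymptomatic, symptomatic}`.
#' @export
classify_kidney_status <- function(donor, ureter_stone, renal_stone_mm) {
  n <- max(length(donor), length(ureter_stone), length(renal_stone_mm))
  donor <- rep_len(donor, n)
  ureter_stone <- rep_len(ureter_stone, n)
  renal_stone_mm <- rep_len(renal_stone_mm, n)
  ifelse(donor, "normal",
         ifelse(ureter_stone | renal_stone_mm > 10, "symptomatic",
                "asymptomatic"))
}

#' Per-status-group GFR report
#'
#' Classifies every kidney with [classify_kidney_status()] (unless a
#' `status` column is already present), summarizes individual GFR per
#' group and method, and attaches delegated hypothesis tests (paired
#' within-group method comparisons; between-group ANOVA and
#' Kruskal-Wallis per method). The p-values are reported, not asserted.
#'
#' @param results tibble with one row per kidney: GFR columns named in
#'   `methods`, plus either a `status` column or `donor`, `ureter_stone`,
#'   `renal_stone_mm` metadata.
#' @param methods character vector naming the GFR columns to summarize
#'   (default `c("gfr_reference", "gfr_test")`).
#' @return A `group_report`: `groups` (per group x method n/mean/sd
#'   tibble), `paired_tests`, `between_tests` (NULL when fewer than two
#'   groups are present), and the augmented `data`.
#' @export
group_report <- function(results, methods = c("gfr_reference", "gfr_test")) {
  stopifnot(is.data.frame(results))
  if (!all(methods %in% names(results)))
    stop("missing GFR columns: ", paste(setdiff(methods, names(results)),
                                        collapse = ", "), call. = FALSE)
  if (!"status" %in% names(results)) {
    need <- c("donor", "ureter_stone", "renal_stone_mm")
    if (!all(need %in% names(results)))
      stop("need a `status` column or ", paste(need, collapse = ", "),
           call. = FALSE)
    results$status <- classify_kidney_status(results$donor,
                                             results$ureter_stone,
                                             results$renal_stone_mm)
  }
  if (any(is.na(results$status))) stop("unlabeled kidney in results", call. = FALSE)
  results$status <- factor(results$status,
                           levels = c("normal", "asymptomatic", "symptomatic"))
  results$status <- droplevels(results$status)
  groups <- do.call(rbind, lapply(levels(results$status), function(g) {
    sub <- results[results$status == g, , drop = FALSE]
    do.call(rbind, lapply(methods, function(m) {
      tibble::tibble(status = g, method = m, n = nrow(sub),
                     mean = mean(sub[[m]]),
                     sd = if (nrow(sub) > 1) sd(sub[[m]]) else 0)
    }))
  }))
  paired <- NULL
  if (length(methods) == 2) {
    paired <- do.call(rbind, lapply(levels(results$status), function(g) {
      sub <- results[results$status == g, , drop = FALSE]
      if (nrow(sub) < 3) return(NULL)
      tt <- t.test(sub[[methods[1]]], sub[[methods[2]]], paired = TRUE)
      wt <- suppressWarnings(wilcox.test(sub[[methods[1]]], sub[[methods[2]]],
                                         paired = TRUE, exact = FALSE))
      tibble::tibble(status = g, paired_t_p = tt$p.value,
                     wilcoxon_p = wt$p.value)
    }))
  }
  between <- NULL
  if (nlevels(results$status) >= 2) {
    between <- do.call(rbind, lapply(methods, function(m) {
      fml <- stats::as.formula(paste(m, "~ status"))
      av <- summary(aov(fml, data = results))[[1]]
      kw <- kruskal.test(fml, data = results)
      tibble::tibble(method = m, anova_p = av[["Pr(>F)"]][1],
                     kruskal_p = kw$p.value)
    }))
  }
  structure(list(groups = groups, paired_tests = paired,
                 between_tests = between, data = tibble::as_tibble(results)),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>\n")
  print(x$groups)
  if (!is.null(x$between_tests)) {
    cat("between-group tests:\n")
    print(x$between_tests)
  } else cat("single group: between-group comparisons suppressed\n")
  invisible(x)
}

#' @method tidy group_report
#' @export
tidy.group_report <- function(x, ...) x$groups

#' @method glance group_report
#' @export
glance.group_report <- function(x, ...) {
  tibble::tibble(n_kidneys = nrow(x$data),
                 n_groups = length(unique(x$groups$status)))
}

#' @importFrom rlang .data
NULL
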