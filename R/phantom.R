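#' Digital kidney phantom configuration
#'
#' Parameters of the synthetic SPECT/CT cohort generator. Defaults
#' reproduce the acquisition geometry of a hybrid kidney SPECT/CT study
#' (CT 512x512x161 at 0.977x0.977x2.5 mm, quantitative SPECT 128^3 at
#' 3.452 mm isotropic, 370 MBq injected) with two bean-shaped parenchyma
#' compartments, a non-parenchymal renal pelvis, optional cysts / stones /
#' tumors excluded from the ground-truth VOI, retained iodine contrast in
#' the pelvis in 22.6% of subjects, and occasional single-kidney subjects.
#'
#' @param ct_shape,ct_spacing_mm CT grid (integer triple; mm triple).
#' @param spect_shape,spect_spacing_mm quantitative SPECT grid.
#' @param kidney_semiaxes_mm list with `x`, `y`, `z` ranges (mm) for the
#'   kidney ellipsoid semi-axes (x medial-lateral, y antero-posterior,
#'   z cranio-caudal).
#' @param kidney_offset_mm range of lateral distance of each kidney center
#'   from the mid-sagittal plane (mm).
#' @param pelvis_scale linear scale of the intrarenal pelvis compartment
#'   relative to the kidney semi-axes (controls the pelvis volume fraction).
#' @param contrast_prob probability that residual iodine contrast fills the
#'   renal pelvis (HU >= 150); default 0.226.
#' @param single_kidney_prob probability of a single-kidney subject.
#' @param donor_prob probability that a subject is a healthy kidney donor
#'   (both kidneys "normal", no stones); other subjects are urolithiasis
#'   patients.
#' @param symptomatic_prob among stone patients, probability that one
#'   kidney is symptomatic (ureter stone or renal stone > 10 mm); otherwise
#'   both kidneys carry small (<= 10 mm) renal stones.
#' @param cyst_count_range,cyst_diameter_mm cyst count range and diameter
#'   range (mm); cysts are hypodense and excluded from the parenchyma VOI.
#' @param tumor_prob,tumor_diameter_mm probability and diameter range of a
#'   parenchyma-isodense tumor, also excluded from the VOI.
#' @param pid_range_normal,pid_range_symptomatic uniform sampling ranges of
#'   the true per-kidney percent injected dose; the symptomatic range is
#'   lowered, encoding the functional deficit of obstructed kidneys.
#' @param injected_mbq nominal injected activity (MBq).
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM applied to the SPECT
#'   activity map (reconstructed-resolution surrogate).
#' @param spect_noise_scale multiplier on the expected voxel counts before
#'   Poisson sampling; `0` disables count noise.
#' @param ct_noise_sd HU noise standard deviations per compartment (named:
#'   body, parenchyma, pelvis, cyst, tumor, stone, contrast, air).
#' @param acquisition_minutes SPECT acquisition duration (min).
#' @param seed integer; fixes the whole generated cohort.
#' @return A `phantom_config` list.
#' @seealso [phantom_config_test()] for the scaled-down grid used in tests
#'   and desk-scale demonstrations.
#' @export
phantom_config <- function(ct_shape = c(512L, 512L, 161L),
                           ct_spacing_mm = c(0.977, 0.977, 2.5),
                           spect_shape = c(128L, 128L, 128L),
                           spect_spacing_mm = c(3.452, 3.452, 3.452),
                           kidney_semiaxes_mm = list(x = c(20, 28), y = c(22, 30), z = c(42, 55)),
                           kidney_offset_mm = c(38, 52),
                           pelvis_scale = 0.45,
                           contrast_prob = 0.226,
                           single_kidney_prob = 0.01,
                           donor_prob = 0.28,
                           symptomatic_prob = 0.5,
                           cyst_count_range = c(0L, 2L),
                           cyst_diameter_mm = c(8, 22),
                           tumor_prob = 0.1,
                           tumor_diameter_mm = c(15, 35),
                           pid_range_normal = c(3.5, 4.5),
                           pid_range_symptomatic = c(2.2, 3.2),
                           injected_mbq = 370,
                           psf_fwhm_mm = 12,
                           spect_noise_scale = 1,
                           ct_noise_sd = c(body = 10, parenchyma = 5, pelvis = 5,
                                           cyst = 5, tumor = 5, stone = 50,
                                           contrast = 30, air = 20),
                           acquisition_minutes = 1,
                           seed = 1L) {
  cfg <- list(ct_shape = as.integer(ct_shape), ct_spacing_mm = ct_spacing_mm,
              spect_shape = as.integer(spect_shape), spect_spacing_mm = spect_spacing_mm,
              kidney_semiaxes_mm = kidney_semiaxes_mm,
              kidney_offset_mm = kidney_offset_mm, pelvis_scale = pelvis_scale,
              contrast_prob = contrast_prob, single_kidney_prob = single_kidney_prob,
              donor_prob = donor_prob, symptomatic_prob = symptomatic_prob,
              cyst_count_range = as.integer(cyst_count_range),
              cyst_diameter_mm = cyst_diameter_mm, tumor_prob = tumor_prob,
              tumor_diameter_mm = tumor_diameter_mm,
              pid_range_normal = pid_range_normal,
              pid_range_symptomatic = pid_range_symptomatic,
              injected_mbq = injected_mbq, psf_fwhm_mm = psf_fwhm_mm,
              spect_noise_scale = spect_noise_scale, ct_noise_sd = ct_noise_sd,
              acquisition_minutes = acquisition_minutes, seed = as.integer(seed))
  probs <- c(cfg$contrast_prob, cfg$single_kidney_prob, cfg$donor_prob,
             cfg$symptomatic_prob, cfg$tumor_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(cfg$kidney_semiaxes_mm) <= 0) || any(cfg$kidney_offset_mm <= 0))
    stop("geometric ranges must be positive", call. = FALSE)
  fov <- cfg$ct_shape * cfg$ct_spacing_mm
  need <- c(2 * (max(cfg$kidney_offset_mm) + max(cfg$kidney_semiaxes_mm$x)),
            2 * max(cfg$kidney_semiaxes_mm$y) + 30,
            2 * max(cfg$kidney_semiaxes_mm$z))
  if (any(need > fov))
    stop("kidney geometry does not fit the CT field of view (",
         paste(round(fov), collapse = "x"), " mm)", call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

#' Desk-scale phantom configuration
#'
#' Same generative model as [phantom_config()] on a small grid: CT
#' 64x64x48 at 3.452 mm isotropic, SPECT 48^3 at (4.6, 4.6, 3.452) mm.
#' Kidney anatomy, %ID ranges and noise are unchanged; only the sampling
#' grids shrink, so training and cross-validation fit on a single CPU.
#'
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_test <- function(...) {
  phantom_config(ct_shape = c(64L, 64L, 48L),
                 ct_spacing_mm = c(3.452, 3.452, 3.452),
                 spect_shape = c(48L, 48L, 48L),
                 spect_spacing_mm = c(4.6, 4.6, 3.452),
                 ...)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# world-coordinate arrays of a grid (each a vector per axis)
axis_coords <- function(shape, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
}

# mask of an axis-aligned-in-y ellipsoid, tilted by `tilt` radians in the
# x-z plane, evaluated over the grid
ellipsoid_mask <- function(co, center, semi, tilt = 0) {
  nx <- length(co[[1]]); ny <- length(co[[2]]); nz <- length(co[[3]])
  dx <- co[[1]] - center[1]
  dy <- co[[2]] - center[2]
  dz <- co[[3]] - center[3]
  ct <- cos(tilt); st <- sin(tilt)
  # rotate (dx, dz) into the ellipsoid frame
  X <- array(0, dim = c(nx, ny, nz))
  dxm <- matrix(dx, nx, nz)
  dzm <- matrix(dz, nx, nz, byrow = TRUE)
  u <- (dxm * ct - dzm * st) / semi[1]
  w <- (dxm * st + dzm * ct) / semi[3]
  base <- u^2 + w^2   # nx x nz
  for (iy in seq_len(ny)) {
    X[, iy, ] <- base + (dy[iy] / semi[2])^2
  }
  X <= 1
}

sample_kidney <- function(cfg, sign) {
  sa <- cfg$kidney_semiaxes_mm
  semi <- c(runif1(sa$x), runif1(sa$y), runif1(sa$z))
  center <- c(sign * runif1(cfg$kidney_offset_mm),
              stats::rnorm(1, 12, 4),
              stats::rnorm(1, 0, 6))
  tilt <- sign * stats::runif(1, 5, 18) * pi / 180
  pelvis_center <- center + c(-sign * 0.5 * semi[1], 0, 0)
  pelvis_semi <- cfg$pelvis_scale * c(semi[1], 0.8 * semi[2], 0.55 * semi[3])
  list(center = center, semi = semi, tilt = tilt,
       pelvis_center = pelvis_center, pelvis_semi = pelvis_semi)
}

#' Generate one synthetic SPECT/CT subject
#'
#' Draws a subject-specific anatomy (two bean-shaped kidneys, or one for
#' single-kidney subjects), paints a CT-like HU volume with weak
#' parenchyma/soft-tissue contrast plus lesions, and builds a quantitative
#' SPECT-like activity volume with uniform parenchymal uptake scaled to a
#' sampled ground-truth per-kidney percent injected dose (%ID), PSF blur
#' and Poisson count noise. The ground-truth parenchyma VOI excludes the
#' renal pelvis, cysts, stones and tumors by construction.
#'
#' The SPECT activity is normalized per kidney **after** PSF blurring so
#' that integrating the blurred (noise-free) activity over that kidney's
#' ground-truth VOI on the SPECT grid returns exactly the sampled true %ID;
#' count noise then perturbs this bookkeeping at the percent level.
#'
#' Deterministic given `(cfg$seed, subject_index)`.
#'
#' @param cfg a [phantom_config()].
#' @param subject_index positive integer; subjects are independent.
#' @return A `phantom_truth` list: `ct`, `spect` ([volume_grid()]s),
#'   `truth_mask` (CT grid, [labeled_mask()]), `truth_mask_spect` (the same
#'   VOI resampled to the SPECT grid), `true_pid` (named left/right),
#'   `subject` (one-row tibble), `kidneys` (per-kidney metadata tibble).
#' @export
generate_phantom <- function(cfg, subject_index = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed((cfg$seed * 7919L + 131L * as.integer(subject_index)) %% 2147483647L)

  shape <- cfg$ct_shape
  spacing <- cfg$ct_spacing_mm
  origin <- -(shape - 1) / 2 * spacing  # world origin: volume centered at 0
  co <- axis_coords(shape, spacing, origin)

  sides_present <- c("left", "right")
  single <- stats::runif(1) < cfg$single_kidney_prob
  if (single) sides_present <- sample(c("left", "right"), 1)

  donor <- stats::runif(1) < cfg$donor_prob
  status <- c(left = "normal", right = "normal")
  ureter <- c(left = FALSE, right = FALSE)
  stone_mm <- c(left = 0, right = 0)
  if (!donor) {
    if (stats::runif(1) < cfg$symptomatic_prob) {
      sym <- sample(sides_present, 1)
      status[sym] <- "symptomatic"
      if (stats::runif(1) < 0.5) {
        ureter[sym] <- TRUE
        stone_mm[sym] <- round(runif1(c(3, 9)), 1)
      } else {
        stone_mm[sym] <- round(runif1(c(11, 18)), 1)
      }
      status[setdiff(sides_present, sym)] <- "asymptomatic"
    } else {
      status[sides_present] <- "asymptomatic"
      for (s in sides_present) stone_mm[s] <- round(runif1(c(3, 9)), 1)
    }
  }
  contrast <- stats::runif(1) < cfg$contrast_prob

  # compartment label array: 0 air, 1 body, 2 parenchyma, 3 pelvis,
  # 4 cyst, 5 tumor, 6 stone, 7 contrast pelvis
  lab <- array(0L, dim = shape)
  fov <- shape * spacing
  body_semi <- c(0.44 * fov[1], 0.40 * fov[2], 10 * fov[3])
  body <- ellipsoid_mask(co, c(0, 0, 0), body_semi)
  lab[body] <- 1L

  kid <- list()
  side_sign <- c(left = -1, right = 1)
  for (s in sides_present) {
    kid[[s]] <- sample_kidney(cfg, side_sign[[s]])
  }

  parenchyma <- list(left = NULL, right = NULL)
  pid <- c(left = NA_real_, right = NA_real_)
  for (s in sides_present) {
    k <- kid[[s]]
    kmask <- ellipsoid_mask(co, k$center, k$semi, k$tilt)
    pmask <- kmask & ellipsoid_mask(co, k$pelvis_center, k$pelvis_semi, k$tilt)
    lab[kmask] <- 2L
    lab[pmask] <- if (contrast) 7L else 3L
    par <- kmask & !pmask

    # lesions: drawn inside the kidney, excluded from the parenchyma VOI
    ncyst <- sample(seq(cfg$cyst_count_range[1], cfg$cyst_count_range[2]), 1)
    lesions <- list()
    if (ncyst > 0)
      for (i in seq_len(ncyst))
        lesions <- c(lesions, list(list(type = 4L, d = runif1(cfg$cyst_diameter_mm))))
    if (stats::runif(1) < cfg$tumor_prob)
      lesions <- c(lesions, list(list(type = 5L, d = runif1(cfg$tumor_diameter_mm))))
    if (!ureter[[s]] && stone_mm[[s]] > 0)
      lesions <- c(lesions, list(list(type = 6L, d = stone_mm[[s]])))
    for (le in lesions) {
      cand <- which(par, arr.ind = TRUE)
      if (nrow(cand) == 0) break
      at <- cand[sample(nrow(cand), 1), ]
      lcen <- origin + (at - 1) * spacing
      lmask <- ellipsoid_mask(co, lcen, rep(le$d / 2, 3)) & kmask
      lab[lmask] <- le$type
      par <- par & !lmask
    }
    if (ureter[[s]]) {
      # ureter stone: small calcification inferior-medial to the kidney
      ucen <- k$center + c(-side_sign[[s]] * 0.7 * k$semi[1], 5,
                           -(k$semi[3] + 12))
      umask <- ellipsoid_mask(co, ucen, rep(stone_mm[[s]] / 2, 3)) & body
      lab[umask] <- 6L
    }
    parenchyma[[s]] <- par
    rng <- if (status[[s]] == "symptomatic") cfg$pid_range_symptomatic else cfg$pid_range_normal
    pid[[s]] <- runif1(rng)
  }
  # re-assert exclusions (overlapping kidneys are not generated, but lesions
  # and pelvis always win over parenchyma)
  for (s in sides_present) parenchyma[[s]] <- parenchyma[[s]] & (lab == 2L)

  hu_mean <- c(`0` = -1000, `1` = 40, `2` = 35, `3` = 5, `4` = 10, `5` = 30,
               `6` = 400, `7` = 220)
  sdv <- cfg$ct_noise_sd
  hu_sd <- c(`0` = sdv[["air"]], `1` = sdv[["body"]], `2` = sdv[["parenchyma"]],
             `3` = sdv[["pelvis"]], `4` = sdv[["cyst"]], `5` = sdv[["tumor"]],
             `6` = sdv[["stone"]], `7` = sdv[["contrast"]])
  mean_field <- array(hu_mean[as.character(lab)], dim = shape)
  mean_field <- array(cpp_gauss_smooth3(mean_field, shape, rep(0.7, 3)), dim = shape)
  noise <- array(stats::rnorm(prod(shape)), dim = shape) * hu_sd[as.character(lab)]
  ct_vals <- mean_field + array(noise, dim = shape)
  ct_vals[lab == 6L] <- pmax(ct_vals[lab == 6L], 300)
  ct_vals[lab == 7L] <- pmax(ct_vals[lab == 7L], 150)
  ct_vals[lab == 0L] <- pmin(ct_vals[lab == 0L], -905)
  ct <- volume_grid(ct_vals, spacing_mm = spacing, origin_mm = origin, units = "HU")

  truth_vals <- array(0, dim = shape)
  for (s in sides_present) truth_vals[parenchyma[[s]]] <- 1
  truth_mask <- labeled_mask(volume_grid(truth_vals, spacing_mm = spacing,
                                         origin_mm = origin, units = "binary"))

  # SPECT: per-kidney uniform concentration, PSF blur, post-blur calibration
  sshape <- cfg$spect_shape
  sspacing <- cfg$spect_spacing_mm
  sorigin <- -(sshape - 1) / 2 * sspacing
  svox_ml <- prod(sspacing) / 1000
  sigma_vox <- (cfg$psf_fwhm_mm / 2.35482) / sspacing
  tg <- volume_grid(truth_vals, spacing_mm = spacing, origin_mm = origin,
                    units = "binary")
  truth_spect <- resample(tg, sspacing, sshape, mode = "mask")
  truth_mask_spect <- labeled_mask(truth_spect)
  spect_vals <- array(0, dim = sshape)
  for (s in sides_present) {
    ind <- volume_grid(array(as.numeric(parenchyma[[s]]), dim = shape),
                       spacing_mm = spacing, origin_mm = origin, units = "probability")
    frac <- resample(ind, sspacing, sshape)$values  # fractional occupancy
    if (cfg$psf_fwhm_mm > 0)
      frac <- array(cpp_gauss_smooth3(frac, sshape, sigma_vox), dim = sshape)
    smask <- side_mask(truth_mask_spect, s)
    tot <- sum(frac[smask]) * svox_ml
    target_mbq <- pid[[s]] / 100 * cfg$injected_mbq
    if (tot > 0) spect_vals <- spect_vals + frac * (target_mbq / tot) * 1e6  # Bq/ml
  }
  if (cfg$spect_noise_scale > 0) {
    # expected counts per voxel from the system sensitivity (152.5 cpm/uCi)
    cps <- spect_vals * svox_ml / 1e6 / 0.037 * 152.5 * cfg$acquisition_minutes *
      cfg$spect_noise_scale
    counts <- array(stats::rpois(length(cps), lambda = pmax(cps, 0)), dim = sshape)
    spect_vals <- counts / (svox_ml / 1e6 / 0.037 * 152.5 * cfg$acquisition_minutes *
                              cfg$spect_noise_scale)
  }
  spect <- volume_grid(spect_vals, spacing_mm = sspacing, origin_mm = sorigin,
                       units = "Bq_per_ml")

  sex <- sample(c("M", "F"), 1, prob = c(0.65, 0.35))
  weight <- round(stats::rnorm(1, if (sex == "M") 72 else 60, 10), 1)
  height <- round(stats::rnorm(1, if (sex == "M") 172 else 160, 7), 1)
  subject <- subject_record(id = sprintf("P%04d", subject_index),
                            weight_kg = max(weight, 40),
                            height_cm = max(height, 140),
                            injected_mbq = cfg$injected_mbq,
                            sex = sex, age = round(runif1(c(25, 75))))
  kidneys <- tibble::tibble(
    subject = subject$id,
    side = c("left", "right"),
    present = c("left", "right") %in% sides_present,
    status = unname(status),
    donor = donor,
    ureter_stone = unname(ureter),
    renal_stone_mm = unname(ifelse(ureter, 0, stone_mm)),
    true_pid = unname(pid)
  )
  structure(list(ct = ct, spect = spect, truth_mask = truth_mask,
                 truth_mask_spect = truth_mask_spect,
                 true_pid = pid, subject = subject, kidneys = kidneys,
                 contrast_pelvis = contrast, single_kidney = single,
                 config = cfg, subject_index = as.integer(subject_index)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> subject %s: %s; true %%ID L=%.2f R=%.2f%s\n",
              x$subject$id,
              paste(x$kidneys$status[x$kidneys$present], collapse = "/"),
              x$true_pid[["left"]], x$true_pid[["right"]],
              if (x$contrast_pelvis) "; contrast pelvis" else ""))
  invisible(x)
}

#' Emulate sparse-slice manual VOI drawing
#'
#' Reproduces how manual reference VOIs are drawn in practice: 2D ROIs on
#' every 2nd-3rd coronal slice (up to a slice budget per kidney), optionally
#' jittered in-plane, with the intervening slices reconstructed by
#' shape-based interpolation of per-slice signed distance fields, followed
#' by [smooth_mask()]. Because only the sampled slices honour lesion
#' exclusions, a stone or cyst confined to unsampled slices is wrongly
#' *included* in the emulated VOI while the ground truth excludes it -- the
#' characteristic failure mode of interpolated manual references.
#'
#' @param truth a `phantom_truth` from [generate_phantom()], or a
#'   [labeled_mask()].
#' @param slice_stride integer >= 1; draw every `slice_stride`-th coronal
#'   slice (2-3 emulates routine practice; 1 degenerates to the truth).
#' @param max_slices cap on drawn slices per kidney (default 30).
#' @param jitter_vox integer; each drawn ROI is shifted by a uniform
#'   in-plane offset in `[-jitter_vox, jitter_vox]` voxels (0 = exact ROIs).
#' @param smooth apply [smooth_mask()] to the result (default TRUE).
#' @return A [labeled_mask()] on the truth grid.
#' @export
emulate_manual_voi <- function(truth, slice_stride = 2L, max_slices = 30L,
                               jitter_vox = 1L, smooth = TRUE) {
  m <- if (inherits(truth, "phantom_truth")) truth$truth_mask else truth
  stopifnot(inherits(m, "labeled_mask"))
  if (slice_stride < 1) stop("slice_stride must be >= 1", call. = FALSE)
  if (sum(m$grid$values) == 0) stop("truth mask is empty", call. = FALSE)
  d <- dim(m$grid$values)
  out <- array(0, dim = d)
  for (ci in seq_along(m$sides)) {
    comp <- m$component_map == ci
    ys <- which(apply(comp, 2, any))
    drawn <- ys[seq(1, length(ys), by = slice_stride)]
    if (length(drawn) > max_slices) drawn <- drawn[seq_len(max_slices)]
    sdfs <- list()
    for (y in drawn) {
      sl <- comp[, y, ]
      if (jitter_vox > 0 && sum(sl) > 0) {
        sh <- sample(seq(-jitter_vox, jitter_vox), 2, replace = TRUE)
        sl2 <- array(FALSE, dim = dim(sl))
        xs <- seq_len(d[1]) - sh[1]; zs <- seq_len(d[3]) - sh[2]
        okx <- xs >= 1 & xs <= d[1]; okz <- zs >= 1 & zs <= d[3]
        sl2[okx, okz] <- sl[xs[okx], zs[okz]]
        sl <- sl2
      }
      sdfs[[as.character(y)]] <- matrix(cpp_sdf2(as.logical(sl), d[1], d[3]),
                                        d[1], d[3])
    }
    for (i in seq_along(drawn)) {
      y <- drawn[i]
      out[, y, ][sdfs[[as.character(y)]] <= 0] <- 1
      if (i < length(drawn)) {
        y2 <- drawn[i + 1]
        if (y2 > y + 1) {
          for (ym in (y + 1):(y2 - 1)) {
            w <- (ym - y) / (y2 - y)
            sdf <- (1 - w) * sdfs[[as.character(y)]] + w * sdfs[[as.character(y2)]]
            out[, ym, ][sdf <= 0] <- 1
          }
        }
      }
    }
  }
  res <- labeled_mask(volume_grid(out, spacing_mm = m$grid$spacing_mm,
                                  origin_mm = m$grid$origin_mm, units = "binary"))
  if (smooth) res <- smooth_mask(res)
  res
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` phantoms as NIfTI volumes (`ct_*.nii.gz`, `spect_*.nii.gz`,
#' `truth_*.nii.gz`) plus a tab-separated per-kidney manifest and a frozen
#' YAML copy of the configuration. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @param n number of subjects (>= 1).
#' @param out_dir output directory (created if missing).
#' @return The manifest as a tibble (one row per kidney), invisibly also
#'   written to `manifest.tsv`.
#' @export
generate_cohort <- function(cfg, n, out_dir) {
  stopifnot(inherits(cfg, "phantom_config"), n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(cfg, i)
    ctf <- file.path(out_dir, sprintf("ct_%04d.nii.gz", i))
    spf <- file.path(out_dir, sprintf("spect_%04d.nii.gz", i))
    trf <- file.path(out_dir, sprintf("truth_%04d.nii.gz", i))
    write_volume(ph$ct, ctf)
    write_volume(ph$spect, spf)
    write_volume(ph$truth_mask, trf)
    k <- ph$kidneys
    k$weight_kg <- ph$subject$weight_kg
    k$height_cm <- ph$subject$height_cm
    k$injected_mbq <- ph$subject$injected_mbq
    k$sex <- ph$subject$sex
    k$age <- ph$subject$age
    k$contrast_pelvis <- ph$contrast_pelvis
    k$ct_file <- basename(ctf)
    k$spect_file <- basename(spf)
    k$truth_file <- basename(trf)
    rows[[i]] <- k
  }
  manifest <- do.call(rbind, rows)
  write.table(as.data.frame(manifest), file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "phantom_config.yaml"))
  invisible(tibble::as_tibble(manifest))
}

#' Read a cohort manifest
#'
#' @param path a `manifest.tsv` written by [generate_cohort()], or its
#'   directory.
#' @return tibble, one row per kidney.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
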