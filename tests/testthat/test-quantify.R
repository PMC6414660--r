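test_that("system sensitivity and unit conversions are exact", {
  expect_identical(counts_to_activity(152.5), 1)
  expect_identical(counts_to_activity(0), 0)
  expect_identical(counts_to_activity(305), 2)
  expect_equal(activity_to_counts(counts_to_activity(77.3)), 77.3,
               tolerance = 1e-12)
  expect_equal(uci_to_mbq(1), 0.037)
  expect_equal(mbq_to_uci(uci_to_mbq(5.4)), 5.4, tolerance = 1e-12)
  expect_error(counts_to_activity(-1), "non-negative")
})

test_that("the %ID to GFR conversion is the exact affine calibration", {
  expect_equal(gfr_from_pid(0), 23.0653, tolerance = 1e-12)
  expect_equal(gfr_from_pid(1) - gfr_from_pid(0), 9.1462, tolerance = 1e-12)
  expect_equal(gfr_from_pid(10), 114.5273, tolerance = 1e-12)
  # strictly increasing affine map
  p <- seq(0, 20, by = 0.5)
  expect_true(all(diff(gfr_from_pid(p)) > 0))
  expect_error(gfr_from_pid(-0.1), "non-negative")
})

test_that("Dubois BSA evaluates the printed formula", {
  expect_equal(bsa_dubois(1, 1), 0.007184, tolerance = 1e-15)
  expect_equal(bsa_dubois(80, 180), 1.996421, tolerance = 1e-5)
  expect_gt(bsa_dubois(81, 180), bsa_dubois(80, 180))
  expect_gt(bsa_dubois(80, 181), bsa_dubois(80, 180))
  expect_error(bsa_dubois(0, 170), "positive")
})

test_that("total GFR normalizes the bilateral sum to 1.73 m2", {
  expect_equal(total_gfr(c(30, 40), 1.73), 70, tolerance = 1e-12)
  expect_equal(total_gfr(50, 2.0), 43.25, tolerance = 1e-12)
  expect_equal(total_gfr(c(60, 60), 1.73), 120, tolerance = 1e-12)
  expect_error(total_gfr(numeric(0), 1.8), "at least one")
  expect_error(total_gfr(50, 0), "positive")
})

make_spect_fixture <- function(conc_left = 2e5, conc_right = 1e5,
                               injected = 370) {
  vals <- array(0, dim = c(10L, 6L, 6L))
  vals[2:4, 2:4, 2:4] <- conc_left    # small x = left
  vals[7:9, 2:4, 2:4] <- conc_right
  spect <- volume_grid(vals, spacing_mm = c(10, 10, 10),
                       origin_mm = c(-45, -25, -25), units = "Bq_per_ml")
  mask <- array(0, dim = c(10L, 6L, 6L))
  mask[2:4, 2:4, 2:4] <- 1
  mask[7:9, 2:4, 2:4] <- 1
  voi <- labeled_mask(mask, spacing_mm = c(10, 10, 10),
                      origin_mm = c(-45, -25, -25))
  subj <- subject_record("S1", weight_kg = 70, height_cm = 170,
                         injected_mbq = injected)
  list(spect = spect, voi = voi, subject = subj)
}

test_that("compute_pid integrates concentration over each kidney VOI", {
  fx <- make_spect_fixture()
  res <- compute_pid(fx$spect, fx$voi, fx$subject)
  vox_ml <- 1  # 10 mm cube = 1 ml
  exp_left <- 100 * (27 * 2e5 * vox_ml / 1e6) / 370
  exp_right <- 100 * (27 * 1e5 * vox_ml / 1e6) / 370
  expect_equal(res$pid[res$side == "left"], exp_left, tolerance = 1e-12)
  expect_equal(res$pid[res$side == "right"], exp_right, tolerance = 1e-12)

  # linearity in the SPECT values: halving the concentration halves %ID
  half <- fx$spect
  half$values <- half$values / 2
  res2 <- compute_pid(half, fx$voi, fx$subject)
  expect_equal(res2$pid, res$pid / 2, tolerance = 1e-12)

  # and zeroing half the parenchyma voxels of a uniform kidney halves %ID
  vals <- array(0, dim = c(4L, 4L, 4L))
  vals[1:2, 1:2, 1:2] <- 5e4
  sp <- volume_grid(vals, spacing_mm = c(10, 10, 10), units = "Bq_per_ml")
  voi <- labeled_mask(array(as.numeric(vals > 0), dim(vals)),
                      spacing_mm = c(10, 10, 10))
  full <- suppressWarnings(compute_pid(sp, voi, fx$subject))
  vz <- vals
  vz[which(vals > 0)[1:4]] <- 0
  spz <- volume_grid(vz, spacing_mm = c(10, 10, 10), units = "Bq_per_ml")
  halfvox <- suppressWarnings(compute_pid(spz, voi, fx$subject))
  expect_equal(sum(halfvox$pid), sum(full$pid) / 2, tolerance = 1e-9)
})

test_that("a VOI holding the entire injected activity reads 100 %ID", {
  vals <- array(0, dim = c(4L, 4L, 4L))
  vals[2:3, 2:3, 2:3] <- 370 / (8 / 1e6)  # Bq/ml so total = 370 MBq
  spect <- volume_grid(vals, spacing_mm = c(10, 10, 10), units = "Bq_per_ml")
  mask <- array(as.numeric(vals > 0), dim = dim(vals))
  voi <- labeled_mask(mask, spacing_mm = c(10, 10, 10))
  subj <- subject_record("S2", 70, 170, injected_mbq = 370)
  res <- suppressWarnings(compute_pid(spect, voi, subj))
  expect_equal(max(res$pid), 100, tolerance = 1e-9)
})

test_that("the counts pathway goes through the system sensitivity", {
  fx <- make_spect_fixture()
  act_uci <- mbq_to_uci(fx$spect$values * 1 / 1e6)  # per-voxel MBq -> uCi
  counts <- volume_grid(activity_to_counts(act_uci),
                        spacing_mm = fx$spect$spacing_mm,
                        origin_mm = fx$spect$origin_mm, units = "counts")
  res_c <- compute_pid(counts, fx$voi, fx$subject, acquisition_minutes = 1)
  res_a <- compute_pid(fx$spect, fx$voi, fx$subject)
  expect_equal(res_c$pid, res_a$pid, tolerance = 1e-9)
})

test_that("compute_pid guards its contract", {
  fx <- make_spect_fixture()
  other <- volume_grid(fx$spect$values, spacing_mm = c(9, 10, 10),
                       origin_mm = fx$spect$origin_mm, units = "Bq_per_ml")
  expect_error(compute_pid(other, fx$voi, fx$subject), "same grid")
  bad <- fx$spect
  bad$units <- "HU"
  expect_error(compute_pid(bad, fx$voi, fx$subject), "units")

  # missing side: pid 0 with a warning
  mask <- array(0, dim = dim(fx$spect$values))
  mask[2:4, 2:4, 2:4] <- 1
  left_only <- labeled_mask(mask, spacing_mm = c(10, 10, 10),
                            origin_mm = c(-45, -25, -25))
  expect_warning(res <- compute_pid(fx$spect, left_only, fx$subject), "empty")
  expect_equal(res$pid[res$side == "right"], 0)

  # %ID above 100 under extreme values clamps with a warning (heat one side
  # so exactly one clamp fires)
  hot <- fx$spect
  hot$values[2:4, 2:4, 2:4] <- hot$values[2:4, 2:4, 2:4] * 1e3
  expect_warning(resh <- compute_pid(hot, fx$voi, fx$subject), "clamped")
  expect_true(all(resh$pid <= 100))
})

test_that("quantify_subject composes the chain and keeps its invariant", {
  fx <- make_spect_fixture()
  res <- quantify_subject(fx$spect, fx$voi, fx$subject)
  expect_s3_class(res, "gfr_result")
  expect_equal(nrow(res$kidneys), 2)
  expect_equal(res$kidneys$gfr, gfr_from_pid(res$kidneys$pid), tolerance = 1e-12)
  expect_equal(res$bsa, bsa_dubois(70, 170), tolerance = 1e-12)
  expect_equal(res$total_gfr, sum(res$kidneys$gfr) * 1.73 / res$bsa,
               tolerance = 1e-12)
  td <- tidy(res)
  expect_true(all(c("subject", "side", "pid", "gfr") %in% names(td)))
  expect_equal(glance(res)$total_gfr, res$total_gfr)

  # single kidney: one entry
  mask <- array(0, dim = dim(fx$spect$values))
  mask[2:4, 2:4, 2:4] <- 1
  left_only <- labeled_mask(mask, spacing_mm = c(10, 10, 10),
                            origin_mm = c(-45, -25, -25))
  res1 <- suppressWarnings(quantify_subject(fx$spect, left_only, fx$subject))
  expect_equal(nrow(res1$kidneys), 1)
  expect_equal(res1$total_gfr, res1$kidneys$gfr * 1.73 / res1$bsa,
               tolerance = 1e-12)

  js <- jsonlite::fromJSON(gfr_result_json(res))
  expect_equal(js$total_gfr_ml_min_173, res$total_gfr, tolerance = 1e-9)
})

test_that("subject records demand positive anthropometrics", {
  expect_error(subject_record("x", 0, 170), "positive")
  expect_error(subject_record("x", 70, -1), "positive")
  expect_error(subject_record("x", 70, 170, injected_mbq = 0), "positive")
})
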