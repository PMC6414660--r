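#' Subject record
#'
#' Anthropometrics and injection data needed to turn VOI activity into a
#' BSA-normalized GFR, plus annotation fields used by the group analysis.
#'
#' @param id subject identifier.
#' @param weight_kg body weight (kg, > 0).
#' @param height_cm body height (cm, > 0).
#' @param injected_mbq injected 99mTc-DTPA activity (MBq, > 0; nominal 370).
#' @param sex,age annotation only.
#' @return One-row tibble of class `subject_record`.
#' @export
subject_record <- function(id, weight_kg, height_cm, injected_mbq = 370,
                           sex = NA_character_, age = NA_real_) {
  if (weight_kg <= 0 || height_cm <= 0 || injected_mbq <= 0)
    stop("weight, height and injected activity must be strictly positive",
         call. = FALSE)
  out <- tibble::tibble(id = as.character(id), weight_kg = weight_kg,
                        height_cm = height_cm, injected_mbq = injected_mbq,
                        sex = sex, age = age)
  class(out) <- c("subject_record", class(out))
  out
}

# system sensitivity of the SPECT camera for 99mTc, determined by phantom
# calibration: counts per minute per microcurie
SYSTEM_SENSITIVITY_CPM_PER_UCI <- 152.5
MBQ_PER_UCI <- 0.037

#' Convert a count rate to activity via the system sensitivity
#'
#' The quantitative SPECT calibration: 152.5 counts per minute per
#' microcurie of 99mTc.
#'
#' @param count_rate_cpm count rate (counts/min, >= 0).
#' @return activity in microcuries.
#' @export
counts_to_activity <- function(count_rate_cpm) {
  if (any(count_rate_cpm < 0)) stop("count rate must be non-negative", call. = FALSE)
  count_rate_cpm / SYSTEM_SENSITIVITY_CPM_PER_UCI
}

#' @rdname counts_to_activity
#' @param activity_uci activity in microcuries (>= 0).
#' @export
activity_to_counts <- function(activity_uci) {
  if (any(activity_uci < 0)) stop("activity must be non-negative", call. = FALSE)
  activity_uci * SYSTEM_SENSITIVITY_CPM_PER_UCI
}

#' Microcurie / megabecquerel conversion
#' @param uci activity in microcuries.
#' @return megabecquerels (1 uCi = 0.037 MBq).
#' @export
uci_to_mbq <- function(uci) uci * MBQ_PER_UCI

#' @rdname uci_to_mbq
#' @param mbq activity in MBq.
#' @export
mbq_to_uci <- function(mbq) mbq / MBQ_PER_UCI

#' Percent injected dose within a VOI
#'
#' Applies a parenchyma VOI to the quantitative SPECT volume and returns
#' the per-kidney percent injected dose. Concentration input
#' (`Bq_per_ml`): activity is the sum of value times voxel volume. Counts
#' input: total counts over the acquisition are converted through the
#' system sensitivity ([counts_to_activity()]). No decay correction is
#' applied (the 2-3 min between injection and acquisition is < 0.6% of a
#' 99mTc half-life).
#'
#' @param spect a [volume_grid()] with units `"Bq_per_ml"` or `"counts"`.
#' @param voi a [labeled_mask()] on the same grid.
#' @param subject a [subject_record()].
#' @param acquisition_minutes acquisition duration for counts input
#'   (default 1).
#' @return tibble, one row per side: `side`, `voi_volume_ml`,
#'   `voi_activity_mbq`, `pid`. An absent side yields `pid = 0` with a
#'   warning. Values above 100% (possible under noise) are clamped with a
#'   warning.
#' @export
compute_pid <- function(spect, voi, subject, acquisition_minutes = 1) {
  stopifnot(inherits(spect, "volume_grid"), inherits(voi, "labeled_mask"),
            inherits(subject, "subject_record"))
  if (!spect$units %in% c("Bq_per_ml", "counts"))
    stop("spect units must be Bq_per_ml or counts, got ", spect$units, call. = FALSE)
  stopifnot_same_grid(spect, voi$grid)
  vox_ml <- voxel_volume_ml(spect)
  rows <- lapply(c("left", "right"), function(s) {
    sm <- side_mask(voi, s)
    nvox <- sum(sm)
    if (nvox == 0) {
      warning("empty ", s, " VOI: %ID set to 0")
      return(tibble::tibble(side = s, voi_volume_ml = 0, voi_activity_mbq = 0,
                            pid = 0))
    }
    if (spect$units == "Bq_per_ml") {
      act_mbq <- sum(spect$values[sm]) * vox_ml / 1e6
    } else {
      act_mbq <- uci_to_mbq(counts_to_activity(sum(spect$values[sm]) /
                                                 acquisition_minutes))
    }
    pid <- 100 * act_mbq / subject$injected_mbq
    if (pid > 100) {
      warning(sprintf("%s kidney %%ID %.1f clamped to 100", s, pid))
      pid <- 100
    }
    tibble::tibble(side = s, voi_volume_ml = nvox * vox_ml,
                   voi_activity_mbq = act_mbq, pid = pid)
  })
  do.call(rbind, rows)
}

#' Convert percent injected dose to single-kidney GFR
#'
#' The calibrated linear conversion between parenchymal %ID on
#' quantitative SPECT (2-3 min post-injection) and glomerular filtration
#' rate: `GFR (ml/min) = %ID x 9.1462 + 23.0653`, applied per kidney.
#'
#' @param pid percent injected dose (>= 0).
#' @return GFR in ml/min.
#' @export
gfr_from_pid <- function(pid) {
  if (any(pid < 0)) stop("%ID must be non-negative", call. = FALSE)
  pid * 9.1462 + 23.0653
}

#' Body surface area (Dubois)
#'
#' `BSA (m2) = 0.007184 x weight(kg)^0.425 x height(cm)^0.725`.
#'
#' @param weight_kg weight in kg (> 0).
#' @param height_cm height in cm (> 0).
#' @return body surface area in m2.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be strictly positive", call. = FALSE)
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' BSA-normalized total GFR
#'
#' Sum of the per-kidney GFRs normalized to the 1.73 m2 reference surface:
#' `total = sum(gfr) x 1.73 / BSA`, in ml/min/1.73 m2.
#'
#' @param per_kidney_gfr numeric vector of 1 or 2 per-kidney GFRs (ml/min).
#' @param bsa body surface area (m2, > 0).
#' @return total GFR in ml/min/1.73 m2.
#' @export
total_gfr <- function(per_kidney_gfr, bsa) {
  if (length(per_kidney_gfr) < 1) stop("at least one kidney GFR is required",
                                       call. = FALSE)
  if (bsa <= 0) stop("BSA must be positive", call. = FALSE)
  sum(per_kidney_gfr) * 1.73 / bsa
}

#' Quantify a subject: VOI activity to GFR
#'
#' Composes the quantification chain: [compute_pid()] on the SPECT volume,
#' [gfr_from_pid()] per kidney, [bsa_dubois()] and [total_gfr()].
#'
#' @inheritParams compute_pid
#' @return A `gfr_result`: list with `kidneys` (tibble: side,
#'   voi_volume_ml, voi_activity_mbq, pid, gfr; absent sides dropped),
#'   `bsa` (m2), `total_gfr` (ml/min/1.73 m2) and `subject`.
#' @export
quantify_subject <- function(spect, voi, subject, acquisition_minutes = 1) {
  k <- compute_pid(spect, voi, subject, acquisition_minutes)
  k <- k[k$voi_volume_ml > 0, , drop = FALSE]
  if (nrow(k) == 0) {
    k$gfr <- numeric(0)
  } else {
    k$gfr <- gfr_from_pid(k$pid)
  }
  bsa <- bsa_dubois(subject$weight_kg, subject$height_cm)
  tot <- if (nrow(k) >= 1) total_gfr(k$gfr, bsa) else NA_real_
  structure(list(kidneys = k, bsa = bsa, total_gfr = tot, subject = subject),
            class = "gfr_result")
}

#' @export
print.gfr_result <- function(x, ...) {
  cat(sprintf("<gfr_result> subject %s (BSA %.2f m2)\n", x$subject$id, x$bsa))
  for (i in seq_len(nrow(x$kidneys)))
    cat(sprintf("  %-5s %%ID %5.2f  GFR %6.2f ml/min\n",
                x$kidneys$side[i], x$kidneys$pid[i], x$kidneys$gfr[i]))
  cat(sprintf("  total GFR %.2f ml/min/1.73m2\n", x$total_gfr))
  invisible(x)
}

#' @method tidy gfr_result
#' @export
tidy.gfr_result <- function(x, ...) {
  out <- x$kidneys
  out$subject <- x$subject$id
  out[, c("subject", setdiff(names(out), "subject"))]
}

#' @method glance gfr_result
#' @export
glance.gfr_result <- function(x, ...) {
  tibble::tibble(subject = x$subject$id, n_kidneys = nrow(x$kidneys),
                 bsa = x$bsa, total_gfr = x$total_gfr)
}

#' Serialize a GFR result to JSON
#'
#' @param x a `gfr_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
gfr_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "gfr_result"))
  obj <- list(schema = 1L, subject = as.list(x$subject),
              kidneys = x$kidneys, bsa_m2 = x$bsa,
              total_gfr_ml_min_173 = x$total_gfr)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
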