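#' Volumetric scalar lattice with physical geometry
#'
#' A `volume_grid` is the package's container for every volumetric quantity:
#' CT attenuation (Hounsfield units), quantitative SPECT activity
#' concentration (Bq/ml), raw counts, network probability maps and binary
#' masks. It stores a 3D array together with voxel spacing and world origin
#' under a voxel-center convention: the world coordinate of 0-based voxel
#' index `i` is `origin_mm + i * spacing_mm`. Axes follow the RAS+
#' anatomical convention (world x increases towards the subject's Right,
#' y towards Anterior, z towards Superior).
#'
#' @param values 3D numeric array.
#' @param spacing_mm positive numeric triple, voxel spacing in mm.
#' @param origin_mm numeric triple, world coordinate (mm) of voxel (0,0,0).
#' @param units one of `"HU"`, `"Bq_per_ml"`, `"counts"`, `"probability"`,
#'   `"binary"`.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                        units = c("HU", "Bq_per_ml", "counts", "probability", "binary")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a positive numeric triple", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be a finite numeric triple", call. = FALSE)
  if (units == "binary" && !all(values %in% c(0, 1)))
    stop("binary volume must contain only 0/1 values", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, units = units),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s, %d x %d x %d @ (%.3f, %.3f, %.3f) mm\n",
              x$units, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, value range [%.3g, %.3g]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel volume of a grid in millilitres
#' @param v a [volume_grid()].
#' @return scalar, ml per voxel.
#' @export
voxel_volume_ml <- function(v) prod(v$spacing_mm) / 1000

#' World coordinate of the grid center
#' @param v a [volume_grid()].
#' @return numeric triple (mm).
#' @export
grid_center <- function(v) v$origin_mm + (dim(v$values) - 1) / 2 * v$spacing_mm

# grid identity to 1e-3 mm: NIfTI-1 headers hold float32 geometry, so
# round-tripped origins can differ at the 1e-5 mm level
stopifnot_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(dim(a$values), dim(b$values))) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-3 ||
      max(abs(a$origin_mm - b$origin_mm)) > 1e-3)
    stop("volumes are not defined on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image into a [volume_grid()]. Spacing and origin are
#' taken from the stored xform (axis-aligned affines only); the unit tag is
#' supplied by the caller because NIfTI headers do not carry it.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units unit tag for the values, see [volume_grid()].
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, units = "HU") {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), "D: ", path,
                            call. = FALSE)
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header: ", path,
                              call. = FALSE)
  off <- abs(xf[1:3, 1:3]) - diag(abs(diag(xf[1:3, 1:3])))
  if (max(abs(off)) > 1e-4)
    warning("non-axis-aligned affine; only spacing and translation are honored")
  volume_grid(array(as.numeric(img), dim = d), spacing_mm = spacing,
              origin_mm = origin, units = units)
}

#' Write a volume as NIfTI-1
#'
#' @param v a [volume_grid()] (or [labeled_mask()], whose binary grid is
#'   written).
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "labeled_mask")) v <- v$grid
  stopifnot(inherits(v, "volume_grid"))
  img <- RNifti::asNifti(v$values)
  m <- diag(c(v$spacing_mm, 1))
  m[1:3, 4] <- v$origin_mm
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- v$spacing_mm
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write volume to ", path, call. = FALSE)
  invisible(path)
}

#' Resample a volume onto a new grid
#'
#' Trilinear resampling onto a target spacing (and optionally an explicit
#' target shape). The output grid is centered on the input volume's world
#' center, so a field of view change trims or pads symmetrically. In
#' `"mask"` mode the binary field is interpolated trilinearly and
#' re-thresholded at 0.5, so the output stays binary while edges move
#' smoothly (nearest-neighbour staircasing is avoided).
#'
#' @param v a [volume_grid()].
#' @param target_spacing_mm positive numeric triple (a scalar is recycled).
#' @param target_shape integer triple; default covers the input extent.
#' @param mode `"continuous"` (default) or `"mask"` (binary input required).
#' @param fill value used outside the input field of view (default 0).
#' @return A [volume_grid()] on the target grid.
#' @export
resample <- function(v, target_spacing_mm, target_shape = NULL,
                     mode = c("continuous", "mask"), fill = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "volume_grid"))
  target_spacing_mm <- rep(as.numeric(target_spacing_mm), length.out = 3)
  if (any(target_spacing_mm <= 0)) stop("target spacing must be positive", call. = FALSE)
  if (mode == "mask" && v$units != "binary")
    stop("mode = \"mask\" requires a binary unit tag, got ", v$units, call. = FALSE)
  d <- dim(v$values)
  if (is.null(target_shape))
    target_shape <- pmax(1L, as.integer(round(d * v$spacing_mm / target_spacing_mm)))
  target_shape <- as.integer(target_shape)
  ctr <- grid_center(v)
  out_origin <- ctr - (target_shape - 1) / 2 * target_spacing_mm
  vals <- cpp_resample_trilinear(as.numeric(v$values), d, v$spacing_mm, v$origin_mm,
                                 target_shape, target_spacing_mm, out_origin,
                                 fill)
  vals <- array(vals, dim = target_shape)
  if (mode == "mask") {
    vals <- array(as.numeric(vals >= 0.5), dim = target_shape)
    units <- "binary"
  } else units <- v$units
  volume_grid(vals, spacing_mm = target_spacing_mm, origin_mm = out_origin,
              units = units)
}

#' Crop (with zero padding) to a fixed window
#'
#' Extracts a `window_shape` box about `center` (a 1-based voxel index;
#' default the grid center), zero-padding where the window exceeds the
#' volume. The output carries inverse-mapping metadata so predictions made
#' on the window can be placed back on the uncropped grid with [uncrop()].
#'
#' @param v a [volume_grid()].
#' @param window_shape integer triple.
#' @param center 1-based voxel index triple; default grid center.
#' @param fill pad value (default 0).
#' @return A [volume_grid()] of shape `window_shape` with a `crop_info`
#'   attribute.
#' @export
crop_to_window <- function(v, window_shape, center = NULL, fill = 0) {
  stopifnot(inherits(v, "volume_grid"))
  window_shape <- as.integer(window_shape)
  d <- dim(v$values)
  if (is.null(center)) center <- (d + 1) / 2
  start <- as.integer(ceiling(center - window_shape / 2))  # 1-based start
  out <- array(fill, dim = window_shape)
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + window_shape - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1L
    dst_hi <- src_hi - start + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      v$values[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  origin <- v$origin_mm + (start - 1) * v$spacing_mm
  w <- volume_grid(out, spacing_mm = v$spacing_mm, origin_mm = origin,
                   units = v$units)
  attr(w, "crop_info") <- list(orig_shape = d, orig_origin = v$origin_mm,
                               start = start, fill = fill)
  w
}

#' Place a cropped window back on its original grid
#'
#' Inverse of [crop_to_window()]: voxels outside the window are set to
#' `fill` (default 0).
#'
#' @param w a window produced by [crop_to_window()] (the `crop_info`
#'   attribute must be present), or any [volume_grid()] plus an explicit
#'   `crop_info` list.
#' @param crop_info optional override of the stored metadata.
#' @param fill value outside the window.
#' @return A [volume_grid()] on the original uncropped grid.
#' @export
uncrop <- function(w, crop_info = NULL, fill = 0) {
  stopifnot(inherits(w, "volume_grid"))
  ci <- crop_info %||% attr(w, "crop_info")
  if (is.null(ci)) stop("no crop_info available; was this window produced by crop_to_window()?",
                        call. = FALSE)
  d <- ci$orig_shape
  out <- array(fill, dim = d)
  ws <- dim(w$values)
  src_lo <- pmax(ci$start, 1L)
  src_hi <- pmin(ci$start + ws - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - ci$start + 1L
    dst_hi <- src_hi - ci$start + 1L
    out[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]] <-
      w$values[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]]
  }
  volume_grid(out, spacing_mm = w$spacing_mm, origin_mm = ci$orig_origin,
              units = w$units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary parenchyma mask with per-kidney laterality labels
#'
#' Wraps a binary [volume_grid()] together with its 26-connected components
#' and a left/right label per component. Laterality is assigned from the
#' component centroid's world x coordinate relative to the mid-sagittal
#' plane of the grid.
#'
#' @details With the RAS+ axis convention used throughout the package,
#' world x increases towards the subject's right, so the component whose
#' centroid has the larger world x is labelled `"right"`. With two
#' components the assignment is by relative order (the larger-x component
#' is `"right"`), which stays meaningful even if both components sit on one
#' side of the grid midline; with a single component the side is taken
#' relative to the volume center.
#'
#' @param grid a binary [volume_grid()] (or a 0/1 array plus `spacing_mm`).
#' @param spacing_mm,origin_mm geometry, used only when `grid` is an array.
#' @param max_components keep at most this many largest components
#'   (default `Inf`, i.e. all).
#' @return A `labeled_mask`: list with `grid` (binary volume_grid),
#'   `component_map` (integer array, 0 = background, 1..k by decreasing
#'   size) and `sides` (character vector per component).
#' @export
labeled_mask <- function(grid, spacing_mm = NULL, origin_mm = c(0, 0, 0),
                         max_components = Inf) {
  if (!inherits(grid, "volume_grid")) {
    grid <- volume_grid(array(as.numeric(grid != 0), dim = dim(grid)),
                        spacing_mm = spacing_mm, origin_mm = origin_mm,
                        units = "binary")
  }
  if (grid$units != "binary") stop("labeled_mask requires a binary grid", call. = FALSE)
  d <- dim(grid$values)
  comp <- array(cpp_label_components(as.integer(grid$values != 0), d), dim = d)
  k <- max(comp)
  if (is.finite(max_components) && k > max_components) {
    comp[comp > max_components] <- 0L
    k <- as.integer(max_components)
    grid$values <- array(as.numeric(comp > 0), dim = d)
  }
  sides <- character(0)
  if (k >= 1) {
    cx <- vapply(seq_len(k), function(i) {
      idx <- which(comp == i, arr.ind = TRUE)
      grid$origin_mm[1] + (mean(idx[, 1]) - 1) * grid$spacing_mm[1]
    }, numeric(1))
    if (k == 1) {
      sides <- if (cx >= grid_center(grid)[1]) "right" else "left"
    } else {
      sides <- rep("left", k)
      sides[which.max(cx)] <- "right"
      if (k > 2) {
        # beyond two components keep side by midline for the remainder
        mid <- grid_center(grid)[1]
        extra <- setdiff(seq_len(k), c(which.max(cx), which.min(cx)))
        sides[extra] <- ifelse(cx[extra] >= mid, "right", "left")
      }
    }
  }
  structure(list(grid = grid, component_map = comp, sides = sides),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d component(s): %s; %d foreground voxels\n",
              length(x$sides), paste(x$sides, collapse = ", "),
              sum(x$grid$values)))
  invisible(x)
}

#' Extract one side of a labeled mask
#'
#' @param m a [labeled_mask()].
#' @param side `"left"` or `"right"`.
#' @return logical array (TRUE on that kidney's voxels; all-FALSE for a
#'   missing side, as in single-kidney subjects).
#' @export
side_mask <- function(m, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(m, "labeled_mask"))
  keep <- which(m$sides == side)
  if (length(keep) == 0) return(array(FALSE, dim = dim(m$grid$values)))
  array(m$component_map %in% keep, dim = dim(m$grid$values))
}

#' Smooth and close a binary mask
#'
#' Reduces the inter-slice discontinuity left by stacked 2D ROI drawing:
#' Gaussian-smooths the binary indicator at `sigma_mm`, re-thresholds at
#' 0.5, then applies morphological closing with a cubic structuring element.
#' Laterality labels are recomputed.
#'
#' @param m a [labeled_mask()] or binary [volume_grid()].
#' @param sigma_mm Gaussian sigma in mm; default one voxel of the grid.
#' @param closing_radius_vox closing radius in voxels (default 1).
#' @return A [labeled_mask()].
#' @export
smooth_mask <- function(m, sigma_mm = NULL, closing_radius_vox = 1L) {
  g <- if (inherits(m, "labeled_mask")) m$grid else m
  stopifnot(inherits(g, "volume_grid"))
  if (g$units != "binary") stop("smooth_mask requires a binary mask", call. = FALSE)
  if (sum(g$values) == 0) {
    warning("smooth_mask: empty mask returned unchanged")
    return(labeled_mask(g))
  }
  d <- dim(g$values)
  sigma_mm <- sigma_mm %||% g$spacing_mm
  sigma_vox <- rep(as.numeric(sigma_mm), length.out = 3) / g$spacing_mm
  sm <- cpp_gauss_smooth3(as.numeric(g$values), d, sigma_vox)
  bin <- as.integer(sm >= 0.5)
  if (closing_radius_vox > 0) {
    bin <- cpp_binary_morph(bin, d, as.integer(closing_radius_vox), TRUE)
    bin <- cpp_binary_morph(bin, d, as.integer(closing_radius_vox), FALSE)
  }
  out <- volume_grid(array(as.numeric(bin), dim = d), spacing_mm = g$spacing_mm,
                     origin_mm = g$origin_mm, units = "binary")
  labeled_mask(out)
}
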