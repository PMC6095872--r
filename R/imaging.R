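#' 3-D image and mask containers
#'
#' An `image3d` is a scalar 3-D voxel grid with physical spacing (mm per axis),
#' a modality tag and an intensity-unit tag. A `mask3d` is an aligned binary
#' grid marking the tumor region. These are deliberately lightweight lists:
#' everything downstream of feature extraction works on tibbles.
#'
#' @param voxels Numeric 3-D array. For masks, anything coercible to logical.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all `> 0`.
#' @param modality `"PET"` or `"MR"`.
#' @param units One of `"activity_conc_kBq_per_ml"`, `"SUV"`, `"arbitrary"`.
#' @return An object of class `image3d` (resp. `mask3d`).
#' @examples
#' img <- image3d(array(1, c(4, 4, 4)), spacing = c(2, 2, 2),
#'                modality = "PET", units = "SUV")
#' msk <- mask3d(array(TRUE, c(4, 4, 4)), spacing = c(2, 2, 2))
#' @export
image3d <- function(voxels, spacing, modality = c("PET", "MR"),
                    units = c("arbitrary", "activity_conc_kBq_per_ml", "SUV")) {
  modality <- match.arg(modality)
  units <- match.arg(units)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || length(voxels) == 0L) {
    abort("`voxels` must be a non-empty 3-D array.")
  }
  if (!all(is.finite(voxels))) abort("`voxels` must contain finite values only.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite values (mm).")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 modality = modality, units = units),
            class = "image3d")
}

#' @rdname image3d
#' @export
mask3d <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) abort("mask `voxels` must be a 3-D array.")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) abort("mask must not contain missing values.")
  if (!any(voxels)) abort("mask must contain at least one foreground voxel.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive values (mm).")
  }
  structure(list(voxels = voxels, spacing = spacing), class = "mask3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("<image3d> %s [%s] %s voxels @ %s mm\n", x$modality, x$units,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(image, mask) {
  if (!identical(dim(image$voxels), dim(mask$voxels))) {
    abort("image and mask grids have different shapes.")
  }
  if (max(abs(image$spacing - mask$spacing)) > 1e-9) {
    abort("image and mask have different voxel spacing.")
  }
  invisible(TRUE)
}

masked_values <- function(image, mask) {
  check_aligned(image, mask)
  image$voxels[mask$voxels]
}

## Trilinear sample of a 3-D array at fractional 0-based grid positions given
## per-axis index vectors; subsetting arr[ix, iy, iz] expands the outer grid.
trilinear_grid <- function(arr, ux, uy, uz) {
  d <- dim(arr)
  clamp <- function(u, n) pmin(pmax(u, 0), n - 1)
  ux <- clamp(ux, d[1]); uy <- clamp(uy, d[2]); uz <- clamp(uz, d[3])
  i0x <- pmin(floor(ux), d[1] - 2L); i0x[d[1] == 1L] <- 0L
  i0y <- pmin(floor(uy), d[2] - 2L); i0y[d[2] == 1L] <- 0L
  i0z <- pmin(floor(uz), d[3] - 2L); i0z[d[3] == 1L] <- 0L
  fx <- ux - i0x; fy <- uy - i0y; fz <- uz - i0z
  out <- array(0, c(length(ux), length(uy), length(uz)))
  wx <- cbind(1 - fx, fx); wy <- cbind(1 - fy, fy); wz <- cbind(1 - fz, fz)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(i0x + dx, d[1] - 1L) + 1L
    iy <- pmin(i0y + dy, d[2] - 1L) + 1L
    iz <- pmin(i0z + dz, d[3] - 1L) + 1L
    w <- outer(outer(wx[, dx + 1L], wy[, dy + 1L]), wz[, dz + 1L])
    out <- out + w * arr[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample an image and its mask to isotropic voxels
#'
#' The image is interpolated trilinearly and the mask by nearest neighbor onto
#' a common isotropic grid of `target_spacing` mm. Output voxel centers start
#' at the first input voxel center and never extrapolate beyond the input
#' extent. Images already at the target spacing are returned unchanged.
#'
#' @param image An [image3d()].
#' @param mask The aligned [mask3d()].
#' @param target_spacing Isotropic voxel size in mm, `> 0`.
#' @param tumor_id Optional id used in error messages.
#' @return A list with elements `image` and `mask` on the new grid.
#' @export
resample_isotropic <- function(image, mask, target_spacing, tumor_id = NULL) {
  check_aligned(image, mask)
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("`target_spacing` must be a single positive number.")
  }
  if (max(abs(image$spacing - t)) < 1e-9) {
    return(list(image = image, mask = mask))
  }
  d <- dim(image$voxels)
  s <- image$spacing
  n_out <- pmax(floor((d - 1) * s / t + 1e-9) + 1L, 1L)
  ux <- (seq_len(n_out[1]) - 1) * t / s[1]
  uy <- (seq_len(n_out[2]) - 1) * t / s[2]
  uz <- (seq_len(n_out[3]) - 1) * t / s[3]
  vox <- trilinear_grid(image$voxels, ux, uy, uz)
  rx <- pmin(pmax(round(ux), 0), d[1] - 1) + 1L
  ry <- pmin(pmax(round(uy), 0), d[2] - 1) + 1L
  rz <- pmin(pmax(round(uz), 0), d[3] - 1) + 1L
  mvox <- mask$voxels[rx, ry, rz, drop = FALSE]
  if (!any(mvox)) {
    abort(sprintf("mask%s is empty after resampling to %g mm",
                  if (is.null(tumor_id)) "" else paste0(" for tumor '", tumor_id, "'"),
                  t))
  }
  list(image = image3d(vox, rep(t, 3), image$modality, image$units),
       mask = mask3d(mvox, rep(t, 3)))
}

#' Convert a PET activity-concentration image to standardized uptake values
#'
#' SUV normalizes the measured activity concentration (kBq/ml) by the injected
#' activity decayed to scan time and the patient's body weight:
#' `SUV = C * weight_g / (activity_kBq * 2^(-delay / half_life))`. With
#' `injection_to_scan_min = 0` the caller may pass an activity that is already
#' decay-corrected to scan time.
#'
#' @param image An [image3d()] with `units = "activity_conc_kBq_per_ml"`.
#' @param body_weight_g Patient body weight in grams, `> 0`.
#' @param injected_activity_kBq Injected activity in kBq, `> 0`.
#' @param injection_to_scan_min Minutes between injection and scan.
#' @param half_life_min Radionuclide half-life in minutes (default fluorine-18,
#'   109.77 min).
#' @return An [image3d()] in SUV units.
#' @export
to_suv <- function(image, body_weight_g, injected_activity_kBq,
                   injection_to_scan_min = 0, half_life_min = 109.77) {
  if (image$units != "activity_conc_kBq_per_ml") {
    abort("`to_suv()` expects an image in activity_conc_kBq_per_ml units.")
  }
  if (!is.finite(body_weight_g) || body_weight_g <= 0) {
    abort("`body_weight_g` must be positive.")
  }
  if (!is.finite(injected_activity_kBq) || injected_activity_kBq <= 0) {
    abort("`injected_activity_kBq` must be positive.")
  }
  decayed <- injected_activity_kBq * 2^(-injection_to_scan_min / half_life_min)
  image3d(image$voxels * body_weight_g / decayed, image$spacing,
          modality = image$modality, units = "SUV")
}

#' Discretize masked intensities with a fixed bin width
#'
#' Gray levels are `floor((I - min_masked) / bin_width) + 1` inside the mask
#' and 0 outside; the first bin anchors at the masked minimum and the masked
#' maximum falls in its ordinary floor bin. A constant region is valid and
#' yields a single level (`Ng = 1`).
#'
#' @param image An [image3d()].
#' @param mask The aligned [mask3d()].
#' @param bin_width Positive intensity bin width (same units as the image).
#' @return A `discretized_image`: list with integer array `levels`, gray-level
#'   count `Ng`, `bin_width`, `anchor` (the masked minimum) and `spacing`.
#' @export
discretize <- function(image, mask, bin_width) {
  check_aligned(image, mask)
  if (!is.finite(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  vals <- image$voxels[mask$voxels]
  anchor <- min(vals)
  lev <- array(0L, dim(image$voxels))
  lev[mask$voxels] <- as.integer(floor((vals - anchor) / bin_width)) + 1L
  structure(list(levels = lev, Ng = max(lev), bin_width = bin_width,
                 anchor = anchor, spacing = image$spacing),
            class = "discretized_image")
}

#' Read / write NIfTI tumor volumes
#'
#' Thin wrappers over RNifti keeping spacing, modality and unit metadata on
#' the `image3d` / `mask3d` containers.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality,units Passed to [image3d()].
#' @return `read_nifti_image()` an [image3d()]; `read_nifti_mask()` a
#'   [mask3d()]; the writers return `path` invisibly.
#' @export
read_nifti_image <- function(path, modality = c("PET", "MR"),
                             units = c("arbitrary", "activity_conc_kBq_per_ml", "SUV")) {
  nii <- RNifti::readNifti(path)
  image3d(as.array(nii), spacing = RNifti::pixdim(nii)[1:3],
          modality = match.arg(modality), units = match.arg(units))
}

#' @rdname read_nifti_image
#' @export
read_nifti_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  mask3d(as.array(nii) > 0.5, spacing = RNifti::pixdim(nii)[1:3])
}

#' @rdname read_nifti_image
#' @param x An [image3d()] or [mask3d()] to write.
#' @export
write_nifti <- function(x, path) {
  vox <- if (inherits(x, "mask3d")) array(as.numeric(x$voxels), dim(x$voxels)) else x$voxels
  nii <- RNifti::asNifti(vox)
  RNifti::pixdim(nii) <- x$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}
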