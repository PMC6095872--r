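#' Radiomic feature registry
#'
#' The frozen set of 42 per-modality feature names with their category
#' (9 first-order, 8 shape, 25 GLCM texture). Cohort tables prefix each name
#' with the modality (`PET_`, `MR_`) for 84 columns per PET+MR tumor.
#'
#' @return A tibble with columns `name` and `category`.
#' @export
feature_registry <- function() {
  tibble(
    name = c(
      "min", "max", "mean", "variance", "skewness", "kurtosis",
      "entropy_hist", "energy_hist", "uniformity_hist",
      "volume", "surface_area", "surface_to_volume", "compactness1",
      "compactness2", "sphericity", "spherical_disproportion",
      "max_diameter_3d",
      "autocorrelation", "cluster_prominence", "cluster_shade",
      "cluster_tendency", "contrast", "correlation", "difference_average",
      "difference_entropy", "difference_variance", "average_intensity",
      "dissimilarity", "energy_glcm", "entropy_glcm", "homogeneity1",
      "homogeneity2", "idmn", "idn", "inverse_variance",
      "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
      "sum_squares", "imc1", "imc2"
    ),
    category = rep(c("first_order", "shape", "texture"), c(9, 8, 25))
  )
}

#' Extract the 42 radiomic features of one image--mask pair
#'
#' Runs [first_order_features()], [shape_features()] and [glcm_features()]
#' (the latter on the fixed-bin-width discretization) and returns them as a
#' single row in registry order.
#'
#' @inheritParams first_order_features
#' @param surface_method Passed to [shape_features()].
#' @param prefix Optional column-name prefix (e.g. `"PET_"`); defaults to the
#'   image modality.
#' @return A one-row tibble with 42 columns.
#' @export
extract_features <- function(image, mask, bin_width,
                             surface_method = c("mesh", "face_count"),
                             prefix = NULL) {
  surface_method <- match.arg(surface_method)
  if (is.null(prefix)) prefix <- paste0(image$modality, "_")
  fo <- first_order_features(image, mask, bin_width)
  sh <- shape_features(mask, surface_method)
  tx <- glcm_features(discretize(image, mask, bin_width))
  out <- bind_cols(fo, sh, tx)
  stopifnot(identical(names(out), feature_registry()$name))
  names(out) <- paste0(prefix, names(out))
  out
}

## resolve one modality of a manifest row: in-memory image3d/mask3d columns
## (`pet`, `pet_mask`, ...) take precedence over path columns (`pet_path`, ...)
manifest_modality <- function(row, modality) {
  key <- tolower(modality)
  img <- NULL
  msk <- NULL
  if (key %in% names(row) && !is.null(row[[key]][[1]])) {
    img <- row[[key]][[1]]
    msk <- row[[paste0(key, "_mask")]][[1]]
  } else if (paste0(key, "_path") %in% names(row) &&
             !is.na(row[[paste0(key, "_path")]])) {
    units <- if (modality == "PET") "activity_conc_kBq_per_ml" else "arbitrary"
    img <- read_nifti_image(row[[paste0(key, "_path")]], modality, units)
    msk <- read_nifti_mask(row[[paste0(key, "_mask_path")]])
  }
  if (is.null(img)) return(NULL)
  list(image = img, mask = msk)
}

#' Preprocess and extract radiomic features for a cohort
#'
#' For every tumor in the manifest: resample image and mask to isotropic
#' spacing, convert PET activity images to SUV using the manifest's body
#' weight, injected activity and uptake delay, and extract the 42 features per
#' modality. The result has one row per tumor and 84 feature columns
#' (`PET_*`, `MR_*`); a missing modality leaves its 42 columns `NA` with a
#' warning.
#'
#' @param manifest A tibble with column `tumor_id`, either path columns
#'   (`pet_path`, `pet_mask_path`, `mr_path`, `mr_mask_path`) or in-memory
#'   list-columns (`pet`, `pet_mask`, `mr`, `mr_mask`), and for SUV conversion
#'   `body_weight_g`, `injected_activity_kBq`, `delay_min`.
#' @param pet_spacing,mr_spacing Isotropic target spacing in mm (defaults
#'   2.0 and 0.5).
#' @param pet_bin_width,mr_bin_width Discretization bin widths (defaults 0.1
#'   SUV and 5.0 arbitrary units).
#' @param surface_method Passed to [shape_features()].
#' @param half_life_min Radionuclide half-life for decay correction.
#' @return A tibble: `tumor_id` plus 84 feature columns.
#' @export
extract_cohort_features <- function(manifest,
                                    pet_spacing = 2.0, mr_spacing = 0.5,
                                    pet_bin_width = 0.1, mr_bin_width = 5.0,
                                    surface_method = c("mesh", "face_count"),
                                    half_life_min = 109.77) {
  surface_method <- match.arg(surface_method)
  stopifnot("tumor_id" %in% names(manifest))
  reg <- feature_registry()$name
  empty42 <- function(prefix) {
    as_tibble(setNames(as.list(rep(NA_real_, 42)), paste0(prefix, reg)))
  }
  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    id <- row$tumor_id
    one <- function(modality, spacing, bin_width) {
      mod <- manifest_modality(row, modality)
      if (is.null(mod)) {
        warn(sprintf("tumor '%s': %s modality missing; features set to NA",
                     id, modality))
        return(empty42(paste0(modality, "_")))
      }
      rs <- resample_isotropic(mod$image, mod$mask, spacing, tumor_id = id)
      img <- rs$image
      if (modality == "PET" && img$units == "activity_conc_kBq_per_ml") {
        img <- to_suv(img, row$body_weight_g, row$injected_activity_kBq,
                      injection_to_scan_min = row$delay_min,
                      half_life_min = half_life_min)
      }
      extract_features(img, rs$mask, bin_width, surface_method,
                       prefix = paste0(modality, "_"))
    }
    rows[[r]] <- bind_cols(tibble(tumor_id = id),
                           one("PET", pet_spacing, pet_bin_width),
                           one("MR", mr_spacing, mr_bin_width))
  }
  bind_rows(rows)
}
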