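## Synthetic PET/MR tumor cohorts with known ground truth. Tumors are
## ellipsoids rasterized at modality spacing whose interior intensity is a
## group mean plus a Gaussian random field (smoothed white noise, so the
## texture correlation length is an interpretable knob) plus white noise.
## Clinical outcomes are statistically coupled to the latent groups (grade,
## subtype, stage via per-group categorical tables; recurrence via a logistic
## model on true mean SUV and log tumor volume), so every downstream stage has
## a recoverable planted signal.

#' Specification of a synthetic PET+MR tumor cohort
#'
#' Defaults describe the package's reference cohort: 90 tumors in 3 equal
#' latent groups that differ in complementary feature directions -- one group
#' has low uptake, strong MR enhancement and fine texture; one high uptake,
#' weak enhancement and intermediate texture; one intermediate intensities
#' but coarse texture and larger size -- so no two groups are systematically
#' closer to each other than to the third. Grade/subtype/stage are drawn from
#' per-group tables and recurrence from a logistic model on the true mean SUV
#' and log volume.
#'
#' @param seed Integer seed (mandatory; the cohort is reproducible from it).
#' @param n_tumors Cohort size.
#' @param group_proportions Latent group proportions (sum to 1).
#' @param pet_mean,pet_sd Per-group tumor SUV mean and texture SD.
#' @param mr_mean,mr_sd Per-group MR intensity mean and texture SD (arbitrary
#'   units).
#' @param corr_len Per-group texture correlation length in voxels.
#' @param semi_axes Per-group ellipsoid semi-axes in mm (groups x 3 matrix).
#' @param axis_jitter Relative uniform jitter applied to each semi-axis.
#' @param noise_frac Fraction of the texture SD carried by uncorrelated white
#'   noise (the rest is the correlated field).
#' @param pet_spacing,mr_spacing Voxel size (mm) at which volumes are
#'   generated.
#' @param grade_coupling Per-group probability table over grades 1..3.
#' @param subtype_coupling Per-group probability table over the four
#'   receptor subtypes.
#' @param rfs_coef Logistic coefficients `(intercept, suv, logvol)` for the
#'   probability of recurrence.
#' @param never_free_prob Probability of the "never disease free" state.
#' @param body_weight_g,injected_activity_kBq,delay_min PET acquisition
#'   parameters recorded in the manifest for SUV conversion.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed,
                        n_tumors = 90L,
                        group_proportions = c(1, 1, 1) / 3,
                        pet_mean = c(2.5, 6.0, 4.0),
                        pet_sd = c(0.4, 0.5, 0.45),
                        mr_mean = c(280, 180, 230),
                        mr_sd = c(30, 25, 28),
                        corr_len = c(0.5, 1.0, 3.0),
                        semi_axes = rbind(c(9, 8, 7), c(11, 9, 8), c(13, 11, 9)),
                        axis_jitter = 0.15,
                        noise_frac = 0.3,
                        pet_spacing = 2.0,
                        mr_spacing = 1.0,
                        grade_coupling = rbind(c(0.75, 0.20, 0.05),
                                               c(0.15, 0.70, 0.15),
                                               c(0.05, 0.20, 0.75)),
                        subtype_coupling = rbind(c(0.15, 0.15, 0.20, 0.50),
                                                 c(0.35, 0.25, 0.25, 0.15),
                                                 c(0.65, 0.15, 0.10, 0.10)),
                        rfs_coef = c(intercept = -1.7, suv = 1.0, logvol = 0.5),
                        never_free_prob = 0.08,
                        body_weight_g = 70000,
                        injected_activity_kBq = 370000,
                        delay_min = 60) {
  if (missing(seed)) abort("`seed` is mandatory for a cohort spec.")
  n_groups <- length(group_proportions)
  stopifnot(abs(sum(group_proportions) - 1) < 1e-8,
            length(pet_mean) == n_groups, length(pet_sd) == n_groups,
            length(mr_mean) == n_groups, length(mr_sd) == n_groups,
            length(corr_len) == n_groups, nrow(semi_axes) == n_groups,
            nrow(grade_coupling) == n_groups,
            nrow(subtype_coupling) == n_groups,
            all(pet_sd > 0), all(mr_sd > 0), all(semi_axes > 0),
            pet_spacing > 0, mr_spacing > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

## unit-variance Gaussian random field plus white-noise admixture
texture_field <- function(dims, corr_len, noise_frac) {
  grf <- array(rnorm(prod(dims)), dims)
  if (corr_len > 0) {
    grf <- gaussian_smooth3d(grf, corr_len)
    s <- sd(as.numeric(grf))
    if (s > 0) grf <- grf / s
  }
  wn <- array(rnorm(prod(dims)), dims)
  sqrt(1 - noise_frac^2) * grf + noise_frac * wn
}

ellipsoid_mask <- function(semi_axes_mm, spacing, margin_vox = 5L) {
  semi_vox <- semi_axes_mm / spacing
  if (any(semi_vox < 1)) {
    abort("ellipsoid semi-axes must be at least one voxel long.")
  }
  dims <- as.integer(2 * ceiling(semi_vox) + 2L * margin_vox + 1L)
  ctr <- (dims + 1) / 2
  u <- lapply(1:3, function(a) ((seq_len(dims[a]) - ctr[a]) / semi_vox[a])^2)
  q <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`)
  list(mask = q <= 1, dims = dims)
}

#' Generate one synthetic PET+MR tumor
#'
#' Rasterizes a jittered ellipsoid at each modality's spacing and fills the
#' grid with `mean + sd * texture`, where the texture is a unit-variance
#' Gaussian random field of the requested correlation length mixed with white
#' noise. Background voxels get a low-uptake version of the same texture. The
#' PET volume is stored in activity-concentration units chosen so that SUV
#' conversion with the manifest's weight/activity/delay recovers the intended
#' SUV field.
#'
#' @param group_params List with `pet_mean`, `pet_sd`, `mr_mean`, `mr_sd`,
#'   `corr_len`, `semi_axes` (mm), `noise_frac`, `pet_spacing`, `mr_spacing`,
#'   `body_weight_g`, `injected_activity_kBq`, `delay_min`.
#' @param seed Integer seed.
#' @return A list: `pet`, `pet_mask`, `mr`, `mr_mask`, and `truth` (the
#'   generative parameters actually used).
#' @export
generate_tumor_volume <- function(group_params, seed) {
  gp <- group_params
  withr::with_seed(seed, {
    decayed <- gp$injected_activity_kBq * 2^(-gp$delay_min / 109.77)
    suv_to_act <- decayed / gp$body_weight_g
    make <- function(spacing, mean_in, sd_in, pet) {
      em <- ellipsoid_mask(gp$semi_axes, spacing)
      tex <- texture_field(em$dims, gp$corr_len, gp$noise_frac)
      bg <- 0.25 * mean_in
      vox <- bg + 0.5 * sd_in * tex
      vox[em$mask] <- mean_in + sd_in * tex[em$mask]
      vox <- pmax(vox, 0.01 * mean_in)
      if (pet) {
        image3d(vox * suv_to_act, rep(spacing, 3), "PET",
                "activity_conc_kBq_per_ml")
      } else {
        image3d(vox, rep(spacing, 3), "MR", "arbitrary")
      }
    }
    pet <- make(gp$pet_spacing, gp$pet_mean, gp$pet_sd, pet = TRUE)
    mr <- make(gp$mr_spacing, gp$mr_mean, gp$mr_sd, pet = FALSE)
    pet_mask <- mask3d(ellipsoid_mask(gp$semi_axes, gp$pet_spacing)$mask,
                       rep(gp$pet_spacing, 3))
    mr_mask <- mask3d(ellipsoid_mask(gp$semi_axes, gp$mr_spacing)$mask,
                      rep(gp$mr_spacing, 3))
    list(pet = pet, pet_mask = pet_mask, mr = mr, mr_mask = mr_mask,
         truth = list(semi_axes = gp$semi_axes,
                      volume_mm3 = 4 / 3 * pi * prod(gp$semi_axes),
                      suv_mean = gp$pet_mean, mr_mean = gp$mr_mean,
                      corr_len = gp$corr_len, seed = seed))
  })
}

sample_counts <- function(n, prop) {
  counts <- floor(prop * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate a full synthetic cohort with coupled clinical outcomes
#'
#' Draws latent groups at the spec's proportions, generates one PET+MR tumor
#' per patient, and samples clinical outcomes coupled to the groups: grade and
#' subtype from the spec's per-group tables, stage from volume-linked tables,
#' and recurrence from a logistic model on standardized true mean SUV and log
#' volume, with a small "never disease free" fraction. RFS dichotomies at 1-5
#' years follow from the sampled recurrence times.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, volumes are written as
#'   NIfTI files and the manifest carries paths, otherwise the manifest holds
#'   the volumes in list-columns.
#' @return A list: `manifest` (tumor volumes + SUV conversion columns),
#'   `clinical` (outcomes table), `truth` (latent groups and generative
#'   parameters per tumor).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_tumors
  G <- length(spec$group_proportions)
  subtypes <- c("HR+/HER2-", "HR+/HER2+", "HR-/HER2+", "HR-/HER2-")
  withr::with_seed(spec$seed, {
    group <- sample(rep(seq_len(G), sample_counts(n, spec$group_proportions)))
    tumor_seed <- sample.int(.Machine$integer.max - 1L, n)
    ids <- sprintf("T%03d", seq_len(n))
    vols <- vector("list", n)
    semi <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      g <- group[i]
      semi[i, ] <- spec$semi_axes[g, ] *
        (1 + runif(3, -spec$axis_jitter, spec$axis_jitter))
      gp <- list(pet_mean = spec$pet_mean[g], pet_sd = spec$pet_sd[g],
                 mr_mean = spec$mr_mean[g], mr_sd = spec$mr_sd[g],
                 corr_len = spec$corr_len[g], semi_axes = semi[i, ],
                 noise_frac = spec$noise_frac,
                 pet_spacing = spec$pet_spacing, mr_spacing = spec$mr_spacing,
                 body_weight_g = spec$body_weight_g,
                 injected_activity_kBq = spec$injected_activity_kBq,
                 delay_min = spec$delay_min)
      vols[[i]] <- generate_tumor_volume(gp, tumor_seed[i])
    }
    volume_true <- 4 / 3 * pi * apply(semi, 1, prod)
    suv_true <- spec$pet_mean[group]
    zs <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) return(rep(0, length(x)))
      (x - mean(x)) / s
    }
    eta <- spec$rfs_coef[1] + spec$rfs_coef[2] * zs(suv_true) +
      spec$rfs_coef[3] * zs(log(volume_true))
    p_rec <- stats::plogis(eta)
    # degeneracy is judged on the coupling parameters, not the finite sample:
    # a tiny cohort may legitimately realize a single class
    if (spec$never_free_prob == 0 && (all(p_rec < 1e-8) || all(p_rec > 1 - 1e-8))) {
      abort("degenerate outcome coupling: recurrence probabilities are all 0 or all 1.")
    }
    p_high_grade <- spec$grade_coupling[, 3]
    if (all(p_high_grade < 1e-8) || all(p_high_grade > 1 - 1e-8)) {
      abort("degenerate outcome coupling: dichotomized grade would have one class.")
    }
    never_free <- rbinom(n, 1, spec$never_free_prob) == 1
    recur <- !never_free & rbinom(n, 1, p_rec) == 1
    rec_years <- rep(NA_real_, n)
    if (any(recur)) {
      rec_years[recur] <- pmin(stats::rexp(sum(recur), rate = 1 / 2.5) + 0.2, 8)
    }
    status <- ifelse(never_free, "never disease free",
                     ifelse(recur, "recur", "no recurrence"))
    grade <- vapply(group, function(g) {
      sample.int(3L, 1L, prob = spec$grade_coupling[g, ])
    }, integer(1))
    subtype <- vapply(group, function(g) {
      sample(subtypes, 1L, prob = spec$subtype_coupling[g, ])
    }, character(1))
    vol_ter <- pmax(1L, ceiling(3 * rank(volume_true, ties.method = "first") / n))
    stage_tab <- rbind(c(0.5, 0.35, 0.15), c(0.25, 0.5, 0.25), c(0.15, 0.35, 0.5))
    t_stage <- vapply(vol_ter, function(v) {
      sample(0:2, 1L, prob = stage_tab[v, ])
    }, integer(1))
    n_stage <- vapply(vol_ter, function(v) {
      sample(0:2, 1L, prob = stage_tab[v, ])
    }, integer(1))
    overall_stage <- pmin(t_stage + n_stage, 3L)
    histology <- sample(c("IDC", "ILC", "DCIS/LCIS", "mixed"), n, replace = TRUE,
                        prob = c(0.88, 0.05, 0.045, 0.025))
    site <- ifelse(status != "recur", "no recurrence",
                   ifelse(runif(n) < 0.15, "local", "distant"))
    rfs <- function(y) {
      ifelse(status == "never disease free", 0L,
             ifelse(status == "no recurrence", 1L,
                    as.integer(rec_years > y)))
    }
    clinical <- tibble(
      tumor_id = ids, grade = grade, histology = histology,
      t_stage = t_stage, n_stage = n_stage, overall_stage = overall_stage,
      subtype = subtype, recurrence_status = status, recurrence_site = site,
      recurrence_years = rec_years,
      rfs_free_at_1 = rfs(1), rfs_free_at_2 = rfs(2), rfs_free_at_3 = rfs(3),
      rfs_free_at_4 = rfs(4), rfs_free_at_5 = rfs(5)
    )
    truth <- tibble(
      tumor_id = ids, group = group, suv_mean_true = suv_true,
      mr_mean_true = spec$mr_mean[group], corr_len = spec$corr_len[group],
      volume_true = volume_true, eta = as.numeric(eta),
      tumor_seed = tumor_seed
    )
    manifest <- tibble(
      tumor_id = ids,
      pet = purrr::map(vols, "pet"), pet_mask = purrr::map(vols, "pet_mask"),
      mr = purrr::map(vols, "mr"), mr_mask = purrr::map(vols, "mr_mask"),
      body_weight_g = spec$body_weight_g,
      injected_activity_kBq = spec$injected_activity_kBq,
      delay_min = spec$delay_min
    )
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- purrr::map_dfr(seq_len(n), function(i) {
      base <- file.path(dir, manifest$tumor_id[i])
      tibble(
        pet_path = write_nifti(manifest$pet[[i]], paste0(base, "_pet.nii.gz")),
        pet_mask_path = write_nifti(manifest$pet_mask[[i]],
                                    paste0(base, "_pet_mask.nii.gz")),
        mr_path = write_nifti(manifest$mr[[i]], paste0(base, "_mr.nii.gz")),
        mr_mask_path = write_nifti(manifest$mr_mask[[i]],
                                   paste0(base, "_mr_mask.nii.gz"))
      )
    })
    manifest <- bind_cols(
      manifest[, c("tumor_id", "body_weight_g", "injected_activity_kBq",
                   "delay_min")],
      paths
    )
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  }
  list(manifest = manifest, clinical = clinical, truth = truth)
}
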