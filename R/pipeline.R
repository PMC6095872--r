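#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the preprocess -> extract -> cluster -> associate ->
#' classify pipeline in one validated list. `manifest` and `clinical` may be
#' tibbles or CSV paths; referenced files are checked before any compute.
#'
#' @param manifest Cohort manifest tibble or CSV path (see
#'   [extract_cohort_features()]).
#' @param clinical Clinical outcomes tibble or CSV path.
#' @param out_dir Optional output directory for artifact files.
#' @param pet_spacing,mr_spacing,pet_bin_width,mr_bin_width,surface_method
#'   Preprocessing and feature-extraction settings.
#' @param algorithms,dissimilarities Consensus-clustering menu to run.
#' @param k_range,n_iter,subsample_frac Consensus settings.
#' @param select_outcome Clinical variable used to pick the best clustering
#'   run by Cramer's V.
#' @param ordinal_outcomes,categorical_outcomes Clinical columns for the
#'   Spearman and variance-explained feature associations.
#' @param cv_tasks Classification tasks: `"grade"` and/or `"rfs<year>"`.
#' @param classifier A [classifier_spec()] for the CV stage.
#' @param reps,outer_folds,inner_folds Nested-CV settings.
#' @param seed Master seed (consensus and CV seeds derive from it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, clinical, out_dir = NULL,
                            pet_spacing = 2.0, mr_spacing = 0.5,
                            pet_bin_width = 0.1, mr_bin_width = 5.0,
                            surface_method = "mesh",
                            algorithms = c("HC", "PAM"),
                            dissimilarities = c("pearson", "spearman", "euclidean"),
                            k_range = 2:6, n_iter = 10000, subsample_frac = 0.8,
                            select_outcome = "grade",
                            ordinal_outcomes = c("grade", "t_stage", "n_stage",
                                                 "overall_stage"),
                            categorical_outcomes = c("subtype",
                                                     "recurrence_status"),
                            cv_tasks = c("grade", "rfs1"),
                            classifier = classifier_spec("logistic", "ElasticNet"),
                            reps = 1000, outer_folds = 3, inner_folds = 3,
                            seed = 1L) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) abort(sprintf("manifest file '%s' not found.", manifest))
    manifest <- as_tibble(read.csv(manifest, check.names = FALSE))
  }
  if (is.character(clinical)) {
    if (!file.exists(clinical)) abort(sprintf("clinical file '%s' not found.", clinical))
    clinical <- as_tibble(read.csv(clinical, check.names = FALSE))
  }
  path_cols <- intersect(c("pet_path", "pet_mask_path", "mr_path", "mr_mask_path"),
                         names(manifest))
  for (pc in path_cols) {
    gone <- !file.exists(manifest[[pc]]) & !is.na(manifest[[pc]])
    if (any(gone)) {
      abort(sprintf("missing %s files for tumors: %s", pc,
                    paste(manifest$tumor_id[gone], collapse = ", ")))
    }
  }
  structure(
    list(manifest = manifest, clinical = clinical, out_dir = out_dir,
         pet_spacing = pet_spacing, mr_spacing = mr_spacing,
         pet_bin_width = pet_bin_width, mr_bin_width = mr_bin_width,
         surface_method = surface_method, algorithms = algorithms,
         dissimilarities = dissimilarities, k_range = k_range,
         n_iter = n_iter, subsample_frac = subsample_frac,
         select_outcome = select_outcome, ordinal_outcomes = ordinal_outcomes,
         categorical_outcomes = categorical_outcomes, cv_tasks = cv_tasks,
         classifier = classifier, reps = reps, outer_folds = outer_folds,
         inner_folds = inner_folds, seed = seed),
    class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  inform(sprintf("[%s] done in %.1fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full radiomics pipeline
#'
#' Executes preprocess+extract, z-scoring, consensus clustering over the
#' configured algorithm x dissimilarity menu (with CDF-area cluster-number
#' selection and Cramer's-V algorithm selection), feature--outcome association
#' statistics, and repeated nested cross-validated classification, returning
#' one report object and optionally writing the artifact files.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `features`, `consensus` (summary tibble +
#'   selected run), `associations`, `classification`, and `settings`;
#'   written to `out_dir` as CSV/JSON when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  features <- stage("extract", extract_cohort_features(
    cf$manifest, pet_spacing = cf$pet_spacing, mr_spacing = cf$mr_spacing,
    pet_bin_width = cf$pet_bin_width, mr_bin_width = cf$mr_bin_width,
    surface_method = cf$surface_method))
  scaled <- zscore_table(features)
  clinical <- cf$clinical[match(features$tumor_id, cf$clinical$tumor_id), ]

  menu <- tidyr::expand_grid(algorithm = cf$algorithms,
                             dissimilarity = cf$dissimilarities) %>%
    filter(!(.data$algorithm == "KM" & .data$dissimilarity != "euclidean"))
  runs <- stage("cluster", purrr::pmap(menu, function(algorithm, dissimilarity) {
    run_consensus(scaled, algorithm = algorithm, dissimilarity = dissimilarity,
                  k_range = cf$k_range, n_iter = cf$n_iter,
                  subsample_frac = cf$subsample_frac, seed = cf$seed)
  }))
  best <- select_best_algorithm(runs, clinical[[cf$select_outcome]])
  k_sel <- select_num_clusters(best$run)
  labels <- best$run$labels[[as.character(k_sel)]]

  associations <- stage("associate", {
    cluster_assoc <- purrr::map_dfr(
      c(cf$ordinal_outcomes, cf$categorical_outcomes), function(oc) {
        res <- tryCatch(cramers_v_test(labels, clinical[[oc]]),
                        error = function(e) tibble(chi2 = NA_real_, p = NA_real_,
                                                   dof = NA_integer_,
                                                   cramers_v = NA_real_, n = NA_integer_))
        mutate(res, outcome = oc, .before = 1)
      })
    rho <- purrr::map_dfr(cf$ordinal_outcomes, function(oc) {
      mutate(spearman_assoc(scaled, clinical[[oc]]), outcome = oc, .before = 1)
    })
    r2 <- purrr::map_dfr(cf$categorical_outcomes, function(oc) {
      mutate(anova_r2_assoc(scaled, clinical[[oc]]), outcome = oc, .before = 1)
    })
    list(cluster = cluster_assoc, spearman = rho, r2_mreg = r2)
  })

  classification <- stage("classify", purrr::map(cf$cv_tasks, function(task) {
    if (task == "grade") {
      lab <- dichotomize_outcomes(clinical, "grade")
    } else {
      yr <- as.integer(sub("^rfs", "", task))
      lab <- dichotomize_outcomes(clinical, "rfs", cutoff_years = yr)
    }
    X <- features[match(lab$tumor_id, features$tumor_id), ]
    res <- nested_cv_auc(X, lab$label, cf$classifier,
                         outer_folds = cf$outer_folds,
                         inner_folds = cf$inner_folds,
                         reps = cf$reps, seed = cf$seed)
    list(task = task, result = res)
  }))

  report <- list(
    features = features,
    consensus = list(summary = best$summary, selected_k = k_sel,
                     labels = tibble(tumor_id = features$tumor_id,
                                     cluster = as.integer(labels)),
                     best_algorithm = best$run$algorithm,
                     best_dissimilarity = best$run$dissimilarity,
                     median_cc = median_cluster_consensus(best$run, k_sel),
                     cramers_v = best$cramers_v,
                     runs = runs),
    associations = associations,
    classification = setNames(classification, cf$cv_tasks),
    settings = list(seed = cf$seed, pet_spacing = cf$pet_spacing,
                    mr_spacing = cf$mr_spacing, pet_bin_width = cf$pet_bin_width,
                    mr_bin_width = cf$mr_bin_width,
                    surface_method = cf$surface_method, n_iter = cf$n_iter,
                    subsample_frac = cf$subsample_frac, reps = cf$reps,
                    classifier = cf$classifier$id,
                    version = as.character(utils::packageVersion("radiomix")))
  )
  if (!is.null(cf$out_dir)) {
    dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(cf$out_dir, "features.csv"), row.names = FALSE)
    write.csv(report$consensus$labels, file.path(cf$out_dir, "cluster_labels.csv"),
              row.names = FALSE)
    write.csv(report$consensus$summary, file.path(cf$out_dir, "cluster_summary.csv"),
              row.names = FALSE)
    write.csv(associations$cluster, file.path(cf$out_dir, "cluster_associations.csv"),
              row.names = FALSE)
    write.csv(associations$spearman, file.path(cf$out_dir, "spearman.csv"),
              row.names = FALSE)
    write.csv(associations$r2_mreg, file.path(cf$out_dir, "r2_mreg.csv"),
              row.names = FALSE)
    cv_json <- lapply(report$classification, function(cl) {
      list(task = cl$task, classifier = cl$result$classifier_id,
           mean_auc = cl$result$mean_auc, ci95 = cl$result$ci95,
           max_cv_count = cl$result$max_cv_count,
           top_features = cl$result$top_features)
    })
    jsonlite::write_json(
      list(settings = report$settings,
           consensus = list(selected_k = k_sel,
                            median_cc = report$consensus$median_cc,
                            cramers_v = report$consensus$cramers_v),
           classification = cv_json),
      file.path(cf$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}
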