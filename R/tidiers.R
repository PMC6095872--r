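#' Tidy a consensus run
#'
#' One row per candidate cluster number with the CDF area `A`, its relative
#' change `delta`, and the median cluster consensus at that `k`.
#'
#' @param x A `consensus_run`.
#' @param ... Unused.
#' @return A tibble `k`, `A`, `delta`, `median_cc`.
#' @method tidy consensus_run
#' @export
tidy.consensus_run <- function(x, ...) {
  tibble(k = x$k_range, A = as.numeric(x$A), delta = x$delta,
         median_cc = vapply(as.character(x$k_range),
                            function(key) median(x$cluster_consensus[[key]]),
                            numeric(1)))
}

#' @rdname tidy.consensus_run
#' @method glance consensus_run
#' @export
glance.consensus_run <- function(x, ...) {
  k <- select_num_clusters(x)
  tibble(algorithm = x$algorithm, dissimilarity = x$dissimilarity,
         selected_k = k, median_cc = median_cluster_consensus(x, k),
         n_iter = x$n_iter, subsample_frac = x$subsample_frac, seed = x$seed)
}

#' @rdname tidy.consensus_run
#' @param object A `consensus_run`.
#' @method autoplot consensus_run
#' @export
autoplot.consensus_run <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("A", "delta"), names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = select_num_clusters(object),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(A = "consensus CDF area A(k)",
                            delta = "relative change Δ(k)"))) +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = sprintf("Consensus clustering (%s / %s)",
                                  object$algorithm, object$dissimilarity))
}

#' Tidy a nested cross-validation result
#'
#' @param x A `nested_cv_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-repetition, per-outer-fold AUC tibble.
#'   `glance()`: a one-row summary with the bootstrap mean and CI.
#' @method tidy nested_cv_result
#' @export
tidy.nested_cv_result <- function(x, ...) x$aucs

#' @rdname tidy.nested_cv_result
#' @method glance nested_cv_result
#' @export
glance.nested_cv_result <- function(x, ...) {
  tibble(classifier = x$classifier_id, mean_auc = x$mean_auc,
         ci_lo = x$ci95[1], ci_hi = x$ci95[2],
         n_fits = x$max_cv_count, reps = x$reps,
         outer_folds = x$outer_folds, seed = x$seed)
}

#' @rdname tidy.nested_cv_result
#' @param object A `nested_cv_result`.
#' @method autoplot nested_cv_result
#' @export
autoplot.nested_cv_result <- function(object, ...) {
  ggplot2::ggplot(object$aucs, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_auc, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ci95, linetype = "dotted") +
    ggplot2::labs(x = "outer-fold AUC", y = "count",
                  title = sprintf("%s: mean AUC %.2f (95%% CI %.2f-%.2f)",
                                  object$classifier_id, object$mean_auc,
                                  object$ci95[1], object$ci95[2]))
}

#' Plot feature-importance tallies
#'
#' Horizontal bar chart of the proportion of CV fits in which each of the top
#' features carried weight.
#'
#' @param result A `nested_cv_result` from a logistic classifier.
#' @param top_n Number of features to show (default 10).
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(result, top_n = 10L) {
  stopifnot(inherits(result, "nested_cv_result"))
  if (is.null(result$tallies)) {
    abort(paste0("no coefficient tallies for '", result$classifier_id,
                 "'; importance counting needs a logistic (coefficient) model."))
  }
  d <- head(result$tallies, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion,
                                  y = stats::reorder(.data$feature,
                                                     .data$proportion))) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = sprintf("selected in %% of %d CV fits", result$max_cv_count),
                  y = NULL, title = result$classifier_id)
}
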