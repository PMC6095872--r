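#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks of the scores (equivalent
#' to the Mann-Whitney statistic), so ties are handled by the trapezoidal
#' convention.
#'
#' @param score Numeric scores, higher = more class-1-like.
#' @param y Binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC needs both classes present.")
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier specification for nested cross-validation
#'
#' Describes one entry of the classifier menu: regularized logistic
#' regression (L1, L2 or ElasticNet via glmnet), an RBF support vector
#' machine, or a random forest. The logistic hyperparameter grid is the
#' inverse-regularization strength `cost` (mapped to the glmnet penalty as
#' `lambda = 1 / (n * cost)`) crossed with the ElasticNet `mixing` ratio.
#'
#' @param family `"logistic"`, `"svm"` or `"random_forest"`.
#' @param regularization For logistic: `"ElasticNet"`, `"L1"` or `"L2"`.
#' @param cost Inverse-regularization grid (logistic / SVM).
#' @param mixing ElasticNet mixing-ratio grid (ignored for L1/L2).
#' @param ntree Random-forest tree count.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("logistic", "svm", "random_forest"),
                            regularization = c("ElasticNet", "L1", "L2"),
                            cost = c(0.01, 0.1, 1, 10),
                            mixing = c(0.2, 0.5, 0.8),
                            ntree = 100L) {
  family <- match.arg(family)
  regularization <- if (family == "logistic") match.arg(regularization) else "none"
  alpha <- switch(regularization,
                  ElasticNet = sort(mixing), L1 = 1, L2 = 0, none = NA_real_)
  grid <- switch(family,
    logistic = tidyr::expand_grid(alpha = alpha, cost = sort(cost, decreasing = FALSE)),
    svm = tibble(cost = sort(cost)),
    random_forest = tibble(ntree = as.integer(ntree))
  )
  if (nrow(grid) == 0L) abort("hyperparameter grid must be non-empty.")
  id <- switch(family,
               logistic = paste0(tolower(regularization), "_logreg"),
               svm = "svm_rbf",
               random_forest = "random_forest")
  structure(list(id = id, family = family, regularization = regularization,
                 grid = grid, ntree = as.integer(ntree)),
            class = "classifier_spec")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

## scale columns by train-fold mean / population SD (constant columns pass)
fold_scaler <- function(xtr) {
  mu <- colMeans(xtr)
  s <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, s = s,
       apply = function(x) sweep(sweep(x, 2, mu), 2, s, `/`))
}

fit_logistic <- function(x, y, alpha, lambdas) {
  glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                 alpha = alpha, lambda = sort(lambdas, decreasing = TRUE),
                 standardize = FALSE)
}

svm_score <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the decision value toward the first class in the colname
  if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
}

## inner-CV hyperparameter selection by mean AUC; ties resolve to the
## strongest penalty (grid rows are ordered weakest-cost-last)
inner_select <- function(spec, x, y, inner_folds) {
  k <- min(inner_folds, min(table(y)))
  if (k < 2L) k <- 2L
  fold <- stratified_folds(y, k)
  if (spec$family == "logistic") {
    alphas <- unique(spec$grid$alpha)
    costs <- sort(unique(spec$grid$cost))
    lambdas <- 1 / (nrow(x) * costs) # strongest penalty = smallest cost
    auc_acc <- matrix(0, length(alphas), length(lambdas))
    cnt <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      cnt <- cnt + 1L
      for (ai in seq_along(alphas)) {
        fit <- fit_logistic(x[tr, , drop = FALSE], y[tr], alphas[ai], lambdas)
        pr <- predict(fit, x[!tr, , drop = FALSE],
                      s = sort(lambdas, decreasing = TRUE), type = "response")
        for (li in seq_along(lambdas)) {
          lam <- sort(lambdas, decreasing = TRUE)[li]
          a <- auc_midrank(pr[, li], y[!tr])
          auc_acc[ai, match(lam, lambdas)] <- auc_acc[ai, match(lam, lambdas)] + a
        }
      }
    }
    if (cnt == 0L) return(list(alpha = alphas[1], lambda = max(lambdas)))
    mean_auc <- auc_acc / cnt
    # iterate lambdas descending (strong penalty first) so ties keep parsimony
    ord <- order(lambdas, decreasing = TRUE)
    best <- c(1L, ord[1L]); best_auc <- -Inf
    for (li in ord) for (ai in seq_along(alphas)) {
      if (mean_auc[ai, li] > best_auc + 1e-12) {
        best_auc <- mean_auc[ai, li]; best <- c(ai, li)
      }
    }
    list(alpha = alphas[best[1]], lambda = lambdas[best[2]])
  } else if (spec$family == "svm") {
    costs <- sort(unique(spec$grid$cost)) # small cost = stronger penalty
    aucs <- numeric(length(costs)); cnt <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      cnt <- cnt + 1L
      for (ci in seq_along(costs)) {
        fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                          kernel = "radial", cost = costs[ci], scale = FALSE)
        aucs[ci] <- aucs[ci] + auc_midrank(svm_score(fit, x[!tr, , drop = FALSE]),
                                           y[!tr])
      }
    }
    list(cost = costs[which.max(aucs)])
  } else {
    list(ntree = spec$ntree)
  }
}

fit_final <- function(spec, x, y, params) {
  if (spec$family == "logistic") {
    costs <- sort(unique(spec$grid$cost))
    lambdas <- 1 / (nrow(x) * costs)
    if (!params$lambda %in% lambdas) lambdas <- sort(c(lambdas, params$lambda))
    fit <- fit_logistic(x, y, params$alpha, lambdas)
    co <- as.numeric(predict(fit, s = params$lambda, type = "coefficients"))[-1]
    names(co) <- colnames(x)
    list(score = function(newx) as.numeric(predict(fit, newx, s = params$lambda,
                                                   type = "response")),
         coefficients = co)
  } else if (spec$family == "svm") {
    fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                      cost = params$cost, scale = FALSE)
    list(score = function(newx) svm_score(fit, newx), coefficients = NULL)
  } else {
    fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                      ntree = params$ntree)
    list(score = function(newx) predict(fit, newx, type = "prob")[, "1"],
         coefficients = NULL)
  }
}

#' Repeated stratified nested cross-validated AUC
#'
#' For each repetition the data are split into `outer_folds` stratified
#' folds; per outer-train fold the features are z-scaled with that fold's own
#' statistics, the hyperparameters are chosen by `inner_folds`-fold inner CV
#' on mean AUC, the winning model is refit on the outer-train fold and scored
#' by AUC on the held-out fold. All `reps * outer_folds` AUCs are kept, the
#' bootstrap mean/CI is computed over them, and (for logistic families) each
#' outer fit contributes to the per-feature coefficient tally: a feature
#' counts as selected when its coefficient is nonzero (L1/ElasticNet) or has
#' absolute value above 0.01 (L2).
#'
#' @param features Tibble or matrix of predictors (non-numeric columns such
#'   as `tumor_id` are dropped).
#' @param labels Binary outcome (0/1), both classes present with at least
#'   `outer_folds` members each.
#' @param spec A [classifier_spec()].
#' @param outer_folds,inner_folds Fold counts (default 3 and 3).
#' @param reps Number of repetitions (default 1000, making the tally
#'   denominator 1000 x 3 folds = 3000 fits).
#' @param seed Integer seed; results are reproducible from it.
#' @param n_boot Bootstrap resamples for the AUC confidence interval.
#' @return A `nested_cv_result`: tibble of per-fold AUCs, `mean_auc`, `ci95`,
#'   per-feature `tallies`, `max_cv_count`, and `top_features`.
#' @export
nested_cv_auc <- function(features, labels, spec, outer_folds = 3L,
                          inner_folds = 3L, reps = 1000L, seed = 1L,
                          n_boot = 1000L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(features[vapply(features, is.numeric, logical(1))])
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (min(table(y)) < outer_folds) {
    abort("each class needs at least `outer_folds` members.")
  }
  p <- ncol(X)
  sel_counts <- setNames(numeric(p), colnames(X))
  logistic <- spec$family == "logistic"
  thr <- if (spec$regularization == "L2") 0.01 else 0
  rows <- vector("list", reps * outer_folds)
  ri <- 0L
  withr::with_seed(seed, {
    for (rep_i in seq_len(reps)) {
      fold <- stratified_folds(y, outer_folds)
      tries <- 0L
      while (any(vapply(seq_len(outer_folds), function(f) {
        length(unique(y[fold == f])) < 2L || length(unique(y[fold != f])) < 2L
      }, logical(1))) && tries < 20L) {
        warn("a fold missed a class; reshuffling this repetition.")
        fold <- stratified_folds(y, outer_folds)
        tries <- tries + 1L
      }
      for (f in seq_len(outer_folds)) {
        tr <- fold != f
        scaler <- fold_scaler(X[tr, , drop = FALSE])
        xtr <- scaler$apply(X[tr, , drop = FALSE])
        xte <- scaler$apply(X[!tr, , drop = FALSE])
        params <- inner_select(spec, xtr, y[tr], inner_folds)
        fit <- fit_final(spec, xtr, y[tr], params)
        a <- auc_midrank(fit$score(xte), y[!tr])
        if (logistic) {
          sel_counts <- sel_counts + (abs(fit$coefficients) > thr)
        }
        ri <- ri + 1L
        rows[[ri]] <- tibble(rep = rep_i, fold = f, auc = a)
      }
    }
  })
  aucs <- bind_rows(rows)
  boot <- bootstrap_summary(aucs$auc, n_boot = n_boot, seed = seed)
  max_cv <- reps * outer_folds
  tallies <- if (logistic) {
    tibble(feature = names(sel_counts), count = as.integer(sel_counts),
           proportion = as.numeric(sel_counts) / max_cv) %>%
      arrange(desc(.data$proportion), .data$feature)
  } else NULL
  structure(list(classifier_id = spec$id, spec = spec, aucs = aucs,
                 mean_auc = boot$mean, ci95 = c(boot$lo, boot$hi),
                 tallies = tallies, max_cv_count = max_cv,
                 top_features = if (!is.null(tallies)) head(tallies, 10L),
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 reps = reps, seed = seed),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %s: mean AUC %.3f (95%% CI %.3f-%.3f) over %d fits\n",
              x$classifier_id, x$mean_auc, x$ci95[1], x$ci95[2], x$max_cv_count))
  if (!is.null(x$top_features)) {
    cat("  top features:",
        paste(sprintf("%s (%.0f%%)", head(x$top_features$feature, 3),
                      100 * head(x$top_features$proportion, 3)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bootstrap mean and percentile confidence interval of an AUC list
#'
#' @param aucs Numeric vector of outer-fold AUC values (length >= 2).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `lo`, `hi`.
#' @export
bootstrap_summary <- function(aucs, n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(length(aucs) >= 2L)
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(aucs, replace = TRUE)), numeric(1))
  })
  qs <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble(mean = mean(aucs), lo = qs[1], hi = qs[2])
}

#' Tally how often features carried weight across CV fits
#'
#' Counts, over a matrix of fitted coefficients (one row per outer-fold fit),
#' how many fits gave each feature a coefficient passing the selection rule:
#' nonzero for L1/ElasticNet fits, `|coef| > 0.01` for L2. The proportion is
#' relative to `max_cv_count` and the top 10 features are ranked by it, ties
#' broken alphabetically.
#'
#' @param coefs Numeric matrix, fits x features, with column names.
#' @param regularization `"ElasticNet"`, `"L1"` or `"L2"`.
#' @param max_cv_count Denominator (defaults to `nrow(coefs)`).
#' @return A tibble `feature`, `count`, `proportion`, ranked.
#' @export
tally_feature_importance <- function(coefs,
                                     regularization = c("ElasticNet", "L1", "L2"),
                                     max_cv_count = nrow(coefs)) {
  regularization <- match.arg(regularization)
  if (is.null(colnames(coefs))) abort("`coefs` needs column names.")
  thr <- if (regularization == "L2") 0.01 else 0
  counts <- colSums(abs(coefs) > thr)
  tibble(feature = colnames(coefs), count = as.integer(counts),
         proportion = as.numeric(counts) / max_cv_count) %>%
    arrange(desc(.data$proportion), .data$feature)
}

#' Dichotomize clinical outcomes for classification
#'
#' Grade task: grades 1-2 are labeled 0, grades 3-4 are labeled 1. RFS task:
#' patients recurrence-free beyond the cutoff are labeled 1, everyone else
#' (recurrence at or before the cutoff, or never disease free) 0. When the
#' table carries `recurrence_status` / `recurrence_years` those are used;
#' otherwise a precomputed `rfs_free_at_<cutoff>` column is accepted. Rows
#' with a missing outcome are excluded and counted in a message.
#'
#' @param clinical Clinical tibble with `tumor_id`.
#' @param task `"grade"` or `"rfs"`.
#' @param cutoff_years RFS cutoff in 1..5 (required for `task = "rfs"`).
#' @return A tibble `tumor_id`, `label` (0/1).
#' @export
dichotomize_outcomes <- function(clinical, task = c("grade", "rfs"),
                                 cutoff_years = NULL) {
  task <- match.arg(task)
  if (task == "grade") {
    g <- clinical$grade
    if (!all(is.na(g) | g %in% 1:4)) abort("grade must be in 1..4.")
    lab <- ifelse(g >= 3, 1L, 0L)
  } else {
    if (is.null(cutoff_years) || !cutoff_years %in% 1:5) {
      abort("`cutoff_years` must be one of 1..5 for the RFS task.")
    }
    if (all(c("recurrence_status", "recurrence_years") %in% names(clinical))) {
      st <- clinical$recurrence_status
      yrs <- clinical$recurrence_years
      lab <- ifelse(is.na(st), NA_integer_,
             ifelse(st == "never disease free", 0L,
             ifelse(st == "no recurrence", 1L,
                    as.integer(!is.na(yrs) & yrs > cutoff_years))))
    } else {
      col <- paste0("rfs_free_at_", cutoff_years)
      if (!col %in% names(clinical)) {
        abort(sprintf("clinical table has neither recurrence columns nor '%s'.", col))
      }
      lab <- as.integer(clinical[[col]])
    }
  }
  excluded <- sum(is.na(lab))
  if (excluded > 0L) {
    inform(sprintf("%d rows excluded for missing outcome.", excluded))
  }
  tibble(tumor_id = clinical$tumor_id, label = lab) %>%
    filter(!is.na(.data$label))
}
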