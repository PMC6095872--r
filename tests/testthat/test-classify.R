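test_that("outcome dichotomization follows the cutoff and grade rules", {
  clin <- tibble::tibble(
    tumor_id = c("A", "B", "C", "D"),
    grade = c(1L, 2L, 3L, NA),
    recurrence_status = c("recur", "no recurrence", "never disease free", "recur"),
    recurrence_years = c(1.5, NA, NA, 3.2))
  rfs1 <- dichotomize_outcomes(clin, "rfs", cutoff_years = 1)
  expect_equal(rfs1$label[rfs1$tumor_id == "A"], 1L) # recurred after the cutoff
  rfs2 <- dichotomize_outcomes(clin, "rfs", cutoff_years = 2)
  expect_equal(rfs2$label[rfs2$tumor_id == "A"], 0L)
  expect_equal(rfs2$label[rfs2$tumor_id == "B"], 1L)
  expect_equal(rfs2$label[rfs2$tumor_id == "C"], 0L) # never disease free
  expect_message(g <- dichotomize_outcomes(clin, "grade"), "1 rows excluded")
  expect_equal(g$label, c(0L, 0L, 1L)) # grades 1-2 -> 0, grade 3 -> 1
  # precomputed column fallback
  clin2 <- tibble::tibble(tumor_id = c("A", "B"), rfs_free_at_3 = c(1L, 0L))
  expect_equal(dichotomize_outcomes(clin2, "rfs", 3)$label, c(1L, 0L))
})

test_that("midrank AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  for (seed in 1:6) {
    withr::with_seed(seed, {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- 0:1
      s <- rnorm(40) + 0.8 * y
      s[sample(40, 5)] <- s[sample(40, 5)] # leave ties possible
    })
    expect_equal(auc_midrank(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("bootstrap summaries behave at the degenerate limits", {
  const <- bootstrap_summary(c(0.7, 0.7, 0.7), seed = 1)
  expect_equal(const$mean, 0.7)
  expect_equal(const$lo, 0.7)
  expect_equal(const$hi, 0.7)
  two <- bootstrap_summary(c(0, 1), seed = 2)
  expect_equal(two$mean, 0.5)
  expect_gte(two$lo, 0)
  expect_lte(two$hi, 1)
})

test_that("the bootstrap CI covers a known mean at the nominal rate", {
  hits <- 0L
  runs <- 60L
  withr::with_seed(99, {
    for (i in seq_len(runs)) {
      draws <- rbeta(200, 7, 3) # true mean 0.7
      ci <- bootstrap_summary(draws, n_boot = 400, seed = i)
      if (ci$lo <= 0.7 && 0.7 <= ci$hi) hits <- hits + 1L
    }
  })
  expect_gte(hits / runs, 0.85)
})

test_that("nested CV keeps every fold, stratifies, and is seeded", {
  d <- null_table(n = 48, p = 6, seed = 3)
  spec <- classifier_spec("logistic", "L2", cost = c(0.1, 1))
  res <- nested_cv_auc(d$X, d$y, spec, reps = 4, seed = 5)
  expect_equal(nrow(res$aucs), 4 * 3)
  expect_equal(res$max_cv_count, 12)
  expect_true(all(res$aucs$auc >= 0 & res$aucs$auc <= 1))
  expect_true(all(res$tallies$count <= res$max_cv_count))
  res2 <- nested_cv_auc(d$X, d$y, spec, reps = 4, seed = 5)
  expect_identical(res$aucs, res2$aucs)
  expect_identical(res$tallies, res2$tallies)
})

test_that("outer folds preserve class proportions to within one item", {
  withr::with_seed(17, {
    y <- c(rep(1L, 30), rep(0L, 60))[sample(90)]
    fold <- radiomix:::stratified_folds(y, 3)
  })
  for (f in 1:3) {
    expect_lte(abs(sum(y[fold == f]) - 10), 1)
    expect_lte(abs(sum(fold == f) - 30), 1)
  }
})

test_that("a feature identical to the label is found and dominates", {
  d <- null_table(n = 60, p = 8, seed = 7)
  X <- d$X
  X$signal <- d$y + withr::with_seed(8, rnorm(60, 0, 0.01))
  spec <- classifier_spec("logistic", "ElasticNet", cost = c(0.1, 1))
  res <- suppressWarnings(nested_cv_auc(X, d$y, spec, reps = 3, seed = 9))
  expect_gte(res$mean_auc, 0.99)
  expect_identical(res$top_features$feature[1], "signal")
  expect_equal(res$top_features$proportion[1], 1)
})

test_that("shuffling the labels destroys the AUC signal", {
  d <- null_table(n = 60, p = 8, seed = 11)
  X <- d$X
  X$signal <- d$y
  y_shuf <- withr::with_seed(12, sample(d$y))
  spec <- classifier_spec("logistic", "ElasticNet", cost = c(0.1, 1))
  res <- suppressWarnings(nested_cv_auc(X, y_shuf, spec, reps = 5, seed = 13))
  expect_lt(abs(res$mean_auc - 0.5), 0.1)
})

test_that("importance tallies follow the L1/ElasticNet and L2 rules", {
  co <- rbind(c(0.5, 0, 0.005), c(-0.2, 0, 0.005), c(0.1, 0, 0.5))
  colnames(co) <- c("always", "never", "small")
  en <- tally_feature_importance(co, "ElasticNet")
  expect_equal(en$proportion[en$feature == "always"], 1)
  expect_equal(en$proportion[en$feature == "never"], 0)
  expect_equal(en$proportion[en$feature == "small"], 1) # nonzero counts
  l2 <- tally_feature_importance(co, "L2")
  expect_equal(l2$proportion[l2$feature == "small"], 1 / 3) # |coef| > 0.01
  # ties rank alphabetically
  co2 <- cbind(b = c(1, 1), a = c(1, 1), c = c(0, 0))
  expect_equal(tally_feature_importance(co2, "L1")$feature, c("a", "b", "c"))
})

test_that("SVM and random-forest menu entries run without coefficient tallies", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  d <- null_table(n = 36, p = 4, seed = 15)
  X <- d$X
  X$signal <- d$y + withr::with_seed(16, rnorm(36, 0, 0.05))
  svm_res <- nested_cv_auc(X, d$y, classifier_spec("svm", cost = c(1, 10)),
                           reps = 2, seed = 17)
  expect_gte(svm_res$mean_auc, 0.9)
  expect_null(svm_res$tallies)
  rf_res <- nested_cv_auc(X, d$y, classifier_spec("random_forest", ntree = 50),
                          reps = 2, seed = 18)
  expect_gte(rf_res$mean_auc, 0.9)
  expect_null(rf_res$tallies)
  expect_error(plot_feature_importance(rf_res), "coefficient")
})
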