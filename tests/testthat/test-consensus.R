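# well-separated blobs in feature space for recovery checks
blob_features <- function(n_per, centers, sd = 0.5, p = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(centers), function(g) {
      matrix(rnorm(n_per * p, mean = centers[g], sd = sd), n_per, p)
    }))
  })
  tibble::as_tibble(as.data.frame(X)) |>
    dplyr::mutate(tumor_id = sprintf("s%02d", dplyr::row_number()), .before = 1)
}

test_that("two well-separated blobs reach within-blob consensus near 1", {
  f <- blob_features(20, centers = c(0, 10), seed = 2)
  run <- run_consensus(f, "HC", "euclidean", k_range = 2:3, n_iter = 100,
                       seed = 3)
  M2 <- run$M[["2"]]
  truth <- rep(1:2, each = 20)
  within <- M2[outer(truth, truth, `==`) & upper.tri(M2)]
  expect_true(all(within >= 0.99))
  between <- M2[outer(truth, truth, `!=`)]
  expect_true(all(between <= 0.01))
})

test_that("consensus matrices are symmetric with unit diagonal in [0,1]", {
  f <- blob_features(10, centers = c(0, 3, 6), seed = 4)
  run <- run_consensus(f, "PAM", "euclidean", k_range = 2:4, n_iter = 50,
                       seed = 5)
  for (M in run$M) {
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("a full-sample deterministic clusterer yields a binary consensus", {
  f <- blob_features(12, centers = c(0, 4), seed = 6)
  run <- run_consensus(f, "HC", "euclidean", k_range = 2:3, n_iter = 1,
                       subsample_frac = 1, seed = 7)
  M <- run$M[["2"]]
  expect_true(all(M %in% c(0, 1)))
  # entries match the single partition exactly
  cl <- cutree(hclust(dist(as.matrix(f[-1])), "ward.D2"), 2)
  expect_equal(M[upper.tri(M)],
               as.numeric(outer(cl, cl, `==`)[upper.tri(M)]))
})

test_that("the same seed reproduces an identical run", {
  f <- blob_features(10, centers = c(0, 2, 5), seed = 8)
  r1 <- run_consensus(f, "KMdist", "spearman", k_range = 2:4, n_iter = 60,
                      seed = 11)
  r2 <- run_consensus(f, "KMdist", "spearman", k_range = 2:4, n_iter = 60,
                      seed = 11)
  expect_identical(r1, r2)
})

test_that("cluster-number selection maximizes the relative CDF-area change", {
  # A = {2: 0.5, 3: 0.9, 4: 0.92} -> delta = {0.5, 0.8, 0.022} -> k = 3
  A <- c(0.5, 0.9, 0.92)
  delta <- c(A[1], (A[2] - A[1]) / A[1], (A[3] - A[2]) / A[2])
  fake <- structure(list(k_range = 2:4, A = A, delta = delta),
                    class = "consensus_run")
  expect_equal(select_num_clusters(fake), 3L)
  # ties go to the smaller k
  tie <- structure(list(k_range = 2:4, delta = c(0.4, 0.4, 0.1)),
                   class = "consensus_run")
  expect_equal(select_num_clusters(tie), 2L)
})

test_that("median cluster consensus summarizes within-cluster stability", {
  f <- blob_features(15, centers = c(0, 10), seed = 9)
  run <- run_consensus(f, "HC", "euclidean", k_range = 2:3, n_iter = 100,
                       seed = 10)
  expect_equal(median_cluster_consensus(run, 2), 1.0)
  # hand-built 3-cluster consensus with per-cluster means {0.9, 0.7, 0.8}
  labels <- rep(1:3, each = 2)
  M <- diag(6)
  for (cl in 1:3) {
    i <- which(labels == cl)
    M[i[1], i[2]] <- M[i[2], i[1]] <- c(0.9, 0.7, 0.8)[cl]
  }
  fake <- structure(list(k_range = 3L,
                         cluster_consensus = list("3" = c(0.9, 0.7, 0.8))),
                    class = "consensus_run")
  expect_equal(median_cluster_consensus(fake, 3), 0.8)
  # constant off-diagonal consensus c -> median CC = c
  Mc <- matrix(0.65, 8, 8); diag(Mc) <- 1
  fake2 <- structure(list(k_range = 2L, cluster_consensus = list(
    "2" = vapply(1:2, function(cl) {
      idx <- which(rep(1:2, each = 4) == cl)
      mean(Mc[idx, idx][upper.tri(Mc[idx, idx])])
    }, numeric(1)))), class = "consensus_run")
  expect_equal(median_cluster_consensus(fake2, 2), 0.65)
})

test_that("algorithm selection picks the run with the highest Cramer's V", {
  f <- blob_features(15, centers = c(0, 10), seed = 12)
  clinical <- rep(c("low", "high"), each = 15)
  good <- run_consensus(f, "HC", "euclidean", k_range = 2:3, n_iter = 50,
                        seed = 1)
  noisy <- run_consensus(f, "KM", "euclidean", k_range = 2:3, n_iter = 50,
                         seed = 2)
  # overwrite the noisy run's labels with an uninformative partition
  noisy$labels[["2"]] <- setNames(rep(1:2, 15), names(noisy$labels[["2"]]))
  noisy$delta <- c(1, 0) # force selected k = 2
  sel <- select_best_algorithm(list(noisy, good), clinical)
  expect_identical(sel$run$algorithm, "HC")
  expect_equal(sel$cramers_v, 1)
  # identical runs: ties break to the first
  sel2 <- select_best_algorithm(list(good, good), clinical)
  expect_identical(sel2$summary$algorithm[1], "HC")
  expect_equal(which.max(sel2$summary$cramers_v), 1L)
  expect_error(select_best_algorithm(list(good), rep("x", 30)), "two observed")
})

test_that("planted three-group structure is recovered across seeds", {
  hits <- 0L
  for (seed in 1:5) {
    f <- blob_features(30, centers = c(0, 4, 8), sd = 1, seed = seed)
    run <- run_consensus(f, "HC", "euclidean", k_range = 2:5, n_iter = 100,
                         seed = seed + 100)
    k <- select_num_clusters(run)
    ari <- label_agreement(run$labels[[as.character(k)]], rep(1:3, each = 30))
    if (k == 3L && ari >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("the adjusted Rand index matches the mclust oracle", {
  skip_if_not_installed("mclust")
  expect_equal(label_agreement(rep(1:3, 10), rep(1:3, 10)), 1)
  for (seed in 1:6) {
    withr::with_seed(seed, {
      a <- sample(1:4, 60, replace = TRUE)
      b <- sample(1:3, 60, replace = TRUE)
    })
    expect_equal(label_agreement(a, b), mclust::adjustedRandIndex(a, b))
  }
})
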