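## Consensus clustering: repeated clustering of subsampled items; the
## co-clustering frequency matrix measures partition stability, the area under
## its empirical CDF selects the cluster number, and the per-cluster mean
## consensus summarises cluster quality.

feature_matrix <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  X <- as.matrix(num)
  rn <- if ("tumor_id" %in% names(features)) features$tumor_id else seq_len(nrow(X))
  rownames(X) <- rn
  X
}

## item x item dissimilarity; correlation dissimilarities are computed across
## the feature vectors of item pairs, constant vectors guarded to correlation 0
dissimilarity_matrix <- function(X, dissimilarity) {
  switch(dissimilarity,
    euclidean = as.matrix(dist(X)),
    pearson = ,
    spearman = {
      cc <- suppressWarnings(cor(t(X), method = dissimilarity))
      cc[!is.finite(cc)] <- 0
      1 - cc
    },
    abort(sprintf("unknown dissimilarity '%s'", dissimilarity))
  )
}

cluster_subsample <- function(algorithm, X, D, idx, k) {
  switch(algorithm,
    HC = cutree(hclust(stats::as.dist(D[idx, idx]), method = "ward.D2"), k),
    KM = kmeans(X[idx, , drop = FALSE], centers = k, nstart = 1,
                iter.max = 30)$cluster,
    KMdist = kmeans(D[idx, idx, drop = FALSE], centers = k, nstart = 1,
                    iter.max = 30)$cluster,
    PAM = cluster::pam(stats::as.dist(D[idx, idx]), k = k,
                       do.swap = TRUE, cluster.only = TRUE),
    abort(sprintf("unknown algorithm '%s'", algorithm))
  )
}

## area under the empirical CDF of the upper-triangle consensus entries
consensus_cdf_area <- function(M) {
  xs <- sort(M[upper.tri(M)])
  m <- length(xs)
  sum(diff(c(xs, 1)) * seq_len(m) / m)
}

per_cluster_consensus <- function(M, labels) {
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(1)
    sub <- M[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' Consensus clustering of a feature table
#'
#' Repeatedly subsamples items without replacement, clusters each subsample
#' into `k` groups for every `k` in `k_range`, and accumulates how often each
#' item pair is clustered together relative to how often it was co-sampled.
#' Final per-`k` labels come from average-linkage hierarchical clustering of
#' `1 - M(k)`. The area `A(k)` under the empirical CDF of the consensus
#' entries and its relative change `delta(k)` support cluster-number
#' selection via [select_num_clusters()].
#'
#' @param features Tibble of (z-scored) features; numeric columns are used,
#'   `tumor_id` (if present) names the items.
#' @param algorithm `"HC"` (Ward hierarchical), `"KM"` (k-means on the data
#'   matrix; euclidean only), `"KMdist"` (k-means on the rows of the
#'   dissimilarity matrix) or `"PAM"` (partitioning around medoids).
#' @param dissimilarity `"pearson"`, `"spearman"` (both as 1 - correlation)
#'   or `"euclidean"`.
#' @param k_range Integer vector of cluster numbers, spanning at least 2.
#' @param n_iter Number of resampling iterations (default 10,000; a few
#'   hundred already stabilize well-separated cohorts).
#' @param subsample_frac Fraction of items drawn per iteration, in (0, 1].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `consensus_run` object: per-`k` consensus matrices `M`, CDF
#'   areas `A`, relative changes `delta`, labels, per-cluster consensus, and
#'   the run settings.
#' @export
run_consensus <- function(features,
                          algorithm = c("HC", "KM", "KMdist", "PAM"),
                          dissimilarity = c("pearson", "spearman", "euclidean"),
                          k_range = 2:6, n_iter = 10000, subsample_frac = 0.8,
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  dissimilarity <- match.arg(dissimilarity)
  if (algorithm == "KM" && dissimilarity != "euclidean") {
    abort("KM clusters the data matrix directly; use dissimilarity = \"euclidean\".")
  }
  if (n_iter < 1L) abort("`n_iter` must be >= 1.")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    abort("`subsample_frac` must be in (0, 1].")
  }
  k_range <- sort(unique(as.integer(k_range)))
  X <- feature_matrix(features)
  n <- nrow(X)
  if (any(k_range >= n)) abort("`k_range` must stay below the number of items.")
  D <- if (algorithm == "KM") NULL else dissimilarity_matrix(X, dissimilarity)
  m_sub <- max(2L, floor(subsample_frac * n))
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  samp <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sort(sample.int(n, m_sub))
      samp[idx, idx] <- samp[idx, idx] + 1
      for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        cl <- tryCatch(cluster_subsample(algorithm, X, D, idx, k),
                       error = function(e) NULL)
        if (is.null(cl)) next
        for (g in unique(cl)) {
          gi <- idx[cl == g]
          conn[[ki]][gi, gi] <- conn[[ki]][gi, gi] + 1
        }
      }
    }
  })
  never <- samp == 0
  diag(never) <- FALSE
  if (any(never)) {
    warn(sprintf("%d item pairs were never co-sampled; consensus imputed as 0.",
                 sum(never) / 2))
  }
  M <- lapply(conn, function(C) {
    out <- ifelse(samp > 0, C / samp, 0)
    diag(out) <- 1
    out <- (out + t(out)) / 2
    dimnames(out) <- list(rownames(X), rownames(X))
    out
  })
  A <- vapply(M, consensus_cdf_area, numeric(1))
  delta <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    delta[ki] <- if (ki == 1L) A[ki] else (A[ki] - A[ki - 1]) / A[ki - 1]
  }
  labels <- lapply(seq_along(k_range), function(ki) {
    hc <- hclust(stats::as.dist(1 - M[[ki]]), method = "average")
    setNames(cutree(hc, k_range[ki]), rownames(X))
  })
  names(labels) <- as.character(k_range)
  cc <- lapply(seq_along(k_range), function(ki) {
    per_cluster_consensus(M[[ki]], labels[[ki]])
  })
  names(cc) <- as.character(k_range)
  structure(list(algorithm = algorithm, dissimilarity = dissimilarity,
                 k_range = k_range, M = M, A = A, delta = delta,
                 labels = labels, cluster_consensus = cc,
                 n_iter = n_iter, subsample_frac = subsample_frac,
                 seed = seed, items = rownames(X)),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf("<consensus_run> %s / %s, %d iterations, %d items\n",
              x$algorithm, x$dissimilarity, x$n_iter, length(x$items)))
  cat(sprintf("  selected k = %d (largest relative CDF-area change)\n",
              select_num_clusters(x)))
  invisible(x)
}

#' Select the number of clusters from a consensus run
#'
#' Returns the `k` with the largest relative change in the area under the
#' consensus CDF, `delta(k) = (A(k) - A(k-1)) / A(k-1)` with
#' `delta(k_min) = A(k_min)`. Ties break toward smaller `k`.
#'
#' @param run A `consensus_run`.
#' @return The selected integer `k`.
#' @export
select_num_clusters <- function(run) {
  stopifnot(inherits(run, "consensus_run"))
  run$k_range[which.max(run$delta)]
}

#' Median cluster consensus
#'
#' Per-cluster consensus is the mean consensus over within-cluster item pairs
#' (singletons count as 1); the summary statistic is the median across
#' clusters at the chosen `k`.
#'
#' @param run A `consensus_run`.
#' @param k Cluster number; defaults to [select_num_clusters()].
#' @return A single value in `[0, 1]`.
#' @export
median_cluster_consensus <- function(run, k = NULL) {
  stopifnot(inherits(run, "consensus_run"))
  if (is.null(k)) k <- select_num_clusters(run)
  key <- as.character(k)
  if (!key %in% names(run$cluster_consensus)) {
    abort(sprintf("k = %d is not in the run's k_range.", k))
  }
  median(run$cluster_consensus[[key]])
}

#' Pick the consensus run most associated with a clinical variable
#'
#' Computes Cramer's V between each run's labels (at its selected `k`) and a
#' categorical clinical variable, and returns the run with the highest V
#' (ties break by run order).
#'
#' @param runs A list of `consensus_run` objects.
#' @param clinical_variable Categorical vector aligned with the items.
#' @return A list: `run` (the winner), `cramers_v`, and `summary`, a tibble
#'   of algorithm, dissimilarity, selected k, median cluster consensus and V
#'   for every run.
#' @export
select_best_algorithm <- function(runs, clinical_variable) {
  stopifnot(length(runs) >= 1L)
  summary <- purrr::map_dfr(runs, function(run) {
    k <- select_num_clusters(run)
    v <- cramers_v_test(run$labels[[as.character(k)]], clinical_variable)
    tibble(algorithm = run$algorithm, dissimilarity = run$dissimilarity,
           k = k, median_cc = median_cluster_consensus(run, k),
           chi2 = v$chi2, p = v$p, cramers_v = v$cramers_v, n = v$n)
  })
  best <- which.max(summary$cramers_v)
  list(run = runs[[best]], cramers_v = summary$cramers_v[best],
       summary = summary)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovery of planted groups. 1 means identical partitions (up to
#' label permutation), 0 is the chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
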