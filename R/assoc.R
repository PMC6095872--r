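#' Chi-squared test of independence with Cramer's V
#'
#' Cross-tabulates two categorical variables (pairwise-complete cases), runs
#' the chi-squared test of independence without continuity correction, and
#' reports Cramer's V, \eqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}}, as the
#' strength of association.
#'
#' @param labels,outcome Vectors of equal length; coerced to factors. Each
#'   must have at least two observed levels after dropping missing pairs.
#' @return A one-row tibble: `chi2`, `p`, `dof`, `cramers_v`, `n`.
#' @examples
#' cramers_v_test(rep(c("a", "b"), each = 10), rep(c("x", "y"), each = 10))
#' @export
cramers_v_test <- function(labels, outcome) {
  ok <- !is.na(labels) & !is.na(outcome)
  l <- factor(labels[ok])
  o <- factor(outcome[ok])
  l <- droplevels(l)
  o <- droplevels(o)
  if (nlevels(l) < 2L || nlevels(o) < 2L) {
    abort("both variables need at least two observed levels.")
  }
  tab <- table(l, o)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(as.numeric(ht$statistic) / (n * (min(dim(tab)) - 1)))
  tibble(chi2 = as.numeric(ht$statistic), p = ht$p.value,
         dof = as.integer(ht$parameter), cramers_v = v, n = n)
}

#' Spearman association between radiomic features and an ordered outcome
#'
#' Spearman rank correlation (midrank ties, pairwise-complete) between every
#' numeric feature column and an ordinal outcome. The full table is always
#' returned; `pass_threshold` marks features exceeding the display cutoff
#' (default \eqn{|\rho| > 0.2}).
#'
#' @param features Tibble of features; non-numeric columns (e.g. `tumor_id`)
#'   are carried over as identifiers and skipped.
#' @param outcome Ordinal outcome vector aligned with the rows.
#' @param threshold Display threshold on \eqn{|\rho|}.
#' @return A tibble: `feature`, `rho`, `n`, `pass_threshold`. Constant
#'   features get `rho = NA`.
#' @export
spearman_assoc <- function(features, outcome, threshold = 0.2) {
  num <- features[vapply(features, is.numeric, logical(1))]
  out <- purrr::map_dfr(names(num), function(nm) {
    x <- num[[nm]]
    ok <- !is.na(x) & !is.na(outcome)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L) {
      return(tibble(feature = nm, rho = NA_real_, n = sum(ok)))
    }
    tibble(feature = nm,
           rho = suppressWarnings(cor(x[ok], as.numeric(outcome[ok]),
                                      method = "spearman")),
           n = sum(ok))
  })
  out$pass_threshold <- !is.na(out$rho) & abs(out$rho) > threshold
  out
}

#' Proportion of variance explained by a categorical outcome
#'
#' Fits a feature on the dummy-coded outcome groups; the returned
#' \eqn{r^2_{mreg}} is the between-group sum of squares over the total sum of
#' squares (one-way ANOVA eta squared, identical to the squared multiple
#' correlation of the dummy-coded least-squares fit).
#'
#' @param feature Numeric vector.
#' @param groups Categorical vector of the same length.
#' @return A single value in `[0, 1]`; zero total variance returns 0 with a
#'   warning.
#' @examples
#' anova_r2(c(1, 2, 3, 4), c("a", "a", "b", "b"))
#' @export
anova_r2 <- function(feature, groups) {
  ok <- !is.na(feature) & !is.na(groups)
  x <- feature[ok]
  g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2L) abort("need at least two groups with observations.")
  sst <- sum((x - mean(x))^2)
  if (sst == 0) {
    warn("feature has zero variance; r2 set to 0.")
    return(0)
  }
  gm <- tapply(x, g, mean)
  gn <- tapply(x, g, length)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssb / sst
}

#' @rdname anova_r2
#' @param features Tibble of features (non-numeric columns skipped).
#' @param threshold Display threshold on \eqn{r^2_{mreg}} (default 0.04).
#' @return `anova_r2_assoc()`: a tibble `feature`, `r2_mreg`, `n`,
#'   `pass_threshold`.
#' @export
anova_r2_assoc <- function(features, groups, threshold = 0.04) {
  num <- features[vapply(features, is.numeric, logical(1))]
  out <- purrr::map_dfr(names(num), function(nm) {
    x <- num[[nm]]
    ok <- !is.na(x) & !is.na(groups)
    r2 <- tryCatch(suppressWarnings(anova_r2(x, groups)),
                   error = function(e) NA_real_)
    tibble(feature = nm, r2_mreg = r2, n = sum(ok))
  })
  out$pass_threshold <- !is.na(out$r2_mreg) & out$r2_mreg > threshold
  out
}

#' Z-score a feature table
#'
#' Centers and scales every numeric column to mean 0 and population standard
#' deviation 1 (divisor `n`, so refitting held-out rows with the returned
#' parameters is exact). Constant columns are flagged, left unscaled and
#' warned about.
#'
#' @param features Tibble; non-numeric columns pass through untouched.
#' @return The scaled tibble with attribute `"scaling"`: a tibble of
#'   `feature`, `center`, `scale`, `constant`.
#' @export
zscore_table <- function(features) {
  is_num <- vapply(features, is.numeric, logical(1))
  out <- features
  sc <- purrr::map_dfr(names(features)[is_num], function(nm) {
    x <- features[[nm]]
    mu <- mean(x, na.rm = TRUE)
    s <- sqrt(mean((x - mu)^2, na.rm = TRUE))
    constant <- !is.finite(s) || s == 0
    tibble(feature = nm, center = mu, scale = if (constant) 1 else s,
           constant = constant)
  })
  if (any(sc$constant)) {
    warn(sprintf("constant columns left unscaled: %s",
                 paste(sc$feature[sc$constant], collapse = ", ")))
  }
  for (r in seq_len(nrow(sc))) {
    if (sc$constant[r]) next
    nm <- sc$feature[r]
    out[[nm]] <- (features[[nm]] - sc$center[r]) / sc$scale[r]
  }
  attr(out, "scaling") <- sc
  out
}

#' @rdname zscore_table
#' @param new_data Rows to transform with a previously computed scaling.
#' @param scaling The `"scaling"` attribute of a [zscore_table()] result.
#' @export
apply_zscore <- function(new_data, scaling) {
  out <- new_data
  for (r in seq_len(nrow(scaling))) {
    if (isTRUE(scaling$constant[r])) next
    nm <- scaling$feature[r]
    if (nm %in% names(out)) {
      out[[nm]] <- (new_data[[nm]] - scaling$center[r]) / scaling$scale[r]
    }
  }
  out
}
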