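#' The 13 canonical GLCM directions
#'
#' The 26-connected 3-D neighborhood contains 13 unique displacement
#' directions once opposite offsets are identified (co-occurrences are
#' accumulated symmetrically). Returns one representative per pair, with the
#' first nonzero component positive.
#'
#' @return An integer 13 x 3 matrix of voxel offsets.
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  out <- g[keep, , drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts ordered pairs of masked voxels separated by `direction * distance`,
#' accumulates them symmetrically (both \eqn{(i,j)} and \eqn{(j,i)}), and
#' normalizes to probabilities. Pairs with either voxel outside the mask are
#' skipped. If a direction yields no valid pair, `NULL` is returned so the
#' caller can exclude that direction from averaging.
#'
#' @param disc A `discretized_image` from [discretize()] (level 0 = outside).
#' @param direction Integer length-3 offset, typically a row of
#'   [glcm_offsets()].
#' @param distance Voxel distance (default 1).
#' @return A `glcm` object (list with probability matrix `p`, `direction`,
#'   `distance`, `n_pairs`), or `NULL` when the direction has no valid pairs.
#' @export
glcm_matrix <- function(disc, direction, distance = 1L) {
  lev <- disc$levels
  Ng <- disc$Ng
  d <- dim(lev)
  o <- as.integer(direction) * as.integer(distance)
  sel_a <- vector("list", 3)
  sel_b <- vector("list", 3)
  for (ax in 1:3) {
    if (abs(o[ax]) >= d[ax]) return(NULL)
    if (o[ax] >= 0) {
      sel_a[[ax]] <- seq_len(d[ax] - o[ax])
      sel_b[[ax]] <- seq_len(d[ax] - o[ax]) + o[ax]
    } else {
      sel_a[[ax]] <- seq_len(d[ax] + o[ax]) - o[ax]
      sel_b[[ax]] <- seq_len(d[ax] + o[ax])
    }
  }
  a <- lev[sel_a[[1]], sel_a[[2]], sel_a[[3]], drop = FALSE]
  b <- lev[sel_b[[1]], sel_b[[2]], sel_b[[3]], drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(NULL)
  ia <- a[ok]
  ib <- b[ok]
  counts <- matrix(tabulate((ia - 1L) * Ng + ib, nbins = Ng * Ng), Ng, Ng)
  counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), direction = as.integer(direction),
                 distance = as.integer(distance), n_pairs = length(ia)),
            class = "glcm")
}

xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

## the 25 texture features of one co-occurrence probability matrix
glcm_feature_values <- function(p) {
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(Ng) * px)
  mu_y <- sum(seq_len(Ng) * py)
  sd_x <- sqrt(sum((seq_len(Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(Ng) - mu_y)^2 * py))
  ## distributions of i+j (2..2Ng) and |i-j| (0..Ng-1)
  ks_sum <- 2:(2 * Ng)
  p_sum <- vapply(ks_sum, function(k) sum(p[i + j == k]), numeric(1))
  ks_dif <- 0:(Ng - 1)
  p_dif <- vapply(ks_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))
  dif_avg <- sum(ks_dif * p_dif)
  sum_avg <- sum(ks_sum * p_sum)
  HXY <- -sum(xlog2x(p))
  HX <- -sum(xlog2x(px))
  HY <- -sum(xlog2x(py))
  pxy <- outer(px, py)
  HXY1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  HXY2 <- -sum(xlog2x(pxy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (max(HX, HY) > 0) sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)) else 0
  corr <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  offdiag <- abs(i - j) > 0
  c(
    autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = dif_avg,
    difference_entropy = -sum(xlog2x(p_dif)),
    difference_variance = sum((ks_dif - dif_avg)^2 * p_dif),
    average_intensity = mu_x,
    dissimilarity = sum(abs(i - j) * p),
    energy_glcm = sum(p^2),
    entropy_glcm = HXY,
    homogeneity1 = sum(p / (1 + abs(i - j))),
    homogeneity2 = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + ((i - j) / Ng)^2)),
    idn = sum(p / (1 + abs(i - j) / Ng)),
    inverse_variance = if (Ng > 1) sum(p[offdiag] / (i - j)[offdiag]^2) else 0,
    maximum_probability = max(p),
    sum_average = sum_avg,
    sum_entropy = -sum(xlog2x(p_sum)),
    sum_variance = sum((ks_sum - sum_avg)^2 * p_sum),
    sum_squares = sum((i - mu_x)^2 * p),
    imc1 = imc1,
    imc2 = imc2
  )
}

#' Direction-averaged GLCM texture features
#'
#' Builds one co-occurrence matrix per canonical direction (see
#' [glcm_offsets()]) at the given voxel distance and returns the mean of each
#' of the 25 texture features across the directions that have at least one
#' valid voxel pair. Logarithms are base 2 with \eqn{0 \log 0 := 0};
#' degenerate single-level regions return the documented guard values
#' (correlation 1, IMC1/IMC2 0, inverse variance 0).
#'
#' @param disc A `discretized_image` from [discretize()].
#' @param distance Voxel distance (default 1).
#' @return A one-row tibble with 25 texture columns.
#' @export
glcm_features <- function(disc, distance = 1L) {
  offs <- glcm_offsets()
  mats <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    mats[[r]] <- glcm_matrix(disc, offs[r, ], distance)
  }
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0L) {
    abort("no voxel pairs found in any GLCM direction (disconnected mask?)")
  }
  vals <- vapply(mats, function(m) glcm_feature_values(m$p), numeric(25))
  as_tibble(as.list(rowMeans(vals)))
}
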