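#' First-order intensity features
#'
#' Nine first-order statistics of the masked voxel intensities. Histogram
#' statistics (entropy, uniformity) are computed on the fixed-bin-width
#' histogram produced by [discretize()]; `energy_hist` is the plain sum of
#' squared voxel intensities. Variance and the moment ratios use population
#' (divisor `n`) moments; a zero-variance region returns skewness and
#' kurtosis of 0 by convention rather than NaN.
#'
#' @param image An [image3d()].
#' @param mask The aligned [mask3d()].
#' @param bin_width Histogram bin width in intensity units.
#' @return A one-row tibble with columns `min`, `max`, `mean`, `variance`,
#'   `skewness`, `kurtosis`, `entropy_hist`, `energy_hist`, `uniformity_hist`.
#' @examples
#' img <- image3d(array(1:8, c(2, 2, 2)), c(1, 1, 1), "PET", "SUV")
#' msk <- mask3d(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
#' first_order_features(img, msk, bin_width = 1)
#' @export
first_order_features <- function(image, mask, bin_width) {
  x <- masked_values(image, mask)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  disc <- discretize(image, mask, bin_width)
  p_h <- tabulate(disc$levels[mask$voxels], nbins = disc$Ng) / n
  p_h <- p_h[p_h > 0]
  tibble(
    min = min(x), max = max(x), mean = mu, variance = m2,
    skewness = skew, kurtosis = kurt,
    entropy_hist = -sum(p_h * log2(p_h)),
    energy_hist = sum(x^2),
    uniformity_hist = sum(p_h^2)
  )
}
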