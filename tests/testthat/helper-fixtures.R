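# Small programmatic fixtures shared across tests.

# place values in a 3-D grid (first dim fastest), rest of grid zero/FALSE
test_image <- function(vals, dims = c(length(vals), 1, 1), spacing = c(1, 1, 1),
                       modality = "PET", units = "SUV") {
  arr <- array(0, dims)
  arr[seq_along(vals)] <- vals
  image3d(arr, spacing, modality, units)
}

test_mask <- function(n_true, dims = c(n_true, 1, 1), spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dims)
  arr[seq_len(n_true)] <- TRUE
  mask3d(arr, spacing)
}

ball_mask <- function(r, spacing = c(1, 1, 1), pad = 3) {
  n <- 2 * r + 1 + 2 * pad
  ctr <- (n + 1) / 2
  x <- (1:n - ctr)^2
  q <- outer(outer(x, x, `+`), x, `+`)
  mask3d(q <= r^2, spacing)
}

cube_mask <- function(side = 10, pad = 2, spacing = c(1, 1, 1)) {
  n <- side + 2 * pad
  arr <- array(FALSE, c(n, n, n))
  arr[pad + seq_len(side), pad + seq_len(side), pad + seq_len(side)] <- TRUE
  mask3d(arr, spacing)
}

# a small-but-real synthetic cohort for unit tests (not the reference cohort)
small_cohort_spec <- function(seed, n = 18) {
  cohort_spec(seed = seed, n_tumors = n,
              semi_axes = rbind(c(7, 6, 6), c(8, 7, 6), c(9, 8, 7)))
}

# feature table with labels independent of the features
null_table <- function(n = 90, p = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
    names(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = rbinom(n, 1, 0.5))
  })
}

random_discretized <- function(seed, max_dim = 8, max_levels = 6) {
  withr::with_seed(seed, {
    d <- sample(3:max_dim, 3, replace = TRUE)
    img <- image3d(array(runif(prod(d)), d), c(1, 1, 1), "PET", "SUV")
    mk <- array(runif(prod(d)) < 0.75, d)
    if (!any(mk)) mk[1] <- TRUE
    msk <- mask3d(mk, c(1, 1, 1))
    bw <- 1 / sample(seq_len(max_levels - 1), 1)
    list(disc = discretize(img, msk, bw), image = img, mask = msk,
         bin_width = bw)
  })
}
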