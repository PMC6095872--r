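# Independent brute-force oracles kept deliberately naive: explicit loops and
# first-principles formulas, sharing no code with the package implementation.

# direction-averaged GLCM features by direct enumeration of all voxel pairs
oracle_glcm_features <- function(lev, Ng, dirs = glcm_offsets()) {
  d <- dim(lev)
  per_dir <- list()
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    cnt <- matrix(0, Ng, Ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      b <- lev[x2, y2, z2]
      if (b == 0) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
    sx <- sqrt(sum((1:Ng - mux)^2 * px)); sy <- sqrt(sum((1:Ng - muy)^2 * py))
    ac <- cp <- cs <- ct <- con <- dis <- ssq <- 0
    hom1 <- hom2 <- idmn <- idn <- iv <- ent <- en <- 0
    for (i in 1:Ng) for (j in 1:Ng) {
      pij <- p[i, j]
      ac <- ac + i * j * pij
      cp <- cp + (i + j - mux - muy)^4 * pij
      cs <- cs + (i + j - mux - muy)^3 * pij
      ct <- ct + (i + j - mux - muy)^2 * pij
      con <- con + (i - j)^2 * pij
      dis <- dis + abs(i - j) * pij
      ssq <- ssq + (i - mux)^2 * pij
      hom1 <- hom1 + pij / (1 + abs(i - j))
      hom2 <- hom2 + pij / (1 + (i - j)^2)
      idmn <- idmn + pij / (1 + ((i - j) / Ng)^2)
      idn <- idn + pij / (1 + abs(i - j) / Ng)
      if (i != j) iv <- iv + pij / (i - j)^2
      if (pij > 0) ent <- ent - pij * log2(pij)
      en <- en + pij^2
    }
    psum <- sapply(2:(2 * Ng), function(k) {
      s <- 0
      for (i in 1:Ng) for (j in 1:Ng) if (i + j == k) s <- s + p[i, j]
      s
    })
    pdif <- sapply(0:(Ng - 1), function(k) {
      s <- 0
      for (i in 1:Ng) for (j in 1:Ng) if (abs(i - j) == k) s <- s + p[i, j]
      s
    })
    sa <- sum((2:(2 * Ng)) * psum); da <- sum((0:(Ng - 1)) * pdif)
    se <- -sum(ifelse(psum > 0, psum * log2(psum), 0))
    de <- -sum(ifelse(pdif > 0, pdif * log2(pdif), 0))
    sv <- sum(((2:(2 * Ng)) - sa)^2 * psum)
    dv <- sum(((0:(Ng - 1)) - da)^2 * pdif)
    HX <- -sum(ifelse(px > 0, px * log2(px), 0))
    HY <- -sum(ifelse(py > 0, py * log2(py), 0))
    HXY1 <- 0; HXY2 <- 0
    for (i in 1:Ng) for (j in 1:Ng) {
      q <- px[i] * py[j]
      if (q > 0) {
        HXY2 <- HXY2 - q * log2(q)
        if (p[i, j] > 0) HXY1 <- HXY1 - p[i, j] * log2(q)
      }
    }
    imc1 <- if (max(HX, HY) > 0) (ent - HXY1) / max(HX, HY) else 0
    imc2 <- if (max(HX, HY) > 0) sqrt(max(1 - exp(-2 * (HXY2 - ent)), 0)) else 0
    corr <- if (sx > 0 && sy > 0) (ac - mux * muy) / (sx * sy) else 1
    per_dir[[length(per_dir) + 1]] <-
      c(autocorrelation = ac, cluster_prominence = cp, cluster_shade = cs,
        cluster_tendency = ct, contrast = con, correlation = corr,
        difference_average = da, difference_entropy = de,
        difference_variance = dv, average_intensity = mux,
        dissimilarity = dis, energy_glcm = en, entropy_glcm = ent,
        homogeneity1 = hom1, homogeneity2 = hom2, idmn = idmn, idn = idn,
        inverse_variance = iv, maximum_probability = max(p),
        sum_average = sa, sum_entropy = se, sum_variance = sv,
        sum_squares = ssq, imc1 = imc1, imc2 = imc2)
  }
  rowMeans(do.call(cbind, per_dir))
}

# central moment ratios straight from the definitions
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m <- function(k) sum((x - mu)^k) / n
  list(mean = mu, variance = m(2),
       skewness = if (m(2) > 0) m(3) / m(2)^1.5 else 0,
       kurtosis = if (m(2) > 0) m(4) / m(2)^2 else 0)
}
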