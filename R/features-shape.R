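## Shape descriptors of the 3-D tumor mask. Two surface-area estimators are
## provided: exact face counting (sums exposed voxel faces; exact on boxes but
## does not converge to the true area of curved surfaces) and a triangulated
## mesh of the 0.5 isosurface of a lightly smoothed copy of the mask, which
## converges for smooth shapes and is the default.

pad_array <- function(arr, pad, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
  out
}

## separable Gaussian smoothing along the three axes (zero boundary)
gaussian_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    n <- d[1]
    band <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      idx <- which(seq_len(n) + o >= 1 & seq_len(n) + o <= n)
      band[cbind(idx, idx + o)] <- k[o + r + 1]
    }
    out <- band %*% m
    aperm(array(out, d), order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

face_count_area <- function(mask_arr, spacing) {
  m <- pad_array(mask_arr, 1L)
  d <- dim(m)
  face_areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2])
  total <- 0
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (ax in 1:3) {
    s <- shifts[[ax]]
    a <- m[seq_len(d[1] - s[1]), seq_len(d[2] - s[2]), seq_len(d[3] - s[3]), drop = FALSE]
    b <- m[seq_len(d[1] - s[1]) + s[1], seq_len(d[2] - s[2]) + s[2],
           seq_len(d[3] - s[3]) + s[3], drop = FALSE]
    total <- total + sum(a != b) * face_areas[ax]
  }
  total
}

## tetrahedral decomposition of the unit cube (corner indices 1..8)
mt_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
mt_tets <- rbind(
  c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
  c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))
mt_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

tri_area_rows <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

## isosurface area by marching tetrahedra with linear edge interpolation;
## field must be zero-padded so the surface closes
marching_tetra_area <- function(field, spacing, iso = 0.5) {
  d <- dim(field)
  inside <- field > iso
  c000 <- inside[-d[1], -d[2], -d[3]]
  c100 <- inside[-1,    -d[2], -d[3]]
  c110 <- inside[-1,    -1,    -d[3]]
  c010 <- inside[-d[1], -1,    -d[3]]
  c001 <- inside[-d[1], -d[2], -1]
  c101 <- inside[-1,    -d[2], -1]
  c111 <- inside[-1,    -1,    -1]
  c011 <- inside[-d[1], -1,    -1]
  n_in <- c000 + c100 + c110 + c010 + c001 + c101 + c111 + c011
  active <- which(n_in > 0L & n_in < 8L)
  if (length(active) == 0L) return(0)
  dc <- d - 1L
  ai <- arrayInd(active, dc)
  corner_vals <- matrix(0, length(active), 8)
  for (c8 in 1:8) {
    off <- mt_corners[c8, ]
    corner_vals[, c8] <- field[cbind(ai[, 1] + off[1], ai[, 2] + off[2],
                                     ai[, 3] + off[3])]
  }
  total <- 0
  scale <- spacing
  for (t in seq_len(nrow(mt_tets))) {
    tet <- mt_tets[t, ]
    vals <- corner_vals[, tet, drop = FALSE]
    pos <- mt_corners[tet, , drop = FALSE] * rep(scale, each = 4)
    ins <- vals > iso
    code <- ins %*% c(1L, 2L, 4L, 8L)
    for (cd in 1:14) {
      rows <- which(code == cd)
      if (length(rows) == 0L) next
      bits <- as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))
      cross <- which(bits[mt_edges[, 1]] != bits[mt_edges[, 2]])
      pts <- vector("list", length(cross))
      for (e in seq_along(cross)) {
        a <- mt_edges[cross[e], 1]; b <- mt_edges[cross[e], 2]
        va <- vals[rows, a]; vb <- vals[rows, b]
        tt <- (iso - va) / (vb - va)
        pa <- matrix(pos[a, ], length(rows), 3, byrow = TRUE)
        pb <- matrix(pos[b, ], length(rows), 3, byrow = TRUE)
        pts[[e]] <- pa + tt * (pb - pa)
      }
      if (length(cross) == 3L) {
        total <- total + sum(tri_area_rows(pts[[1]], pts[[2]], pts[[3]]))
      } else {
        total <- total + sum(tri_area_rows(pts[[1]], pts[[2]], pts[[3]])) +
          sum(tri_area_rows(pts[[2]], pts[[4]], pts[[3]]))
      }
    }
  }
  total
}

mesh_area <- function(mask_arr, spacing, smooth_sigma = 0.8) {
  field <- gaussian_smooth3d(pad_array(array(as.numeric(mask_arr), dim(mask_arr)),
                                       max(4L, ceiling(3 * smooth_sigma) + 1L)),
                             smooth_sigma)
  a <- marching_tetra_area(field, spacing)
  if (a <= 0) face_count_area(mask_arr, spacing) else a
}

surface_voxel_coords <- function(mask_arr, spacing) {
  m <- pad_array(mask_arr, 1L)
  d0 <- dim(mask_arr)
  inner <- function(dx, dy, dz) {
    m[1L + dx + seq_len(d0[1]), 1L + dy + seq_len(d0[2]), 1L + dz + seq_len(d0[3])]
  }
  nb <- inner(1, 0, 0) + inner(-1, 0, 0) + inner(0, 1, 0) +
    inner(0, -1, 0) + inner(0, 0, 1) + inner(0, 0, -1)
  surf <- which(mask_arr & nb < 6L)
  ai <- arrayInd(surf, d0)
  sweep(ai - 1, 2, spacing, `*`)
}

max_diameter_3d <- function(mask_arr, spacing, chunk = 512L) {
  co <- surface_voxel_coords(mask_arr, spacing)
  n <- nrow(co)
  if (n == 1L) return(0)
  sq <- rowSums(co^2)
  best <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * co[idx, , drop = FALSE] %*% t(co)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3-D shape features of a tumor mask
#'
#' Eight geometric descriptors: volume, surface area, surface-to-volume
#' ratio, compactness1 \eqn{V / (\sqrt{\pi} A^{3/2})}, compactness2
#' \eqn{36\pi V^2 / A^3}, sphericity \eqn{\pi^{1/3} (6V)^{2/3} / A},
#' spherical disproportion \eqn{A / (4\pi R^2)} with \eqn{R = (3V/4\pi)^{1/3}},
#' and the maximum 3-D diameter (largest pairwise Euclidean distance between
#' surface-voxel centers).
#'
#' @param mask A [mask3d()].
#' @param surface_method `"mesh"` (default; triangulated isosurface of a
#'   lightly smoothed mask, accurate for smooth shapes) or `"face_count"`
#'   (sum of exposed voxel faces; exact on axis-aligned boxes).
#' @return A one-row tibble with columns `volume`, `surface_area`,
#'   `surface_to_volume`, `compactness1`, `compactness2`, `sphericity`,
#'   `spherical_disproportion`, `max_diameter_3d`.
#' @examples
#' cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
#' shape_features(mask3d(cube, c(1, 1, 1)), surface_method = "face_count")
#' @export
shape_features <- function(mask, surface_method = c("mesh", "face_count")) {
  surface_method <- match.arg(surface_method)
  m <- mask$voxels
  sp <- mask$spacing
  V <- sum(m) * prod(sp)
  A <- switch(surface_method,
              face_count = face_count_area(m, sp),
              mesh = mesh_area(m, sp))
  R <- (3 * V / (4 * pi))^(1 / 3)
  tibble(
    volume = V,
    surface_area = A,
    surface_to_volume = A / V,
    compactness1 = V / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * V^2 / A^3,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    spherical_disproportion = A / (4 * pi * R^2),
    max_diameter_3d = max_diameter_3d(m, sp)
  )
}
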