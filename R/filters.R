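# Array numerics shared by the phantom, registration and measurement layers:
# separable Gaussian smoothing, finite-difference gradients, trilinear
# interpolation, and displacement-field warping. All operate on plain arrays;
# spacing-aware wrappers live with their callers.

# Shift an array by `by` voxels along `axis`, replicating the edge.
shift_array <- function(a, by, axis) {
  if (by == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) - by
  idx[idx < 1] <- 1
  idx[idx > n] <- n
  if (length(d) == 2) {
    if (axis == 1) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (axis == 1) a[idx, , , drop = FALSE]
    else if (axis == 2) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

gauss_kernel_1d <- function(sigma) {
  # 2.5 sigma support keeps > 98.7% of the mass at ~20% fewer taps
  r <- max(1L, ceiling(2.5 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  list(offsets = x, weights = k / sum(k))
}

# Separable Gaussian smoothing; sigma in voxels, scalar or per-axis.
# Works for 2D and 3D arrays. sigma <= 0 on an axis skips that axis.
gauss_smooth <- function(a, sigma) {
  nd <- length(dim(a))
  sigma <- rep_len(sigma, nd)
  out <- a
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0) next
    k <- gauss_kernel_1d(sigma[ax])
    acc <- array(0, dim(out))
    for (i in seq_along(k$offsets)) {
      acc <- acc + k$weights[i] * shift_array(out, k$offsets[i], ax)
    }
    out <- acc
  }
  out
}

# Central-difference gradient of a 3D array; spacing in mm per axis.
# Returns list(gx, gy, gz) in intensity / mm.
gradient3 <- function(a, spacing = c(1, 1, 1)) {
  spacing <- rep_len(spacing, 3)
  list(
    gx = (shift_array(a, -1, 1) - shift_array(a, 1, 1)) / (2 * spacing[1]),
    gy = (shift_array(a, -1, 2) - shift_array(a, 1, 2)) / (2 * spacing[2]),
    gz = (shift_array(a, -1, 3) - shift_array(a, 1, 3)) / (2 * spacing[3])
  )
}

# 5/7-point Laplacian (2D/3D), spacing-aware.
laplacian <- function(a, spacing = 1) {
  nd <- length(dim(a))
  spacing <- rep_len(spacing, nd)
  out <- array(0, dim(a))
  for (ax in seq_len(nd)) {
    out <- out + (shift_array(a, -1, ax) + shift_array(a, 1, ax) - 2 * a) /
      spacing[ax]^2
  }
  out
}

# Vectorised trilinear interpolation of 3D array `a` at fractional 1-based
# voxel coordinates (xi, yi, zi). Out-of-bounds samples return `fill`.
interp_trilinear <- function(a, xi, yi, zi, fill = NA_real_) {
  d <- dim(a)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(xi))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]; zi <- zi[inside]
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  # base linear index once; corner offsets are constants
  o2 <- d[1]; o3 <- d[1] * d[2]
  lin0 <- x0 + o2 * (y0 - 1) + o3 * (z0 - 1)
  v000 <- a[lin0]
  v100 <- a[lin0 + 1]
  v010 <- a[lin0 + o2]
  v110 <- a[lin0 + o2 + 1]
  v001 <- a[lin0 + o3]
  v101 <- a[lin0 + o3 + 1]
  v011 <- a[lin0 + o2 + o3]
  v111 <- a[lin0 + o2 + o3 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Nearest-neighbour interpolation (label masks).
interp_nearest <- function(a, xi, yi, zi, fill = 0) {
  d <- dim(a)
  xi <- round(xi); yi <- round(yi); zi <- round(zi)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(xi))
  if (any(inside)) {
    out[inside] <- a[xi[inside] + d[1] * (yi[inside] - 1) +
                       d[1] * d[2] * (zi[inside] - 1)]
  }
  out
}

# Voxel-index grids for an array dimension, as long vectors in array order.
index_grid <- function(d) {
  list(
    xi = rep(seq_len(d[1]), times = d[2] * d[3]),
    yi = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    zi = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

# Resample array `a` through a displacement field: out(x) = a(x + u(x)),
# u in mm on the same grid, spacing in mm. `method` "linear" or "nearest".
warp_array <- function(a, field, spacing, fill = 0, method = "linear") {
  d <- dim(a)
  if (all(field == 0)) return(a)
  g <- index_grid(d)
  spacing <- rep_len(spacing, 3)
  xi <- g$xi + as.vector(field[, , , 1]) / spacing[1]
  yi <- g$yi + as.vector(field[, , , 2]) / spacing[2]
  zi <- g$zi + as.vector(field[, , , 3]) / spacing[3]
  v <- if (method == "nearest") interp_nearest(a, xi, yi, zi, fill = fill)
       else interp_trilinear(a, xi, yi, zi, fill = fill)
  array(v, d)
}

#' Warp a volume through a displacement field
#'
#' Resamples `vol` at `x + u(x)` for every voxel `x` of its grid, where `u`
#' is a per-voxel displacement in mm (pull-back convention: the field lives
#' on the output grid).
#'
#' @param vol a [brw_volume()].
#' @param field array `(nx, ny, nz, 3)` of displacements in mm on `vol`'s grid.
#' @param fill value for samples falling outside the volume.
#' @param method `"linear"` for intensities, `"nearest"` for label masks.
#' @return A [brw_volume()] on the same grid.
#' @export
warp_volume <- function(vol, field, fill = 0, method = "linear") {
  stopifnot(is_volume(vol), length(dim(field)) == 4, dim(field)[4] == 3)
  out <- warp_array(vol$data, field, vol$spacing, fill = fill, method = method)
  brw_volume(out, spacing = vol$spacing, modality = vol$modality,
             origin = vol$origin)
}

# Downsample a 3D array by integer factor (block mean) for multiresolution.
downsample2 <- function(a) {
  d <- dim(a)
  nd <- floor(d / 2)
  i <- seq_len(nd[1]) * 2L; j <- seq_len(nd[2]) * 2L; k <- seq_len(nd[3]) * 2L
  (a[i - 1L, j - 1L, k - 1L] + a[i, j - 1L, k - 1L] +
   a[i - 1L, j,      k - 1L] + a[i, j,      k - 1L] +
   a[i - 1L, j - 1L, k     ] + a[i, j - 1L, k     ] +
   a[i - 1L, j,      k     ] + a[i, j,      k     ]) / 8
}

# Upsample a per-component field array to a target dim by trilinear sampling.
upsample_field <- function(field, target_dim) {
  src <- dim(field)[1:3]
  g <- index_grid(target_dim)
  sc <- (src - 1) / pmax(target_dim - 1, 1)
  out <- array(0, c(target_dim, 3))
  for (c3 in 1:3) {
    out[, , , c3] <- array(
      interp_trilinear(field[, , , c3],
                       1 + (g$xi - 1) * sc[1],
                       1 + (g$yi - 1) * sc[2],
                       1 + (g$zi - 1) * sc[3], fill = 0),
      target_dim)
  }
  out
}
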