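#' Nearest-rank percentile
#'
#' The value below or at which at least `q * 100` percent of the sample
#' lies: element `ceiling(q * n)` of the sorted sample. This convention is
#' used everywhere a percentile rule appears in the correction (uniform
#' scatter estimate, mask cutoffs).
#'
#' @param x numeric vector (non-empty).
#' @param q fraction in (0, 1].
#' @return A single sample element.
#' @examples
#' nearestRankPercentile(seq(10, 100, by = 10), 0.10)  # 10
#' @export
nearestRankPercentile <- function(x, q) {
  stopifnot(length(x) > 0, q > 0, q <= 1)
  sort(x)[ceiling(q * length(x))]
}

# Normalized 1D Gaussian taps at integer offsets -radius..radius.
gaussianTaps <- function(sigmaPx, radiusPx) {
  k <- exp(-(seq(-radiusPx, radiusPx))^2 / (2 * sigmaPx^2))
  k / sum(k)
}

# Band (Toeplitz) convolution matrix for 1D taps, zero-padded boundaries:
# (K %*% x)[i] = sum_j taps[i - j] x[j].
convBandMatrix <- function(n, taps) {
  r <- min((length(taps) - 1L) / 2L, n - 1L)
  K <- matrix(0, n, n)
  mid <- (length(taps) - 1L) / 2L
  taps <- taps[(mid - r + 1L):(mid + r + 1L)]
  r <- as.integer(r)
  for (d in -r:r) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx + d, idx)] <- taps[r + 1L + d]
    else        K[cbind(idx, idx - d)] <- taps[r + 1L - d]
  }
  K
}

# Separable zero-padded 2D convolution of matrix A with outer(tu, tv).
sepConv2 <- function(A, Ku, Kv) Ku %*% A %*% t(Kv)

# World coordinates of voxel centres along one axis.
axisCoords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# Voxel centre coordinate arrays for a volume-like grid description.
gridCoords <- function(dim, spacing, origin) {
  list(x = axisCoords(dim[1], spacing[1], origin[1]),
       y = axisCoords(dim[2], spacing[2], origin[2]),
       z = axisCoords(dim[3], spacing[3], origin[3]))
}

# Extract a sub-volume whose grid is exactly aligned with `vol` (same
# spacing, origins differing by integer voxel shifts). Errors otherwise.
cropToGrid <- function(vol, dim, spacing, origin) {
  stopifnot(methods::is(vol, "VoxelVolume"))
  if (max(abs(spacingMm(vol) - spacing)) > 1e-9)
    stop("cropToGrid requires identical spacing")
  shift <- (origin - originMm(vol)) / spacing
  if (max(abs(shift - round(shift))) > 1e-6)
    stop("cropToGrid requires integer-voxel alignment")
  shift <- as.integer(round(shift))
  d0 <- dim(volArray(vol))
  idx <- lapply(1:3, function(a) shift[a] + seq_len(dim[a]))
  if (any(vapply(1:3, function(a) idx[[a]][1] < 1 || idx[[a]][dim[a]] > d0[a],
                 logical(1))))
    stop("requested grid extends beyond the volume")
  VoxelVolume(volArray(vol)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              spacing = spacing, origin = origin, units = volUnits(vol))
}

# Logical array: voxel centres within `radius` mm of point `center`.
sphereMask <- function(dim, spacing, origin, center, radius) {
  co <- gridCoords(dim, spacing, origin)
  dx2 <- (co$x - center[1])^2
  dy2 <- (co$y - center[2])^2
  dz2 <- (co$z - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

# Per-axial-slice central-difference gradient magnitude of a 3D array,
# one-sided at slice borders.
sliceGradientMagnitude <- function(a) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d)
  nx <- d[1]; ny <- d[2]
  gx[2:(nx - 1), , ] <- (a[3:nx, , ] - a[1:(nx - 2), , ]) / 2
  gx[1, , ] <- a[2, , ] - a[1, , ]
  gx[nx, , ] <- a[nx, , ] - a[nx - 1, , ]
  gy[, 2:(ny - 1), ] <- (a[, 3:ny, ] - a[, 1:(ny - 2), ]) / 2
  gy[, 1, ] <- a[, 2, ] - a[, 1, ]
  gy[, ny, ] <- a[, ny, ] - a[, ny - 1, ]
  sqrt(gx^2 + gy^2)
}

# Internal guard: two volumes on the same grid.
stopIfGridMismatch <- function(a, b) {
  if (!identical(dim(volArray(a)), dim(volArray(b))) ||
      max(abs(spacingMm(a) - spacingMm(b))) > 1e-9 ||
      max(abs(originMm(a) - originMm(b))) > 1e-6)
    stop("volumes are not on the same grid")
  invisible(TRUE)
}
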