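#' Feldkamp-Davis-Kress reconstruction
#'
#' Filtered backprojection for full circular cone-beam scans: projections
#' are rescaled to a virtual detector at the isocenter, cosine-weighted,
#' row-wise ramp-filtered in the frequency domain (zero-padded to the next
#' power of two to avoid circular-convolution bias; optional Hann
#' apodization), and backprojected voxel-driven with the standard
#' distance weight. Output is in LAC units (1/mm).
#'
#' @param stack a `line_integral` [ProjectionStack-class] covering a full
#'   turn.
#' @param grid reconstruction grid: list with `dim` (voxels), `spacing`
#'   (mm, scalar or length 3) and optional `origin` (default centred on
#'   the isocenter).
#' @param filter `"ramlak"` (default) or `"hann"`.
#' @return A [VoxelVolume-class] with `units = "LAC"`.
#' @examples
#' \donttest{
#' v <- VoxelVolume(array(0, c(32, 32, 8)), spacing = 4, units = "LAC")
#' volArray(v)[8:24, 8:24, ] <- 0.02
#' g <- ConeBeamGeometry(detPixels = c(96, 24), pixelPitch = 4,
#'                       viewAngles = seq(0, 358, 2))
#' rec <- fdkReconstruct(forwardProject(v, g),
#'                       grid = list(dim = c(32, 32, 8), spacing = 4))
#' }
#' @export
fdkReconstruct <- function(stack, grid = list(dim = c(192, 192, 64),
                                              spacing = 1.5),
                           filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  if (projDomain(stack) != "line_integral")
    stop("fdkReconstruct needs a line-integral stack; convert intensities ",
         "with toLineIntegral()")
  g <- geometry(stack)
  ang <- g@viewAngles
  step <- mean(diff(ang))
  if ((ang[length(ang)] - ang[1]) < 360 - step - 1e-6)
    stop("short scans are not supported (need a full 360 degree turn)")
  if (length(grid$spacing) == 1L) grid$spacing <- rep(grid$spacing, 3L)
  if (is.null(grid$origin))
    grid$origin <- -(grid$dim - 1) / 2 * grid$spacing
  q <- fdkFilterStack(volArray(stack), g, filter)
  rec <- .fdkBackprojectCpp(as.numeric(q), g@detPixels[1], g@detPixels[2],
                            ang, g@sad, g@sdd, g@pixelPitch,
                            as.integer(grid$dim), grid$spacing, grid$origin,
                            fovRadiusMm(g) * 1.05)
  VoxelVolume(array(rec, grid$dim), grid$spacing, grid$origin, units = "LAC")
}

# Cosine weighting + frequency-domain ramp filtering of all views.
# Returns the filtered stack in virtual-detector (isocenter) scale so the
# backprojector's integral has the correct 1/mm normalization.
fdkFilterStack <- function(p, geom, filter) {
  nu <- dim(p)[1]; nv <- dim(p)[2]; nViews <- dim(p)[3]
  mag <- geom@sad / geom@sdd
  du <- geom@pixelPitch * mag               # virtual detector pitch (mm)
  u <- (seq_len(nu) - (nu + 1) / 2) * du
  v <- (seq_len(nv) - (nv + 1) / 2) * du
  w <- geom@sad / sqrt(geom@sad^2 + outer(u^2, v^2, "+"))  # cosine weight
  N <- 2^ceiling(log2(2 * nu))
  f <- c(seq(0, N / 2), seq(-N / 2 + 1, -1)) / (N * du)    # cycles/mm
  H <- abs(f)
  if (filter == "hann") {
    fNyq <- 1 / (2 * du)
    H <- H * 0.5 * (1 + cos(pi * f / fNyq))
  }
  out <- array(0, dim(p))
  pad <- matrix(0, N, nv)
  for (k in seq_len(nViews)) {
    pad[seq_len(nu), ] <- p[, , k] * w
    Q <- stats::mvfft(pad)
    q <- Re(stats::mvfft(Q * H, inverse = TRUE)) / N
    out[, , k] <- q[seq_len(nu), ]
  }
  out
}

# Scalar HU <-> LAC conversions (the affine water calibration).
huToLacValue <- function(hu, muW = 0.02) hu / 1000 * muW + muW
lacToHuValue <- function(mu, muW = 0.02) (mu - muW) / muW * 1000

#' HU / LAC conversion
#'
#' The affine water calibration `mu = HU/1000 * mu_w + mu_w` and its exact
#' inverse `HU = 1000 (mu - mu_w) / mu_w`. Water maps to HU 0 and LAC
#' `mu_w`; air (-1000 HU) maps to LAC 0.
#'
#' @param vol a [VoxelVolume-class] in the appropriate units.
#' @param muW water LAC in 1/mm (> 0), default 0.02.
#' @return The converted [VoxelVolume-class].
#' @examples
#' v <- VoxelVolume(array(c(-1000, 0, 190), c(3, 1, 1)), units = "HU")
#' volArray(huToLac(v))  # 0, 0.020, 0.0238
#' @name hu-lac
#' @export
huToLac <- function(vol, muW = 0.02) {
  stopifnot(volUnits(vol) == "HU", muW > 0)
  VoxelVolume(huToLacValue(volArray(vol), muW), spacingMm(vol),
              originMm(vol), units = "LAC")
}

#' @rdname hu-lac
#' @export
lacToHu <- function(vol, muW = 0.02) {
  stopifnot(volUnits(vol) == "LAC", muW > 0)
  VoxelVolume(lacToHuValue(volArray(vol), muW), spacingMm(vol),
              originMm(vol), units = "HU")
}
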