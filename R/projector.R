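#' Cone-beam forward projection
#'
#' Computes line integrals of a linear-attenuation-coefficient (LAC)
#' volume along every source-to-pixel ray of a circular cone-beam scan
#' (fixed-step ray marching with trilinear interpolation). The object must
#' fit inside the laterally reconstructible field of view: truncated
#' projections are refused.
#'
#' @param lac a [VoxelVolume-class] with `units = "LAC"` (1/mm).
#' @param geom a [ConeBeamGeometry-class].
#' @param step ray-marching step in mm.
#' @return A [ProjectionStack-class] in the `line_integral` domain.
#' @examples
#' v <- VoxelVolume(array(0.02, c(24, 24, 8)), spacing = 4, units = "LAC")
#' g <- ConeBeamGeometry(detPixels = c(48, 16), pixelPitch = 6,
#'                       viewAngles = seq(0, 350, 10))
#' p <- forwardProject(v, g)
#' range(volArray(p))
#' @export
forwardProject <- function(lac, geom, step = 1) {
  stopifnot(methods::is(lac, "VoxelVolume"), volUnits(lac) == "LAC")
  a <- volArray(lac)
  dm <- dim(a)
  # lateral truncation guard: non-zero voxels must be inside the scan FOV
  fov <- fovRadiusMm(geom)
  co <- gridCoords(dm, spacingMm(lac), originMm(lac))
  r2 <- array(outer(co$x^2, co$y^2, "+"), dm)
  if (any(a != 0 & r2 > fov^2))
    stop("volume extends beyond the reconstructible FOV (radius ",
         round(fov, 1), " mm); truncation is not supported")
  p <- .forwardProjectCpp(as.numeric(a), dm, spacingMm(lac), originMm(lac),
                          geom@sad, geom@sdd, geom@detPixels[1],
                          geom@detPixels[2], geom@pixelPitch,
                          geom@viewAngles, step)
  ProjectionStack(array(p, c(geom@detPixels, length(geom@viewAngles))),
                  domain = "line_integral", geometry = geom)
}

# Lateral field-of-view radius at the isocenter implied by the detector.
fovRadiusMm <- function(geom) {
  halfDetIso <- geom@detPixels[1] / 2 * geom@pixelPitch * geom@sad / geom@sdd
  # radius of the circle seen by every view (fan edge ray)
  geom@sad * halfDetIso / sqrt(geom@sad^2 + halfDetIso^2)
}

#' Beer-Lambert domain conversion
#'
#' `toIntensity` maps line integrals to detector intensity,
#' `I = I0 exp(-p)`; `toLineIntegral` inverts it, `p = -log(I / I0)`,
#' clamping intensities at `floorFrac * I0` before the log (a warning
#' reports how many pixels were clamped).
#'
#' @param stack a [ProjectionStack-class] in the appropriate domain.
#' @param floorFrac clamp floor as a fraction of I0.
#' @return A [ProjectionStack-class] in the other domain (scatter truth is
#'   carried along unchanged).
#' @name beer-lambert
#' @export
toIntensity <- function(stack) {
  stopifnot(projDomain(stack) == "line_integral")
  g <- geometry(stack)
  ProjectionStack(g@i0 * exp(-volArray(stack)), domain = "intensity",
                  geometry = g, scatterTruth = scatterTruth(stack))
}

#' @rdname beer-lambert
#' @export
toLineIntegral <- function(stack, floorFrac = 1e-6) {
  stopifnot(projDomain(stack) == "intensity")
  g <- geometry(stack)
  a <- volArray(stack)
  floorVal <- floorFrac * g@i0
  nClamped <- sum(a < floorVal)
  if (nClamped > 0) {
    warning(nClamped, " intensity value(s) clamped at ", floorFrac, " * I0")
    a <- pmax(a, floorVal)
  }
  p <- pmax(-log(a / g@i0), 0)
  ProjectionStack(p, domain = "line_integral", geometry = g,
                  scatterTruth = scatterTruth(stack))
}

# Constant-preserving 2D Gaussian blur of one detector view (normalized
# convolution: zero-padded blur divided by the blurred indicator).
blurView <- function(view, Ku, Kv, onesBlur) sepConv2(view, Ku, Kv) / onesBlur

#' Simulate low-frequency detector scatter
#'
#' Adds a smooth additive scatter component to each intensity view:
#' `S = spr * G(I)` where `G` is a constant-preserving 2D Gaussian blur of
#' width `blurSigmaMm` at the detector. `spr` is the scatter-to-primary
#' ratio a flat field would see. The generated component is stored in
#' `scatterTruth`.
#'
#' @param stack intensity-domain [ProjectionStack-class].
#' @param spr scatter-to-primary scale (>= 0).
#' @param blurSigmaMm Gaussian width at the detector in mm.
#' @return The stack with `data = I + S` and `scatterTruth = S`.
#' @export
simulateScatter <- function(stack, spr = 1.0, blurSigmaMm = 50) {
  stopifnot(projDomain(stack) == "intensity", spr >= 0)
  g <- geometry(stack)
  a <- volArray(stack)
  if (spr == 0)
    return(ProjectionStack(a, "intensity", g,
                           scatterTruth = array(0, dim(a))))
  sigmaPx <- blurSigmaMm / g@pixelPitch
  r <- ceiling(3 * sigmaPx)
  taps <- gaussianTaps(sigmaPx, r)
  Ku <- convBandMatrix(dim(a)[1], taps)
  Kv <- convBandMatrix(dim(a)[2], taps)
  onesBlur <- sepConv2(matrix(1, dim(a)[1], dim(a)[2]), Ku, Kv)
  S <- array(0, dim(a))
  for (k in seq_len(dim(a)[3]))
    S[, , k] <- spr * blurView(a[, , k], Ku, Kv, onesBlur)
  ProjectionStack(a + S, "intensity", g, scatterTruth = S)
}

#' Inject Poisson counting noise
#'
#' Scaled-Poisson model: the unattenuated beam carries `photonsPerI0`
#' photons per pixel; each pixel's photon count is Poisson with mean
#' `I / I0 * photonsPerI0`, floored at one photon to preserve positivity.
#'
#' @param stack intensity-domain [ProjectionStack-class].
#' @param photonsPerI0 photons corresponding to intensity I0 (> 0).
#' @param seed integer seed (noise is reproducible given the seed).
#' @return The stack with noisy intensities.
#' @export
addNoise <- function(stack, photonsPerI0 = 1e5, seed = 1) {
  stopifnot(projDomain(stack) == "intensity", photonsPerI0 > 0)
  g <- geometry(stack)
  a <- volArray(stack)
  set.seed(seed)
  counts <- stats::rpois(length(a), as.numeric(a) / g@i0 * photonsPerI0)
  counts <- pmax(counts, 1)
  ProjectionStack(array(counts / photonsPerI0 * g@i0, dim(a)), "intensity",
                  g, scatterTruth = scatterTruth(stack))
}
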