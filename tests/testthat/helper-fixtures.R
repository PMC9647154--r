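# Shared fixtures. Heavy objects are computed lazily and cached for the
# whole test run.

.fixtures <- new.env(parent = emptyenv())

# Small phantom/scan configuration: same physics as the default benchmark
# but 3 mm voxels, a 192 x 72 detector and 180 views, so a full pipeline
# run takes seconds.
smallConfig <- function() {
  cfg <- defaultRunConfig()
  cfg$phantom$gridShape <- c(128, 96, 48)
  cfg$phantom$voxelSize <- 3
  cfg$geometry$detPixels <- c(192, 72)
  cfg$geometry$pixelPitch <- 3.104
  cfg$geometry$nViews <- 180
  cfg$recon$zDim <- 40
  cfg$dose$dim <- c(32, 32, 50)
  cfg$dose$spacing <- c(5, 5, 2)
  cfg
}

smallBenchmark <- function() {
  if (is.null(.fixtures$smallBench))
    .fixtures$smallBench <- runBenchmark(smallConfig())
  .fixtures$smallBench
}

# The full-scale study used by the acceptance checks (default config).
fullBenchmark <- function() {
  if (is.null(.fixtures$fullBench))
    .fixtures$fullBench <- runBenchmark(defaultRunConfig())
  .fixtures$fullBench
}

# Tiny cylinder scan for projector/reconstruction physics tests.
cylinderFixture <- function() {
  if (!is.null(.fixtures$cyl)) return(.fixtures$cyl)
  dm <- c(96, 96, 32)
  sp <- 2
  or <- -(dm - 1) / 2 * sp
  x <- or[1] + (seq_len(dm[1]) - 1) * sp
  y <- or[2] + (seq_len(dm[2]) - 1) * sp
  r2 <- outer(x^2, y^2, "+")
  v <- array(0, dm)
  for (k in seq_len(dm[3])) v[, , k] <- ifelse(r2 <= 50^2, 0.02, 0)
  vol <- VoxelVolume(v, sp, units = "LAC")
  geom <- ConeBeamGeometry(detPixels = c(128, 32), pixelPitch = 3,
                           viewAngles = seq(0, 358, 2))
  .fixtures$cyl <- list(vol = vol, geom = geom, r2 = r2,
                        proj = forwardProject(vol, geom))
  .fixtures$cyl
}

# Independent oracle for the masked normalized convolution (Eq.-style
# local filtration): explicit per-pixel weighted average with the same
# truncated, unit-sum Gaussian taps and zero padding.
filtrationOracle2D <- function(r, f, sigmaPx, radiusPx, denomFloor,
                               globalMean) {
  n1 <- nrow(r); n2 <- ncol(r)
  taps <- exp(-(-radiusPx:radiusPx)^2 / (2 * sigmaPx^2))
  taps <- taps / sum(taps)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    num <- 0; den <- 0
    for (di in -radiusPx:radiusPx) for (dj in -radiusPx:radiusPx) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      w <- taps[di + radiusPx + 1] * taps[dj + radiusPx + 1]
      num <- num + w * r[ii, jj] * f[ii, jj]
      den <- den + w * f[ii, jj]
    }
    out[i, j] <- if (den < denomFloor) globalMean else num / den
  }
  out
}

# Exhaustive brute-force local-gamma oracle on tiny grids: trilinear
# interpolation written independently, full offset scan (no early exit).
gammaOracle <- function(ref, ev, spacing, origin, dd, dta, threshold,
                        searchFactor = 3, subdiv = 5) {
  dm <- dim(ref)
  interp <- function(p) {
    ix <- (p - origin) / spacing        # 0-based voxel coords
    if (any(ix < 0) || any(ix > dm - 1)) return(NA_real_)
    i0 <- pmin(floor(ix), dm - 2)
    fr <- ix - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) *
           (if (dy) fr[2] else 1 - fr[2]) *
           (if (dz) fr[3] else 1 - fr[3])
      acc <- acc + w * ev[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }
  step <- dta / subdiv
  m <- floor(searchFactor * dta / step)
  offs <- expand.grid(x = (-m:m) * step, y = (-m:m) * step,
                      z = (-m:m) * step)
  offs <- offs[offs$x^2 + offs$y^2 + offs$z^2 <=
                 (searchFactor * dta)^2, , drop = FALSE]
  g <- array(NA_real_, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      dr <- ref[i, j, k]
      if (dr < threshold) next
      p0 <- origin + (c(i, j, k) - 1) * spacing
      best <- Inf
      for (o in seq_len(nrow(offs))) {
        de <- interp(p0 + as.numeric(offs[o, ]))
        if (is.na(de)) next
        g2 <- (offs$x[o]^2 + offs$y[o]^2 + offs$z[o]^2) / dta^2 +
          ((de - dr) / (dd / 100 * dr))^2
        if (g2 < best) best <- g2
      }
      g[i, j, k] <- sqrt(best)
    }
  g
}

# Flat-field intensity stack helper.
flatStack <- function(value, geom) {
  ProjectionStack(array(value, c(geom@detPixels, length(geom@viewAngles))),
                  "intensity", geom)
}

tinyGeom <- function(nu = 32, nv = 8, nViews = 24, pitch = 6, i0 = 1000)
  ConeBeamGeometry(detPixels = c(nu, nv), pixelPitch = pitch,
                   viewAngles = seq(0, 360 - 360 / nViews,
                                    length.out = nViews), i0 = i0)
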