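#' Tissue class codes used by the correction
#'
#' Integer codes of the segmentation classes: air 1, fat 2, muscle 3,
#' bone 4, applicator 5. Voxels whose HU falls outside every window are
#' labeled air with the confidence flag cleared (they get zero weight in
#' the local filtration).
#'
#' @return Named integer vector.
#' @export
tissueClassCodes <- function() {
  c(air = 1L, fat = 2L, muscle = 3L, bone = 4L, applicator = 5L)
}

#' Extract per-tissue reference LACs from the planning CT
#'
#' For each tissue class the histogram (1 HU bins) of the prior's voxels
#' inside the class window is formed; the mode is taken as the class HU
#' (ties broken toward the window centre) and converted to LAC with the
#' water calibration. A class whose window contains fewer than
#' `minVoxels` voxels either raises an error (default) or falls back to
#' the window midpoint -- useful when an anatomy has a gap-class bulk and
#' a window is legitimately (near-)empty; the fallback LAC is never used
#' downstream in that case because no voxel is labeled with that class.
#'
#' @param prior planning-CT HU [VoxelVolume-class].
#' @param huWindows segmentation windows, see [defaultHuWindows()].
#' @param muW water LAC (1/mm).
#' @param minVoxels minimum voxel count per window.
#' @param fallback `"error"` or `"window_mid"`.
#' @param applicatorHu HU used for the applicator reference LAC.
#' @return A [TissueLACTable-class].
#' @export
extractTissueLACs <- function(prior, huWindows = defaultHuWindows(),
                              muW = 0.02, minVoxels = 50,
                              fallback = c("error", "window_mid"),
                              applicatorHu = 2500) {
  fallback <- match.arg(fallback)
  stopifnot(volUnits(prior) == "HU")
  a <- as.numeric(volArray(prior))
  modes <- vapply(names(huWindows), function(cl) {
    w <- huWindows[[cl]]
    inw <- a[a >= w[1] & a <= w[2]]
    if (length(inw) < minVoxels) {
      if (fallback == "error")
        stop("tissue class '", cl, "' has only ", length(inw),
             " voxels in its window (need >= ", minVoxels, ")")
      mid <- if (is.finite(w[2])) mean(w) else w[1] + 100
      return(mid)
    }
    bins <- round(inw)
    tab <- table(bins)
    best <- as.numeric(names(tab)[tab == max(tab)])
    if (length(best) > 1L) {         # tie: toward the window centre
      ctr <- if (is.finite(w[2])) mean(w) else w[1] + 100
      best <- best[which.min(abs(best - ctr))]
    }
    best
  }, numeric(1))
  TissueLACTable(muAir = huToLacValue(modes[["air"]], muW),
                 muFat = huToLacValue(modes[["fat"]], muW),
                 muMuscle = huToLacValue(modes[["muscle"]], muW),
                 muBone = huToLacValue(modes[["bone"]], muW),
                 muW = muW,
                 muApplicator = huToLacValue(applicatorHu, muW),
                 huWindows = huWindows)
}

#' Estimate the empirical uniform scatter
#'
#' Object pixels are those whose intensity falls below
#' `objectRule * I0`; pooled over all views, the uniform scatter estimate
#' `s_bar` is the nearest-rank percentile such that a fraction
#' `1 - percentile` of the object signals are larger (default: 90% of the
#' object signals exceed `s_bar`).
#'
#' @param stack intensity-domain [ProjectionStack-class].
#' @param objectRule object-pixel threshold as a fraction of I0.
#' @param percentile percentile of the pooled object intensities.
#' @param capFrac optional positivity cap: when non-`NULL`, `sBar` is
#'   additionally bounded by `capFrac` times the minimum object
#'   intensity. The percentile rule presumes the low end of the object
#'   signal is scatter-dominated and fairly uniform across views; when
#'   the scatter floor varies strongly between views the percentile can
#'   exceed the darkest pixels entirely, and subtracting it collapses
#'   them to (soft-cut) zero -- line integrals far above any physical
#'   attenuation that ring through the reconstruction. The cap keeps the
#'   subtraction below every object signal, which is the operational
#'   meaning of "preserve projection positivity". `NULL` (default)
#'   applies the pure percentile rule.
#' @return List with `sBar`, `nObject`, and the rule parameters.
#' @export
estimateUniformScatter <- function(stack, objectRule = 0.9,
                                   percentile = 0.10, capFrac = NULL) {
  stopifnot(projDomain(stack) == "intensity")
  g <- geometry(stack)
  a <- as.numeric(volArray(stack))
  obj <- a[a < objectRule * g@i0]
  if (length(obj) < 0.01 * length(a))
    stop("fewer than 1% object pixels; is there an object in the scan?")
  sBar <- nearestRankPercentile(obj, percentile)
  if (!is.null(capFrac) && is.finite(capFrac))
    sBar <- min(sBar, capFrac * min(obj))
  list(sBar = sBar, nObject = length(obj), objectRule = objectRule,
       percentile = percentile, capFrac = capFrac)
}

#' Soft-cut uniform scatter subtraction
#'
#' Subtracts the uniform scatter estimate while guaranteeing strictly
#' positive corrected intensities: where `I - sBar >= eps * I` the plain
#' difference is used; below that switch the output rolls off as
#' `eps * I * exp((I - sBar - eps * I) / (eps * I))`, which matches value
#' and first derivative at the switch and stays positive.
#'
#' @param stack intensity-domain [ProjectionStack-class].
#' @param sBar uniform scatter estimate (intensity units).
#' @param eps switch fraction in (0, 0.5).
#' @return The corrected intensity stack.
#' @export
softCutSubtract <- function(stack, sBar, eps = 0.05) {
  stopifnot(projDomain(stack) == "intensity", eps > 0, eps < 0.5,
            sBar >= 0)
  a <- volArray(stack)
  out <- softCutValues(a, sBar, eps)
  ProjectionStack(out, "intensity", geometry(stack),
                  scatterTruth = scatterTruth(stack))
}

softCutValues <- function(I, sBar, eps) {
  d <- I - sBar
  lin <- d >= eps * I
  out <- d
  out[!lin] <- eps * I[!lin] *
    exp((d[!lin] - eps * I[!lin]) / (eps * I[!lin]))
  out
}

#' First-pass reconstruction with uniform scatter removal
#'
#' Chains [estimateUniformScatter()], [softCutSubtract()],
#' [toLineIntegral()] and [fdkReconstruct()] to produce the first-pass
#' volume CBCT_c used by the image-domain correction.
#'
#' @param stack raw intensity-domain [ProjectionStack-class].
#' @param grid reconstruction grid (see [fdkReconstruct()]).
#' @param objectRule,percentile,eps,capFrac see the component functions;
#'   `capFrac = Inf` (default) leaves the published percentile rule
#'   untouched.
#' @param filter reconstruction filter.
#' @param floorFrac intensity floor (fraction of I0) applied before the
#'   log. The first pass uses a larger floor than the generic conversion:
#'   pixels whose soft-cut output collapses toward zero (rays through
#'   metal/bone whose intensity lies far below the global uniform
#'   estimate) would otherwise map to line integrals far above any
#'   physically plausible attenuation and ring through the
#'   reconstruction; 1e-4 caps them near the attenuation ceiling of a
#'   pelvis-with-applicator scan.
#' @return List with `cbctC` (LAC [VoxelVolume-class]) and `estimate`
#'   (the uniform scatter estimate actually used).
#' @export
firstPassReconstruct <- function(stack, grid, objectRule = 0.9,
                                 percentile = 0.10, eps = 0.05,
                                 filter = "ramlak", floorFrac = 1e-4,
                                 capFrac = Inf) {
  est <- estimateUniformScatter(stack, objectRule, percentile, capFrac)
  pc <- suppressWarnings(
    toLineIntegral(softCutSubtract(stack, est$sBar, eps), floorFrac))
  list(cbctC = fdkReconstruct(pc, grid, filter), estimate = est)
}

#' Threshold segmentation into tissue classes
#'
#' Labels each voxel by its HU window (air, fat, muscle, bone, plus an
#' optional high-HU applicator class). Voxels outside every window are
#' labeled air with the confidence flag cleared: they contribute zero
#' weight to the local filtration downstream.
#'
#' @param vol HU [VoxelVolume-class] (the planning prior, or the
#'   first-pass CBCT in `cbct` segmentation mode).
#' @param huWindows segmentation windows.
#' @param applicatorHu HU above which a voxel is labeled applicator
#'   (`NULL` disables the class).
#' @return List with `labels` (a `label` [VoxelVolume-class] of
#'   [tissueClassCodes()]) and `confident` (logical array).
#' @export
segmentTissues <- function(vol, huWindows = defaultHuWindows(),
                           applicatorHu = 1000) {
  stopifnot(volUnits(vol) == "HU")
  a <- volArray(vol)
  codes <- tissueClassCodes()
  lab <- array(codes[["air"]], dim(a))
  conf <- array(FALSE, dim(a))
  for (cl in c("air", "fat", "muscle", "bone")) {
    w <- huWindows[[cl]]
    m <- a >= w[1] & a <= w[2]
    lab[m] <- codes[[cl]]
    conf[m] <- TRUE
  }
  if (!is.null(applicatorHu)) {
    m <- a > applicatorHu
    lab[m] <- codes[["applicator"]]
    conf[m] <- TRUE
  }
  list(labels = VoxelVolume(lab, spacingMm(vol), originMm(vol),
                            units = "label"),
       confident = conf)
}

#' Build the piecewise-constant template volume
#'
#' Fills every voxel with the reference LAC of its tissue class. The
#' result has at most five distinct values.
#'
#' @param labels label [VoxelVolume-class] from [segmentTissues()].
#' @param lacTable a [TissueLACTable-class].
#' @return A LAC [VoxelVolume-class].
#' @export
buildTemplate <- function(labels, lacTable) {
  stopifnot(volUnits(labels) == "label")
  codes <- tissueClassCodes()
  lu <- c(lacTable@muAir, lacTable@muFat, lacTable@muMuscle,
          lacTable@muBone, lacTable@muApplicator)
  la <- volArray(labels)
  if (any(!(la %in% codes)))
    stop("unknown label code in label volume")
  VoxelVolume(array(lu[la], dim(la)), spacingMm(labels), originMm(labels),
              units = "LAC")
}

#' Scatter-ratio field
#'
#' `r = template / max(cbctC, epsFloor)`: the per-voxel multiplicative
#' factor that would map the first-pass reconstruction onto the
#' template. The floor keeps the ratio finite where the first-pass volume
#' is near zero; such voxels are later rejected by the sampling mask.
#'
#' @param template,cbctC LAC volumes on one grid.
#' @param epsFloor denominator floor in 1/mm.
#' @return A `ratio` [VoxelVolume-class]; attribute `nFloored` counts the
#'   floored voxels.
#' @export
computeScatterRatio <- function(template, cbctC, epsFloor = 1e-4) {
  stopIfGridMismatch(template, cbctC)
  c0 <- volArray(cbctC)
  nFloored <- sum(c0 < epsFloor)
  r <- volArray(template) / pmax(c0, epsFloor)
  out <- VoxelVolume(r, spacingMm(cbctC), originMm(cbctC), units = "ratio")
  structure(out, nFloored = nFloored)
}

#' Binary sampling mask for the ratio field
#'
#' Implements the mask rule: a voxel is sampled (`f = 1`) unless its
#' ratio magnitude exceeds `r_max`, its per-axial-slice gradient
#' magnitude exceeds `G_max`, or it was not confidently classified (or is
#' classified air: with a near-zero air reference LAC the ratio carries no
#' information there). Both cutoffs are nearest-rank percentiles (default
#' 80%) over the body voxels -- the confidently classified non-air
#' voxels. Ties at exactly the cutoff are kept.
#'
#' @param ratio `ratio` [VoxelVolume-class].
#' @param confident logical array from [segmentTissues()].
#' @param labels label [VoxelVolume-class].
#' @param percentile cutoff percentile.
#' @param applicatorMarginMm exclusion margin around applicator-labeled
#'   voxels. Metal reconstructs with strong near-field streaks that
#'   violate the smooth-multiplicative assumption behind the ratio
#'   field, and the applicator is restored from its reference model in a
#'   separate step anyway, so ratio samples within this distance of the
#'   applicator are discarded.
#' @return List with `mask` (a `mask` [VoxelVolume-class]), `rMax`,
#'   `gMax`, and `body` (the logical body-voxel array used for the
#'   percentiles).
#' @export
buildMask <- function(ratio, confident, labels, percentile = 0.80,
                      applicatorMarginMm = 10) {
  stopifnot(volUnits(ratio) == "ratio")
  codes <- tissueClassCodes()
  la <- volArray(labels)
  body <- confident & (la != codes[["air"]])
  app <- la == codes[["applicator"]]
  if (any(app) && applicatorMarginMm > 0) {
    iter <- ceiling(applicatorMarginMm / min(spacingMm(labels)))
    for (i in seq_len(iter)) app <- dilate3(app)
    body <- body & !app
  }
  if (!any(body)) stop("no body voxels (nothing confidently classified)")
  r <- volArray(ratio)
  rMax <- nearestRankPercentile(abs(r[body]), percentile)
  grad <- sliceGradientMagnitude(r)
  gMax <- nearestRankPercentile(grad[body], percentile)
  f <- body & (abs(r) <= rMax) & (grad <= gMax)
  list(mask = VoxelVolume(array(as.numeric(f), dim(r)), spacingMm(ratio),
                          originMm(ratio), units = "mask"),
       rMax = rMax, gMax = gMax, body = body)
}

#' Local filtration of the masked ratio field
#'
#' Normalized convolution per axial slice:
#' `r_f = conv2(r * f, w) / conv2(f, w)` with a unit-sum 2D Gaussian
#' kernel `w`. Where the denominator falls below `denomFloor` (no samples
#' within the kernel support) the fallback fills in the global mean of
#' the sampled ratio (or leaves the raw ratio with `fallback =
#' "identity"`).
#'
#' @param ratio `ratio` [VoxelVolume-class].
#' @param mask `mask` [VoxelVolume-class] from [buildMask()].
#' @param sigmaMm Gaussian width in mm.
#' @param radiusSigmas kernel truncation radius in units of sigma.
#' @param denomFloor smallest usable denominator (weight sum).
#' @param fallback `"global_mean"` or `"identity"`.
#' @return A `ratio` [VoxelVolume-class] with the smoothed field.
#' @export
localFiltration <- function(ratio, mask, sigmaMm = 12, radiusSigmas = 3,
                            denomFloor = 1e-3,
                            fallback = c("global_mean", "identity")) {
  fallback <- match.arg(fallback)
  stopIfGridMismatch(ratio, mask)
  r <- volArray(ratio)
  f <- volArray(mask)
  if (!any(f > 0)) stop("mask rejects every voxel; nothing to sample")
  sp <- spacingMm(ratio)
  d <- dim(r)
  sigU <- sigmaMm / sp[1]; sigV <- sigmaMm / sp[2]
  Ku <- convBandMatrix(d[1], gaussianTaps(sigU, ceiling(radiusSigmas * sigU)))
  Kv <- convBandMatrix(d[2], gaussianTaps(sigV, ceiling(radiusSigmas * sigV)))
  globalMean <- mean(r[f > 0])
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    num <- sepConv2(r[, , k] * f[, , k], Ku, Kv)
    den <- sepConv2(f[, , k], Ku, Kv)
    rf <- num / pmax(den, denomFloor)
    bad <- den < denomFloor
    rf[bad] <- if (fallback == "global_mean") globalMean else r[, , k][bad]
    out[, , k] <- rf
  }
  VoxelVolume(out, sp, originMm(ratio), units = "ratio")
}

#' Apply the smoothed ratio
#'
#' `CBCT_fc = CBCT_c * r_f`, returned in LAC together with an HU view.
#'
#' @param cbctC first-pass LAC volume.
#' @param ratioSmooth smoothed ratio field.
#' @param muW water LAC for the HU view.
#' @return List with `lac` and `hu` [VoxelVolume-class] objects.
#' @export
applyRatio <- function(cbctC, ratioSmooth, muW = 0.02) {
  stopIfGridMismatch(cbctC, ratioSmooth)
  lac <- VoxelVolume(volArray(cbctC) * volArray(ratioSmooth),
                     spacingMm(cbctC), originMm(cbctC), units = "LAC")
  list(lac = lac, hu = lacToHu(lac, muW))
}

#' Substitute the applicator from a reference model
#'
#' The high-HU applicator in the corrected volume is replaced by the
#' (rigidly transformed) reference applicator model: target applicator
#' voxels above `thresholdHu` are cleared to a local soft-tissue estimate
#' and the transformed model's applicator voxels are written in. The
#' rigid transform is either supplied (`"identity"`, or a length-3 mm
#' translation) or estimated from the two thresholded point clouds by
#' centroid plus principal-axis alignment (no scaling).
#'
#' @param volHu corrected HU volume.
#' @param modelHu applicator model HU volume on the same grid (air
#'   background plus the applicator).
#' @param thresholdHu applicator threshold (HU).
#' @param transform `"estimate"`, `"identity"`, or a numeric length-3
#'   translation in mm (model -> target).
#' @return The HU volume with the substituted applicator; attribute
#'   `transform` carries the translation/rotation used.
#' @export
substituteApplicator <- function(volHu, modelHu, thresholdHu = 1000,
                                 transform = "identity") {
  stopIfGridMismatch(volHu, modelHu)
  a <- volArray(volHu); m <- volArray(modelHu)
  tgt <- a > thresholdHu; src <- m > thresholdHu
  if (!any(src)) stop("no voxels above threshold in the model volume")
  # estimating a transform needs both point clouds; with a known
  # transform an applicator-free (heavily suppressed) target is fine
  if (!any(tgt) && identical(transform, "estimate"))
    stop("no voxels above threshold in the target volume")
  d <- dim(a); sp <- spacingMm(volHu); or <- originMm(volHu)
  pts <- function(sel) {
    ijk <- which(sel, arr.ind = TRUE)
    sweep(sweep(ijk - 1, 2, sp, "*"), 2, or, "+")
  }
  R <- diag(3); tr <- c(0, 0, 0)
  if (is.numeric(transform)) {
    tr <- transform
  } else if (identical(transform, "estimate")) {
    P <- pts(src); Q <- pts(tgt)
    cs <- colMeans(P); ct <- colMeans(Q)
    axis1 <- eigen(stats::cov(P))$vectors[, 1]
    axis2 <- eigen(stats::cov(Q))$vectors[, 1]
    if (sum(axis1 * axis2) < 0) axis2 <- -axis2
    v <- c(axis1[2] * axis2[3] - axis1[3] * axis2[2],
           axis1[3] * axis2[1] - axis1[1] * axis2[3],
           axis1[1] * axis2[2] - axis1[2] * axis2[1])
    s <- sqrt(sum(v^2)); cth <- sum(axis1 * axis2)
    if (s > 1e-9) {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    }
    tr <- ct - as.numeric(R %*% cs)
  } else if (!identical(transform, "identity")) {
    stop("transform must be 'identity', 'estimate', or a translation")
  }
  # clear target applicator voxels to the surrounding-tissue median
  ring <- dilate3(tgt) & !tgt
  fillVal <- if (any(ring)) stats::median(a[ring]) else 0
  out <- a
  out[tgt] <- fillVal
  # write transformed model applicator (map target voxels back to model)
  ijk <- which(array(TRUE, d), arr.ind = TRUE)
  # restrict to a bounding box around the transformed model to stay cheap
  Psrc <- pts(src)
  Ptrans <- sweep(Psrc %*% t(R), 2, tr, "+")
  lo <- apply(Ptrans, 2, min) - sp; hi <- apply(Ptrans, 2, max) + sp
  co <- gridCoords(d, sp, or)
  inBox <- which(array(TRUE, d), arr.ind = TRUE)
  keep <- co$x[inBox[, 1]] >= lo[1] & co$x[inBox[, 1]] <= hi[1] &
    co$y[inBox[, 2]] >= lo[2] & co$y[inBox[, 2]] <= hi[2] &
    co$z[inBox[, 3]] >= lo[3] & co$z[inBox[, 3]] <= hi[3]
  inBox <- inBox[keep, , drop = FALSE]
  if (nrow(inBox)) {
    Pw <- cbind(co$x[inBox[, 1]], co$y[inBox[, 2]], co$z[inBox[, 3]])
    Pm <- sweep(Pw, 2, tr, "-") %*% R   # inverse rigid map (R orthogonal)
    idx <- sweep(Pm, 2, or, "-")
    idx <- sweep(idx, 2, sp, "/") + 1
    nn <- round(idx)
    ok <- nn[, 1] >= 1 & nn[, 1] <= d[1] & nn[, 2] >= 1 & nn[, 2] <= d[2] &
      nn[, 3] >= 1 & nn[, 3] <= d[3]
    if (any(ok)) {
      vals <- m[cbind(nn[ok, 1], nn[ok, 2], nn[ok, 3])]
      sel <- vals > thresholdHu
      if (any(sel)) {
        tgtIdx <- inBox[ok, , drop = FALSE][sel, , drop = FALSE]
        out[cbind(tgtIdx[, 1], tgtIdx[, 2], tgtIdx[, 3])] <- vals[sel]
      }
    }
  }
  res <- VoxelVolume(out, sp, or, units = "HU")
  structure(res, transform = list(rotation = R, translation = tr))
}

# 6-connected binary dilation.
dilate3 <- function(m) {
  d <- dim(m); out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Default correction configuration
#'
#' All tunable parameters of [correctCBCT()] with their defaults: HU
#' segmentation windows, water LAC, object-pixel and percentile rules for
#' the uniform scatter estimate, the soft-cut fraction, the ratio floor,
#' mask percentile, filtration width and fallback, the applicator
#' threshold, and the segmentation source (`"prior"` transfers the
#' planning-CT segmentation, `"cbct"` thresholds the first-pass volume).
#'
#' @return Named list of parameters.
#' @export
defaultCorrectionConfig <- function() {
  list(huWindows = defaultHuWindows(), muW = 0.02, objectRule = 0.9,
       scatterPercentile = 0.10, softCutEps = 0.05, filter = "ramlak",
       floorFrac = 1e-4, sBarCapFrac = Inf, epsFloor = 1e-4,
       maskPercentile = 0.80, sigmaMm = 10,
       radiusSigmas = 3, denomFloor = 1e-3, fallback = "global_mean",
       applicatorMarginMm = 10,
       applicatorHu = 1000, segmentSource = "prior", minVoxelsPerClass = 50,
       lacFallback = "window_mid", applicatorRefHu = 2500)
}

#' Six-step hybrid-domain scatter correction
#'
#' Runs the full correction on a raw intensity-domain projection stack
#' with a planning-CT prior:
#' \enumerate{
#'   \item reference tissue LACs from the prior histogram;
#'   \item uniform scatter subtraction (soft-cut) and first-pass FDK
#'     reconstruction CBCT_c;
#'   \item threshold segmentation (of the prior by default) and template
#'     CBCT_t;
#'   \item scatter ratio r = CBCT_t / CBCT_c and sampling mask f;
#'   \item local filtration to the smoothed ratio r_f;
#'   \item final corrected volume CBCT_fc = CBCT_c * r_f.
#' }
#'
#' @param stack raw intensity [ProjectionStack-class].
#' @param prior planning-CT HU [VoxelVolume-class]. With the default
#'   `segmentSource = "prior"` its grid must match the reconstruction
#'   grid (the phantom does not deform; the prior-to-CBCT mapping is the
#'   identity), or be croppable to it.
#' @param grid reconstruction grid (see [fdkReconstruct()]); default: the
#'   prior's grid.
#' @param config parameter list, see [defaultCorrectionConfig()].
#' @param verbose log each stage.
#' @return A [CorrectionResult-class].
#' @export
correctCBCT <- function(stack, prior, grid = NULL,
                        config = defaultCorrectionConfig(),
                        verbose = FALSE) {
  cfg <- utils::modifyList(defaultCorrectionConfig(), config)
  say <- function(...) if (verbose) message("[correctCBCT] ", ...)
  if (is.null(grid))
    grid <- list(dim = dim(volArray(prior)), spacing = spacingMm(prior),
                 origin = originMm(prior))
  if (length(grid$spacing) == 1L) grid$spacing <- rep(grid$spacing, 3L)
  if (is.null(grid$origin)) grid$origin <- -(grid$dim - 1) / 2 * grid$spacing

  say("step 1: reference LACs from the prior histogram")
  lacTable <- extractTissueLACs(prior, cfg$huWindows, cfg$muW,
                                minVoxels = cfg$minVoxelsPerClass,
                                fallback = cfg$lacFallback,
                                applicatorHu = cfg$applicatorRefHu)

  say("step 2: uniform scatter subtraction + first-pass FDK")
  fp <- firstPassReconstruct(stack, grid, cfg$objectRule,
                             cfg$scatterPercentile, cfg$softCutEps,
                             cfg$filter, cfg$floorFrac, cfg$sBarCapFrac)
  cbctC <- fp$cbctC

  say("step 3: segmentation (source = ", cfg$segmentSource, ") + template")
  segVol <- if (cfg$segmentSource == "prior") {
    if (identical(dim(volArray(prior)), as.integer(grid$dim))) prior
    else cropToGrid(prior, grid$dim, grid$spacing, grid$origin)
  } else lacToHu(cbctC, cfg$muW)
  seg <- segmentTissues(segVol, cfg$huWindows, cfg$applicatorHu)
  template <- buildTemplate(seg$labels, lacTable)

  say("step 4: scatter ratio + mask")
  ratio <- computeScatterRatio(template, cbctC, cfg$epsFloor)
  mk <- buildMask(ratio, seg$confident, seg$labels, cfg$maskPercentile,
                  cfg$applicatorMarginMm)

  say("step 5: local filtration (sigma = ", cfg$sigmaMm, " mm)")
  rf <- localFiltration(ratio, mk$mask, cfg$sigmaMm, cfg$radiusSigmas,
                        cfg$denomFloor, cfg$fallback)

  say("step 6: apply smoothed ratio")
  fc <- applyRatio(cbctC, rf, cfg$muW)

  methods::new("CorrectionResult", cbctFc = fc$lac, cbctFcHu = fc$hu,
               cbctC = cbctC, sBar = fp$estimate$sBar, labels = seg$labels,
               confident = seg$confident, template = template,
               ratio = ratio, ratioSmooth = rf, mask = mk$mask,
               rMax = mk$rMax, gMax = mk$gMax, lacTable = lacTable)
}
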