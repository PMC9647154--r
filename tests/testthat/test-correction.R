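makePrior <- function(values, dim = c(12, 12, 4)) {
  VoxelVolume(array(values, dim), spacing = 2, units = "HU")
}

test_that("tissue LACs come from windowed histogram modes via the water calibration", {
  # a synthetic prior with one block per class
  a <- array(-1000, c(20, 20, 4))
  a[1:10, 1:10, ] <- 50      # muscle
  a[11:20, 1:10, ] <- -100   # adipose
  a[1:10, 11:20, ] <- 400    # bone
  prior <- VoxelVolume(a, spacing = 2, units = "HU")
  tab <- extractTissueLACs(prior, minVoxels = 10)
  expect_equal(tab@muMuscle, 0.02 * 1.05, tolerance = 1e-12)
  expect_equal(tab@muAir, 0, tolerance = 1e-12)
  expect_equal(tab@muFat, huToLac(makePrior(-100), 0.02)@data[1],
               tolerance = 1e-12)
  # voxels outside every window change nothing
  a2 <- a; a2[15:20, 15:20, ] <- 150    # gap-class values
  tab2 <- extractTissueLACs(VoxelVolume(a2, spacing = 2, units = "HU"),
                            minVoxels = 10)
  expect_equal(tab2@muMuscle, tab@muMuscle)
  expect_equal(tab2@muBone, tab@muBone)
  # under-populated class errors by default, window-mid fallback works
  a3 <- a; a3[a3 == 50] <- 150
  p3 <- VoxelVolume(a3, spacing = 2, units = "HU")
  expect_error(extractTissueLACs(p3, minVoxels = 10), "muscle")
  tab3 <- extractTissueLACs(p3, minVoxels = 10, fallback = "window_mid")
  expect_equal(tab3@muMuscle, 0.021, tolerance = 1e-12)  # window midpoint 50 HU
  # ordering invariant holds whenever the window ordering holds
  expect_true(tab@muAir < tab@muFat && tab@muFat < tab@muMuscle &&
                tab@muMuscle < tab@muBone)
})

test_that("uniform scatter estimate implements the nearest-rank object percentile", {
  g <- tinyGeom(nu = 10, nv = 2, nViews = 4, i0 = 1000)
  # object pixels {10, 20, ..., 100} in every row and view (< 0.9 * I0)
  a <- array(rep(seq(10, 100, 10), 8), c(10, 2, 4))
  st <- ProjectionStack(a, "intensity", g)
  est <- estimateUniformScatter(st)
  expect_equal(est$sBar, 10)
  # adding a constant shifts the estimate by exactly that constant
  st2 <- ProjectionStack(a + 7, "intensity", g)
  expect_equal(estimateUniformScatter(st2)$sBar, 17)
  # a scan with no object pixels is refused
  flat <- flatStack(950, g)
  expect_error(estimateUniformScatter(flat), "object")
  # the positivity cap bounds the estimate by the darkest object pixel
  capped <- estimateUniformScatter(st, capFrac = 0.5)
  expect_equal(capped$sBar, 5)
})

test_that("soft-cut subtraction is positive, exact in closed form, and continuous", {
  g <- tinyGeom(nu = 3, nv = 2, nViews = 4, i0 = 1000)
  a <- array(c(100, 20, 50), c(3, 2, 4))
  st <- ProjectionStack(a, "intensity", g)
  out <- volArray(softCutSubtract(st, sBar = 20, eps = 0.05))
  expect_equal(out[1, 1, 1], 80)                      # linear branch
  out2 <- volArray(softCutSubtract(st, sBar = 19.5, eps = 0.05))
  expect_equal(out2[2, 1, 1], 1 * exp(-0.5), tolerance = 1e-12)
  # sBar = 0 is the identity
  expect_identical(volArray(softCutSubtract(st, 0)), a)
  # continuity across the branch switch
  I <- 100; eps <- 0.05
  sw <- I * (1 - eps)       # switch point in sBar
  lo <- cbctscatter:::softCutValues(I, sw - 1e-8, eps)
  hi <- cbctscatter:::softCutValues(I, sw + 1e-8, eps)
  expect_lt(abs(lo - hi), 1e-6)
  # output is strictly positive even for sBar > I
  deep <- cbctscatter:::softCutValues(c(5, 10), 50, eps)
  expect_true(all(deep > 0))
})

test_that("threshold segmentation follows the HU windows and flags the gap", {
  v <- makePrior(c(-800, 50, 100, -90, 300, 2600), dim = c(6, 1, 1))
  seg <- segmentTissues(v)
  codes <- tissueClassCodes()
  lab <- volArray(seg$labels)[, 1, 1]
  expect_equal(lab, unname(codes[c("air", "muscle", "air", "fat", "bone",
                                   "applicator")]))
  expect_equal(seg$confident[, 1, 1], c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("the template is piecewise constant in the class LACs", {
  tab <- TissueLACTable(0, 0.0178, 0.021, 0.0239, muW = 0.02)
  v <- makePrior(c(-800, 50, -90, 300), dim = c(4, 1, 1))
  seg <- segmentTissues(v)
  tpl <- buildTemplate(seg$labels, tab)
  expect_equal(volArray(tpl)[, 1, 1], c(0, 0.021, 0.0178, 0.0239))
  expect_lte(length(unique(as.numeric(volArray(tpl)))), 5)
  # a different table relabels the same regions consistently
  tabSwap <- TissueLACTable(0, 0.016, 0.019, 0.0239, muW = 0.02)
  tplSwap <- buildTemplate(seg$labels, tabSwap)
  expect_equal(volArray(tplSwap)[2, 1, 1], 0.019)
  expect_equal(volArray(tplSwap)[3, 1, 1], 0.016)
  # unknown labels are refused
  bad <- VoxelVolume(array(9L, c(2, 2, 1)), spacing = 2, units = "label")
  expect_error(buildTemplate(bad, tab), "label")
})

test_that("the scatter ratio is floored and exact on constructed volumes", {
  t <- VoxelVolume(array(0.02, c(4, 4, 2)), spacing = 2, units = "LAC")
  c1 <- VoxelVolume(array(0.02, c(4, 4, 2)), spacing = 2, units = "LAC")
  expect_equal(volArray(computeScatterRatio(t, c1)),
               array(1, c(4, 4, 2)))
  c2 <- VoxelVolume(array(0.01, c(4, 4, 2)), spacing = 2, units = "LAC")
  expect_equal(volArray(computeScatterRatio(t, c2)),
               array(2, c(4, 4, 2)))
  cz <- VoxelVolume(array(c(0, rep(0.02, 31)), c(4, 4, 2)), spacing = 2,
                    units = "LAC")
  r <- computeScatterRatio(t, cz, epsFloor = 1e-4)
  expect_equal(volArray(r)[1, 1, 1], 0.02 / 1e-4)
  expect_equal(attr(r, "nFloored"), 1L)
})

test_that("the sampling mask keeps ties, rejects spikes and unclassified voxels", {
  d <- c(9, 9, 3)
  codes <- tissueClassCodes()
  labels <- VoxelVolume(array(codes[["muscle"]], d), spacing = 2,
                        units = "label")
  conf <- array(TRUE, d)
  # constant field, all confident: gradient 0, |r| at the cutoff -> all kept
  rconst <- VoxelVolume(array(1.3, d), spacing = 2, units = "ratio")
  mk <- buildMask(rconst, conf, labels)
  expect_true(all(volArray(mk$mask) == 1))
  expect_equal(mk$rMax, 1.3)
  # a spike is rejected, and its gradient shadow with it
  rsp <- array(1, d); rsp[5, 5, 2] <- 100
  mk2 <- buildMask(VoxelVolume(rsp, spacing = 2, units = "ratio"),
                   conf, labels)
  f <- volArray(mk2$mask)
  expect_equal(f[5, 5, 2], 0)                    # the spike itself
  expect_equal(f[4, 5, 2], 0)                    # gradient neighbours
  expect_equal(f[6, 5, 2], 0)
  expect_equal(f[2, 2, 2], 1)                    # far voxels survive
  # unclassified voxels are zero regardless of their ratio value
  conf3 <- conf; conf3[3, 3, 1] <- FALSE
  mk3 <- buildMask(rconst, conf3, labels)
  expect_equal(volArray(mk3$mask)[3, 3, 1], 0)
  # mask selectivity: kept fraction of candidates <= 80% on rough fields
  set.seed(9)
  rr <- VoxelVolume(array(runif(prod(d), 0.5, 2), d), spacing = 2,
                    units = "ratio")
  mk4 <- buildMask(rr, conf, labels)
  expect_lte(mean(volArray(mk4$mask)[conf]), 0.80)
})

test_that("local filtration equals the brute-force weighted-average oracle", {
  set.seed(21)
  n <- 16
  r2d <- matrix(runif(n * n, 0.5, 2), n, n)
  f2d <- matrix(rbinom(n * n, 1, 0.6), n, n)
  sigmaMm <- 6; spacing <- 2
  sigmaPx <- sigmaMm / spacing
  radiusPx <- ceiling(3 * sigmaPx)
  ratio <- VoxelVolume(array(r2d, c(n, n, 1)), spacing, units = "ratio")
  mask <- VoxelVolume(array(f2d, c(n, n, 1)), spacing, units = "mask")
  rf <- localFiltration(ratio, mask, sigmaMm = sigmaMm, denomFloor = 1e-3)
  oracle <- filtrationOracle2D(r2d, f2d, sigmaPx, radiusPx, 1e-3,
                               mean(r2d[f2d == 1]))
  expect_lt(max(abs(volArray(rf)[, , 1] - oracle)), 1e-6)
})

test_that("local filtration interpolates gaps and falls back on empty slices", {
  n <- 7
  rconst <- array(1.7, c(n, n, 2))
  f <- array(1, c(n, n, 2))
  f[4, 4, 1] <- 0              # one masked-out pixel
  f[, , 2] <- 0                # a slice with no samples at all
  rf <- localFiltration(VoxelVolume(rconst, 2, units = "ratio"),
                        VoxelVolume(f, 2, units = "mask"), sigmaMm = 4)
  expect_equal(volArray(rf)[4, 4, 1], 1.7, tolerance = 1e-9)
  expect_equal(volArray(rf)[, , 2], matrix(1.7, n, n), tolerance = 1e-9)
  # identity fallback leaves the raw ratio on dead slices
  rvar <- rconst; rvar[, , 2] <- 2.5
  rf2 <- localFiltration(VoxelVolume(rvar, 2, units = "ratio"),
                         VoxelVolume(f, 2, units = "mask"), sigmaMm = 4,
                         fallback = "identity")
  expect_equal(volArray(rf2)[, , 2], matrix(2.5, n, n))
  # an all-zero mask is refused
  expect_error(localFiltration(VoxelVolume(rconst, 2, units = "ratio"),
                               VoxelVolume(array(0, dim(rconst)), 2,
                                           units = "mask"), 4),
               "nothing to sample")
})

test_that("applying the smoothed ratio scales the volume and its HU view", {
  c1 <- VoxelVolume(array(0.02, c(4, 4, 2)), 2, units = "LAC")
  rf1 <- VoxelVolume(array(1, c(4, 4, 2)), 2, units = "ratio")
  out <- applyRatio(c1, rf1)
  expect_equal(volArray(out$lac), volArray(c1))
  rf2 <- VoxelVolume(array(2, c(4, 4, 2)), 2, units = "ratio")
  out2 <- applyRatio(c1, rf2)
  expect_equal(volArray(out2$lac), 2 * volArray(c1))
  expect_equal(volArray(out2$hu)[1, 1, 1], 1000)
})

test_that("applicator substitution restores the model and estimates rigid shifts", {
  grid <- list(dim = c(40, 40, 24), spacing = c(2, 2, 2))
  app <- defaultApplicatorSpec()
  app$channel <- rbind(c(0, 0, -16), c(0, 0, 16))
  model <- cbctscatter:::applicatorModelVolume(app, grid)
  # identical applicators, identity transform: applicator region unchanged
  body <- VoxelVolume(array(100, grid$dim), grid$spacing, units = "HU")
  vol <- volArray(body)
  vol[volArray(model) > 1000] <- 2500
  target <- VoxelVolume(vol, grid$spacing, units = "HU")
  out <- substituteApplicator(target, model, transform = "identity")
  expect_equal(volArray(out)[volArray(model) > 1000],
               volArray(model)[volArray(model) > 1000])
  # a known 6 mm translation is recovered within one voxel
  app2 <- app; app2$channel <- app$channel + rep(c(6, 0, 0), each = 2)
  shifted <- cbctscatter:::applicatorModelVolume(app2, grid)
  tvol <- volArray(body); tvol[volArray(shifted) > 1000] <- 2500
  target2 <- VoxelVolume(tvol, grid$spacing, units = "HU")
  out2 <- substituteApplicator(target2, model, transform = "estimate")
  tr <- attr(out2, "transform")$translation
  expect_lt(max(abs(tr - c(6, 0, 0))), 2)
  # no applicator anywhere: estimation is impossible
  expect_error(substituteApplicator(body, model, transform = "estimate"),
               "threshold")
})

test_that("correction is near-idempotent on scatter-free scans and reproducible", {
  cfg <- smallConfig()
  spec <- defaultPhantomSpec(cfg$phantom$gridShape, cfg$phantom$voxelSize,
                             cfg$phantom$bodyAxes, cfg$phantom$textureSd)
  ph <- makePelvisPhantom(spec, seed = 5)
  ph <- insertApplicator(ph$label, ph$hu, defaultApplicatorSpec(), spec)
  prior <- makePlanningCT(ph$hu, cfg$phantom$priorNoiseSd, seed = 6)
  geom <- ConeBeamGeometry(cfg$geometry$sad, cfg$geometry$sdd,
                           cfg$geometry$detPixels, cfg$geometry$pixelPitch,
                           seq(0, 358, 2), cfg$geometry$i0)
  clean <- toIntensity(forwardProject(huToLac(ph$hu), geom))
  pd <- dim(volArray(prior))
  grid <- list(dim = c(pd[1], pd[2], cfg$recon$zDim),
               spacing = spacingMm(prior))
  grid$origin <- originMm(prior) +
    c(0, 0, (pd[3] - grid$dim[3]) / 2 * grid$spacing[3])
  # the positivity cap collapses the uniform estimate to ~0 on a clean
  # scan, so the first pass is essentially the plain reconstruction
  ccfg <- defaultCorrectionConfig(); ccfg$sBarCapFrac <- 0.9
  res <- correctCBCT(clean, prior, grid, ccfg)
  # without scatter the smoothed ratio sits near unity; the few-percent
  # residual is the correction repairing the reconstruction's own small
  # interior bias, so CBCT_fc may differ from CBCT_c by that amount but
  # must not be further from the truth
  body <- res@confident & volArray(res@labels) != tissueClassCodes()[["air"]]
  relDiff <- abs(volArray(res@cbctFc)[body] / volArray(res@cbctC)[body] - 1)
  expect_lt(median(relDiff), 0.05)
  gt <- cbctscatter:::cropToGrid(huToLac(ph$hu), grid$dim, grid$spacing,
                                 grid$origin)
  errFc <- abs(volArray(res@cbctFc)[body] - volArray(gt)[body])
  errC <- abs(volArray(res@cbctC)[body] - volArray(gt)[body])
  expect_lte(median(errFc), median(errC) * 1.05)
  # bit-reproducibility
  res2 <- correctCBCT(clean, prior, grid, ccfg)
  expect_identical(volArray(res2@cbctFc), volArray(res@cbctFc))
  expect_identical(res2@sBar, res@sBar)
})
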