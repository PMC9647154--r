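test_that("zero-noise phantom reproduces configured means and air background", {
  spec <- defaultPhantomSpec(gridShape = c(64, 48, 8), voxelSize = 6,
                             textureSd = 0)
  ph <- makePelvisPhantom(spec, seed = 1)
  hu <- volArray(ph$hu)
  la <- volArray(ph$label)
  ctr <- round(dim(hu) / 2)
  expect_equal(hu[ctr[1], 2, ctr[3]], -1000)   # outside body ellipse
  expect_equal(la[ctr[1], 2, ctr[3]], spec$labels[["air"]])
  # locate a muscle voxel and check the configured mean exactly
  m <- which(la == spec$labels[["muscle"]], arr.ind = TRUE)[1, ]
  expect_equal(hu[m[1], m[2], m[3]], 130)
  # ROI means of the zero-noise phantom equal structure means
  rois <- roiCatalog(ph$label, spec)
  st <- roiStats(ph$hu, rois)
  expect_equal(st$mean, c(rep(130, 6), -112, 191, 196, 199))
  expect_equal(st$sd, rep(0, 10))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- defaultPhantomSpec(gridShape = c(48, 36, 8), voxelSize = 8)
  a <- makePelvisPhantom(spec, seed = 7)
  b <- makePelvisPhantom(spec, seed = 7)
  expect_identical(volArray(a$hu), volArray(b$hu))
  expect_identical(volArray(a$label), volArray(b$label))
  c <- makePelvisPhantom(spec, seed = 8)
  expect_false(identical(volArray(a$hu), volArray(c$hu)))
})

test_that("planning CT adds calibrated Gaussian noise", {
  spec <- defaultPhantomSpec(gridShape = c(48, 36, 8), voxelSize = 8,
                             textureSd = 0)
  ph <- makePelvisPhantom(spec, seed = 1)
  expect_identical(volArray(makePlanningCT(ph$hu, 0, 1)), volArray(ph$hu))
  pr <- makePlanningCT(ph$hu, 10, seed = 3)
  resid <- volArray(pr) - volArray(ph$hu)
  expect_lt(abs(sd(resid) - 10), 1)
  expect_lt(abs(mean(resid)), 1)
})

test_that("prior histogram peaks at the muscle mean", {
  spec <- defaultPhantomSpec(gridShape = c(96, 72, 24), voxelSize = 4)
  ph <- makePelvisPhantom(spec, seed = 2)
  pr <- makePlanningCT(ph$hu, 5, seed = 3)
  v <- round(volArray(pr))
  v <- v[v >= 100 & v <= 160]
  tab <- table(v)
  mode <- as.numeric(names(tab)[which.max(tab)])
  expect_lt(abs(mode - 130), 2)
})

test_that("applicator insertion fills the channel tube", {
  # 1.5 mm voxels: the 3 mm tube needs sub-radius voxels for its
  # rasterized volume to sit within 15% of the analytic cylinder
  spec <- defaultPhantomSpec(gridShape = c(256, 160, 48), voxelSize = 1.5,
                             textureSd = 0)
  app <- defaultApplicatorSpec()
  ph <- makePelvisPhantom(spec, seed = 1)
  out <- insertApplicator(ph$label, ph$hu, app, spec)
  hu <- volArray(out$hu)
  # voxel on the channel axis
  i <- round((c(0, 2, 0) - originMm(out$hu)) / spacingMm(out$hu)) + 1
  expect_equal(hu[i[1], i[2], i[3]], app$huValue)
  # voxel far from the channel is unchanged
  j <- round((c(60, 40, 0) - originMm(out$hu)) / spacingMm(out$hu)) + 1
  expect_equal(hu[j[1], j[2], j[3]], volArray(ph$hu)[j[1], j[2], j[3]])
  # voxel count close to the analytic volume (tube plus the rounded end
  # caps of the distance-to-segment rasterization)
  nApp <- sum(volArray(out$label) == spec$labels[["applicator"]])
  L <- sqrt(sum((app$channel[2, ] - app$channel[1, ])^2))
  analytic <- (pi * app$radius^2 * L + 4 / 3 * pi * app$radius^3) /
    prod(spacingMm(out$hu))
  expect_lt(abs(nApp / analytic - 1), 0.15)
  # applicator HU strictly exceeds every tissue HU
  expect_true(app$huValue > max(vapply(spec$structures, `[[`, 1, "hu")))
  # sub-voxel radius is rejected
  app2 <- app; app2$radius <- 1
  expect_error(insertApplicator(ph$label, ph$hu, app2, spec), "radius")
})

test_that("ROI catalog matches the published census layout and is pure", {
  spec <- defaultPhantomSpec(gridShape = c(128, 96, 48), voxelSize = 3)
  ph <- makePelvisPhantom(spec, seed = 1)
  rois <- roiCatalog(ph$label, spec)
  expect_equal(nrow(rois), 10)
  expect_equal(sum(rois$tissue == "muscle"), 6)
  expect_setequal(unique(rois$tissue),
                  c("muscle", "adipose", "bladder", "uterus", "rectum"))
  expect_equal(sum(rois$role == "target"), 1)
  expect_equal(sum(rois$role == "background"), 1)
  # purity is enforced internally; an absent structure raises
  la <- volArray(ph$label)
  la[la == spec$labels[["rectum"]]] <- spec$labels[["muscle"]]
  broken <- VoxelVolume(la, spacingMm(ph$label), originMm(ph$label), "label")
  expect_error(roiCatalog(broken, spec), "rectum")
})

test_that("window thresholding of the zero-noise truth recovers non-gap labels", {
  spec <- defaultPhantomSpec(gridShape = c(96, 72, 24), voxelSize = 4,
                             textureSd = 0)
  ph <- makePelvisPhantom(spec, seed = 1)
  seg <- segmentTissues(ph$hu, applicatorHu = NULL)
  codes <- tissueClassCodes()
  la <- volArray(ph$label)
  sl <- volArray(seg$labels)
  # expected window class per structure (muscle at 130 HU is gap-class)
  expected <- c(air = codes[["air"]], adipose = codes[["fat"]],
                bone_cortical = codes[["bone"]],
                bone_cancellous = codes[["bone"]],
                bladder = codes[["bone"]], uterus = codes[["bone"]],
                rectum = codes[["bone"]], intestine = codes[["bone"]])
  for (nm in names(expected)) {
    m <- la == spec$labels[[nm]]
    expect_gt(mean(sl[m] == expected[[nm]]), 0.99)
  }
  # gap-class muscle: labeled air and flagged unclassified
  m <- la == spec$labels[["muscle"]]
  expect_true(all(sl[m] == codes[["air"]]))
  expect_true(all(!seg$confident[m]))
})

test_that("structure masks on arbitrary grids give exact analytic volumes", {
  spec <- defaultPhantomSpec()
  grid <- list(dim = c(80, 80, 80), spacing = c(1, 1, 1))
  grid$origin <- c(-39.5, -84.5, -39.5)  # centred on the bladder
  m <- structureMask(spec, "bladder", grid$dim, grid$spacing, grid$origin)
  analytic <- 4 / 3 * pi * 30 * 22 * 30
  expect_lt(abs(sum(m) / analytic - 1), 0.02)
  expect_error(structureMask(spec, "femur", grid$dim, grid$spacing,
                             grid$origin), "femur")
})
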