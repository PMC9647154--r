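vacuumLac <- function(dimn = c(40, 40, 40), sp = 4, mu = 0)
  VoxelVolume(array(mu, dimn), spacing = sp, units = "LAC")

test_that("the dwell plan steps back from the channel tip", {
  plan <- dwellPlan()
  expect_equal(nrow(plan$positions), 10)
  expect_equal(plan$times, rep(30, 10))
  steps <- sqrt(rowSums(diff(plan$positions)^2))
  expect_equal(steps, rep(5, 9), tolerance = 1e-12)
  expect_equal(plan$positions[1, ], c(0, 2, 32))   # tip first
  expect_error(dwellPlan(n = 20), "channel length")
})

test_that("toy dose follows inverse square with exponential attenuation", {
  plan <- list(positions = matrix(c(0, 0, 0), 1), times = 30, strength = 25)
  grid <- list(dim = c(41, 1, 1), spacing = c(1, 1, 1),
               origin = c(-20, 0, 0))
  # vacuum: pure inverse square
  d0 <- toyDose(vacuumLac(), plan, grid, dMin = 0.1, step = 0.5)
  at <- function(dose, x) volArray(dose)[x + 21, 1, 1]
  expect_equal(at(d0, 10) / at(d0, 20), 4, tolerance = 1e-6)
  # uniform mu = 0.02/mm: extra exp(-0.2) at 10 mm
  d1 <- toyDose(vacuumLac(mu = 0.02), plan, grid, dMin = 0.1, step = 0.25)
  expect_equal(at(d1, 10) / at(d0, 10), exp(-0.2), tolerance = 0.01)
  # doubling dwell time doubles dose everywhere
  plan2 <- plan; plan2$times <- 60
  d2 <- toyDose(vacuumLac(), plan2, grid, dMin = 0.1, step = 0.5)
  expect_equal(volArray(d2), 2 * volArray(d0), tolerance = 1e-12)
  # superposition over dwells is exact
  planA <- list(positions = matrix(c(0, 0, 5), 1), times = 30, strength = 25)
  planB <- list(positions = matrix(c(0, 0, -5), 1), times = 30, strength = 25)
  planAB <- list(positions = rbind(planA$positions, planB$positions),
                 times = c(30, 30), strength = 25)
  dA <- toyDose(vacuumLac(), planA, grid, dMin = 0.1)
  dB <- toyDose(vacuumLac(), planB, grid, dMin = 0.1)
  dAB <- toyDose(vacuumLac(), planAB, grid, dMin = 0.1)
  expect_equal(volArray(dAB), volArray(dA) + volArray(dB),
               tolerance = 1e-12)
  # dwells outside the attenuation volume are refused
  planOut <- list(positions = matrix(c(500, 0, 0), 1), times = 30,
                  strength = 25)
  expect_error(toyDose(vacuumLac(), planOut, grid), "outside")
})

test_that("identical dose distributions give gamma zero and full pass", {
  set.seed(5)
  d <- VoxelVolume(array(runif(9^3, 1, 20), c(9, 9, 9)), spacing = 3,
                   units = "Gy")
  res <- gamma3DLocal(d, d, dd = 2, dta = 2, threshold = 3)
  gm <- volArray(res@gammaMap)
  expect_equal(res@passRate, 100)
  expect_true(all(gm[!is.na(gm)] == 0))
  expect_equal(res@nEvaluated, sum(volArray(d) >= 3))
})

test_that("a uniform local dose error with no gradient gives the closed-form gamma", {
  ref <- VoxelVolume(array(10, c(7, 7, 7)), spacing = 2, units = "Gy")
  ev <- VoxelVolume(array(10.3, c(7, 7, 7)), spacing = 2, units = "Gy")
  res <- gamma3DLocal(ref, ev, dd = 2, dta = 2, threshold = 3)
  gm <- volArray(res@gammaMap)
  # 3% error against a 2% criterion, nowhere to escape spatially
  expect_equal(unique(round(gm[!is.na(gm)], 6)), 1.5)
  expect_equal(res@passRate, 0)
})

test_that("gamma agrees with the exhaustive brute-force oracle on small grids", {
  set.seed(31)
  dm <- c(7, 7, 7)
  base <- array(8 + 4 * outer(outer(sin(1:7 / 2), cos(1:7 / 3)),
                              sin(1:7 / 4)), dm)
  ref <- VoxelVolume(base, spacing = 2, units = "Gy")
  ev <- VoxelVolume(base * (1 + array(rnorm(prod(dm), 0, 0.015), dm)),
                    spacing = 2, units = "Gy")
  res <- gamma3DLocal(ref, ev, dd = 2, dta = 2, threshold = 3)
  oracle <- gammaOracle(volArray(ref), volArray(ev), spacingMm(ref),
                        originMm(ref), dd = 2, dta = 2, threshold = 3)
  both <- !is.na(oracle)
  expect_equal(volArray(res@gammaMap)[both], oracle[both],
               tolerance = 1e-3)
})

test_that("gamma pass rates are monotone under criteria relaxation and asymmetric", {
  set.seed(41)
  dm <- c(11, 11, 11)
  base <- array(0, dm)
  co <- (1:11 - 6) * 3
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  base[] <- 80 / (1 + r2 / 100)
  ref <- VoxelVolume(base, spacing = 3, units = "Gy")
  ev <- VoxelVolume(base * 1.025 + 0.1, spacing = 3, units = "Gy")
  # nested subgrids so relaxation can only help
  p11 <- gamma3DLocal(ref, ev, 1, 1, 3, subdiv = 5)@passRate
  p21 <- gamma3DLocal(ref, ev, 2, 1, 3, subdiv = 5)@passRate
  p22 <- gamma3DLocal(ref, ev, 2, 2, 3, subdiv = 10)@passRate
  expect_lte(p11, p21)
  expect_lte(p21, p22)
  # local gamma is asymmetric in reference and evaluated roles
  fwd <- gamma3DLocal(ref, ev, 2, 1, 3)@passRate
  rev <- gamma3DLocal(ev, ref, 2, 1, 3)@passRate
  expect_false(isTRUE(all.equal(fwd, rev)))
})

test_that("DVH metrics implement D90 and interpolated D2cc", {
  # uniform dose: D90 = D2cc = the dose
  m <- array(TRUE, c(10, 10, 10))
  d <- VoxelVolume(array(5.5, c(10, 10, 10)), spacing = c(2, 2, 2),
                   units = "Gy")
  res <- dvhMetrics(d, m)
  expect_equal(res@d90, 5.5)
  expect_equal(res@d2cc, 5.5)
  expect_equal(res@volumeCc, 8)
  # linear ramp 0..10 Gy over 20 cm^3: D90 = 1.0 Gy
  n <- 2500                                  # 2500 voxels x 8 mm^3 = 20 cm^3
  ramp <- VoxelVolume(array(seq(0, 10, length.out = n), c(50, 50, 1)),
                      spacing = 2, units = "Gy")
  mr <- array(TRUE, c(50, 50, 1))
  resR <- dvhMetrics(ramp, mr)
  expect_equal(resR@d90, 1.0, tolerance = 0.01)
  # hottest-2cc boundary via interpolation on the sorted curve
  expect_equal(resR@d2cc, 10 - 2 / 20 * 10, tolerance = 0.01)
  # sub-2cc structures are refused (or NA on request)
  small <- array(FALSE, c(50, 50, 1)); small[1:100] <- TRUE   # 0.8 cm^3
  expect_error(dvhMetrics(ramp, small), "2 cm")
  expect_true(is.na(dvhMetrics(ramp, small, d2ccRequired = FALSE)@d2cc))
})
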