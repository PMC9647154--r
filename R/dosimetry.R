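#' Dwell plan along the applicator channel
#'
#' Builds a high-dose-rate dwell plan on a straight applicator channel:
#' `n` dwell positions starting at the channel tip and stepping back by
#' `stepMm`, each with the same dwell time.
#'
#' @param appSpec applicator specification ([defaultApplicatorSpec()]);
#'   the channel's second end point is the tip.
#' @param n number of dwell positions.
#' @param stepMm step size between dwells in mm.
#' @param dwellTimeS dwell time per position in seconds.
#' @param strength source strength scale (Gy mm^2 / s at unit geometry).
#' @return List with `positions` (n x 3 mm matrix, ordered from the tip),
#'   `times` (s), and `strength`.
#' @examples
#' plan <- dwellPlan()
#' plan$positions[1:2, ]
#' @export
dwellPlan <- function(appSpec = defaultApplicatorSpec(), n = 10,
                      stepMm = 5, dwellTimeS = 30, strength = 25) {
  stopifnot(n >= 1, stepMm > 0, dwellTimeS >= 0, strength > 0)
  p0 <- appSpec$channel[1, ]; p1 <- appSpec$channel[nrow(appSpec$channel), ]
  len <- sqrt(sum((p1 - p0)^2))
  if ((n - 1) * stepMm > len)
    stop("dwell span exceeds the channel length")
  dirv <- (p0 - p1) / len              # from tip back toward the entry
  pos <- t(vapply(seq_len(n) - 1,
                  function(k) p1 + k * stepMm * dirv, numeric(3)))
  list(positions = pos, times = rep(dwellTimeS, n), strength = strength)
}

#' Toy attenuation-aware brachytherapy dose engine
#'
#' A deliberately simple point-source model used to propagate image
#' (attenuation) errors into dose: each dwell contributes
#' `strength * t / max(d^2, dMin^2) * exp(-integral of mu)` along the
#' straight ray from the dwell to the point. No scatter buildup,
#' anisotropy, or consensus source data -- this is a surrogate engine for
#' comparing dose on two attenuation volumes, not a clinical calculation.
#'
#' @param lac LAC [VoxelVolume-class] (1/mm) the rays attenuate through.
#' @param plan dwell plan from [dwellPlan()].
#' @param grid dose grid: list with `dim`, `spacing` (mm, scalar or
#'   length 3), optional `origin` (default centred).
#' @param dMin inverse-square cap distance in mm; default half the dose
#'   voxel diagonal.
#' @param step ray-marching step in mm.
#' @return A `Gy` [VoxelVolume-class].
#' @export
toyDose <- function(lac, plan, grid, dMin = NULL, step = 0.75) {
  stopifnot(volUnits(lac) == "LAC")
  if (length(grid$spacing) == 1L) grid$spacing <- rep(grid$spacing, 3L)
  if (is.null(grid$origin))
    grid$origin <- -(grid$dim - 1) / 2 * grid$spacing
  if (is.null(dMin)) dMin <- sqrt(sum(grid$spacing^2)) / 2
  # dwells must sit inside the attenuation volume
  d <- dim(volArray(lac)); sp <- spacingMm(lac); or <- originMm(lac)
  lo <- or - sp / 2; hi <- or + (d - 0.5) * sp
  pos <- plan$positions
  if (any(t(pos) < lo) || any(t(pos) > hi))
    stop("dwell position outside the attenuation volume")
  dose <- .doseCpp(as.numeric(volArray(lac)), d, sp, or,
                   pos, plan$times, plan$strength,
                   as.integer(grid$dim), grid$spacing, grid$origin,
                   dMin, step)
  VoxelVolume(array(dose, grid$dim), grid$spacing, grid$origin,
              units = "Gy")
}

#' 3D local gamma analysis
#'
#' For every reference voxel at or above the dose threshold, the gamma
#' index is the minimum over nearby evaluated-dose positions of
#' `sqrt((d / dta)^2 + (dD / (dd% * Dref))^2)`, with the evaluated dose
#' trilinearly interpolated on a subgrid of spacing `dta / subdiv` within
#' a search sphere of `searchFactor * dta`. The dose difference is
#' normalized by the local reference dose (local gamma). Pass means
#' gamma <= 1.
#'
#' @param ref,eval `Gy` [VoxelVolume-class] objects on one grid.
#' @param dd dose-difference criterion in percent (local).
#' @param dta distance-to-agreement criterion in mm.
#' @param threshold dose threshold in Gy: voxels with reference dose
#'   below it are not evaluated.
#' @param searchFactor search radius in multiples of `dta`.
#' @param subdiv interpolation subgrid refinement (`dta / subdiv`
#'   spacing).
#' @return A [GammaResult-class].
#' @export
gamma3DLocal <- function(ref, eval, dd = 2, dta = 2, threshold = 3,
                         searchFactor = 3, subdiv = 5) {
  stopifnot(dd > 0, dta > 0, threshold > 0, searchFactor > 0, subdiv >= 1)
  stopIfGridMismatch(ref, eval)
  if (max(volArray(ref)) < threshold)
    stop("threshold exceeds the maximum reference dose")
  g <- .gammaCpp(as.numeric(volArray(ref)), as.numeric(volArray(eval)),
                 dim(volArray(ref)), spacingMm(ref), originMm(ref),
                 dd, dta, threshold, searchFactor, as.integer(subdiv))
  gm <- array(g, dim(volArray(ref)))
  ev <- !is.na(gm)
  methods::new("GammaResult",
               gammaMap = VoxelVolume(gm, spacingMm(ref), originMm(ref),
                                      units = "ratio"),
               passRate = 100 * sum(gm[ev] <= 1) / sum(ev),
               nEvaluated = sum(ev),
               criteria = c(dd = dd, dta = dta, threshold = threshold))
}

#' Gamma pass rates across thresholds
#'
#' The gamma value of a voxel does not depend on the threshold, so one
#' gamma map evaluated at the lowest threshold yields the pass rate at
#' every higher threshold by restricting to the voxels above it.
#'
#' @param ref,eval dose volumes.
#' @param dd,dta criteria as in [gamma3DLocal()].
#' @param thresholds increasing vector of dose thresholds (Gy).
#' @param ... passed to [gamma3DLocal()].
#' @return data.frame with `threshold`, `passRate`, `nEvaluated`.
#' @export
gammaPassTable <- function(ref, eval, dd = 2, dta = 2,
                           thresholds = c(3, 6, 9, 12), ...) {
  res <- gamma3DLocal(ref, eval, dd, dta, threshold = min(thresholds), ...)
  gm <- volArray(res@gammaMap)
  rv <- volArray(ref)
  out <- lapply(thresholds, function(th) {
    ev <- !is.na(gm) & rv >= th
    data.frame(threshold = th,
               passRate = if (any(ev)) 100 * sum(gm[ev] <= 1) / sum(ev)
                          else NA_real_,
               nEvaluated = sum(ev))
  })
  do.call(rbind, out)
}

#' DVH metrics: D90 and D2cc
#'
#' `D90` is the dose received by at least 90% of the structure volume
#' (the nearest-rank 10th percentile of in-structure voxel doses).
#' `D2cc` is the minimum dose of the hottest 2 cm^3: on the descending
#' dose curve, the dose at a cumulative volume of exactly 2 cm^3, with
#' linear interpolation between voxels. Structures smaller than 2 cm^3
#' raise an error for D2cc (use `d2ccRequired = FALSE` to get NA).
#'
#' @param dose `Gy` [VoxelVolume-class].
#' @param mask logical array on the dose grid (the structure).
#' @param d2ccRequired error (default) or NA when the structure is
#'   smaller than 2 cm^3.
#' @return A [DVHResult-class].
#' @export
dvhMetrics <- function(dose, mask, d2ccRequired = TRUE) {
  stopifnot(volUnits(dose) == "Gy", any(mask))
  v <- volArray(dose)[mask]
  voxCc <- prod(spacingMm(dose)) / 1000
  volCc <- length(v) * voxCc
  d90 <- nearestRankPercentile(v, 0.10)
  if (volCc < 2) {
    if (d2ccRequired)
      stop("structure volume ", round(volCc, 2),
           " cm^3 is below 2 cm^3; D2cc undefined")
    d2cc <- NA_real_
  } else {
    s <- sort(v, decreasing = TRUE)
    cum <- seq_along(s) * voxCc          # volume including each voxel
    k <- which(cum >= 2)[1]
    d2cc <- if (k == 1) s[1]
            else stats::approx(cum[(k - 1):k], s[(k - 1):k], xout = 2)$y
  }
  methods::new("DVHResult", d90 = d90, d2cc = d2cc, volumeCc = volCc)
}
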