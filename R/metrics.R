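#' Per-ROI statistics
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and range
#' over the voxels of each spherical ROI (voxel centres within the ROI
#' radius). A `disc` mode restricts each ROI to its central axial slice,
#' matching circle-on-slice measurements.
#'
#' @param vol HU [VoxelVolume-class].
#' @param rois ROI data.frame from [roiCatalog()] (columns `name`, `x`,
#'   `y`, `z`, `radius`, ...).
#' @param shape `"sphere"` (default) or `"disc"`.
#' @return data.frame with `name`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
roiStats <- function(vol, rois, shape = c("sphere", "disc")) {
  shape <- match.arg(shape)
  a <- volArray(vol)
  d <- dim(a); sp <- spacingMm(vol); or <- originMm(vol)
  out <- lapply(seq_len(nrow(rois)), function(i) {
    m <- sphereMask(d, sp, or, c(rois$x[i], rois$y[i], rois$z[i]),
                    rois$radius[i])
    if (shape == "disc") {
      kz <- which.min(abs(axisCoords(d[3], sp[3], or[3]) - rois$z[i]))
      keep <- array(FALSE, d); keep[, , kz] <- TRUE
      m <- m & keep
    }
    if (!any(m)) stop("ROI '", rois$name[i], "' contains no voxels")
    v <- a[m]
    data.frame(name = rois$name[i], mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), n = length(v))
  })
  do.call(rbind, out)
}

#' Root-mean-square error over ROI means
#'
#' `RMSE = sqrt(mean((cbctMeans - ctMeans)^2))`: the overall CT-number
#' accuracy over a set of ROIs, comparing CBCT against the reference CT.
#'
#' @param cbctMeans,ctMeans equal-length numeric vectors of per-ROI mean
#'   HU.
#' @return RMSE in HU.
#' @examples
#' roiRmse(c(140, 126), c(134, 127))
#' @export
roiRmse <- function(cbctMeans, ctMeans) {
  if (length(cbctMeans) != length(ctMeans) || length(cbctMeans) < 1)
    stop("need equal-length, non-empty mean vectors")
  sqrt(mean((cbctMeans - ctMeans)^2))
}

#' Spatial nonuniformity
#'
#' `SNU = max(means) - min(means)` over ROIs of one tissue: how much the
#' reported CT number of a single homogeneous material varies across the
#' image (cupping pushes this up).
#'
#' @param means numeric vector of same-tissue ROI mean HU (length >= 2).
#' @return SNU in HU.
#' @examples
#' snu(c(140, 126, 142, 138, 129, 139))  # 16
#' @export
snu <- function(means) {
  if (length(means) < 2) stop("SNU needs at least two same-tissue ROIs")
  max(means) - min(means)
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean_r - mean_b| / sd_r`: ROI contrast against a background
#' ROI, normalized by the target ROI's own noise.
#'
#' @param targetMean,backgroundMean ROI mean HU.
#' @param targetSd target ROI standard deviation (> 0).
#' @return Dimensionless CNR.
#' @examples
#' cnr(199, 136.3, 28)
#' @export
cnr <- function(targetMean, backgroundMean, targetSd) {
  if (targetSd <= 0) stop("target ROI standard deviation must be > 0")
  abs(targetMean - backgroundMean) / targetSd
}

#' Full image-quality report
#'
#' Computes the per-ROI census (mean/SD/range in both volumes and the HU
#' error), the RMSE over all ROI means, the muscle SNU, and the CNR of
#' the target ROI against the background ROI, for one CBCT volume against
#' the reference.
#'
#' @param cbct,reference HU volumes on (possibly different) grids; each
#'   must contain every ROI.
#' @param rois ROI data.frame from [roiCatalog()]; `role` must mark one
#'   `target` and one `background` ROI for the CNR.
#' @param shape ROI shape passed to [roiStats()].
#' @return List with `roi` (data.frame), `rmse`, `snuByTissue` (named,
#'   tissues with >= 2 ROIs), `cnr`, and `cnrReference` (CNR of the
#'   reference volume itself).
#' @export
metricsReport <- function(cbct, reference, rois, shape = "sphere") {
  sc <- roiStats(cbct, rois, shape)
  sr <- roiStats(reference, rois, shape)
  roi <- data.frame(name = rois$name, tissue = rois$tissue,
                    refMean = sr$mean, refSd = sr$sd,
                    cbctMean = sc$mean, cbctSd = sc$sd,
                    error = sc$mean - sr$mean)
  tissues <- unique(rois$tissue[duplicated(rois$tissue)])
  snuBy <- vapply(tissues, function(tt) snu(sc$mean[rois$tissue == tt]),
                  numeric(1))
  names(snuBy) <- tissues
  it <- which(rois$role == "target"); ib <- which(rois$role == "background")
  cnrVal <- cnrRef <- NA_real_
  if (length(it) == 1 && length(ib) == 1) {
    cnrVal <- cnr(sc$mean[it], sc$mean[ib], sc$sd[it])
    cnrRef <- cnr(sr$mean[it], sr$mean[ib], sr$sd[it])
  }
  list(roi = roi, rmse = roiRmse(sc$mean, sr$mean), snuByTissue = snuBy,
       cnr = cnrVal, cnrReference = cnrRef)
}

#' Bundled reference ROI census
#'
#' Loads the packaged registered-CT / corrected-CBCT / raw-CBCT per-ROI
#' mean table for a physical pelvis phantom (six muscle ROIs plus
#' adipose, bladder, uterus and rectum), used to exercise the RMSE and
#' SNU formulas on published-scale numbers.
#'
#' @return data.frame with columns `tissue`, `ct_mean`, `corrected_mean`,
#'   `raw_mean`.
#' @export
referenceRoiTable <- function() {
  utils::read.csv(system.file("extdata", "phantom_roi_reference.csv",
                              package = "cbctscatter"))
}
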