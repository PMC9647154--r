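#' @include AllGenerics.R
NULL

#' VoxelVolume: a 3D scalar grid with physical metadata
#'
#' The basic container for every image-domain object in the package:
#' ground-truth and reconstructed CT/CBCT volumes (HU or linear attenuation
#' coefficient), label maps, dose grids, ratio and mask fields. World
#' coordinates are voxel-centred: the centre of voxel `(i, j, k)` (1-based)
#' sits at `originMm + (c(i, j, k) - 1) * spacingMm`.
#'
#' @slot data numeric 3D array.
#' @slot spacing numeric length-3, voxel size in mm (strictly positive).
#' @slot origin numeric length-3, world mm coordinate of the first voxel
#'   centre.
#' @slot units character scalar: one of `"HU"`, `"LAC"`, `"Gy"`, `"label"`,
#'   `"ratio"`, `"mask"`.
#'
#' @seealso [VoxelVolume()] for the user constructor,
#'   [volume-accessors] for accessors.
#' @name VoxelVolume-class
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 units = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite numbers")
    ok <- c("HU", "LAC", "Gy", "label", "ratio", "mask")
    if (length(object@units) != 1L || !(object@units %in% ok))
      msg <- c(msg, paste("units must be one of:", paste(ok, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelVolume
#'
#' @param data numeric 3D array.
#' @param spacing voxel size in mm (length 1 or 3).
#' @param origin world mm coordinate of the first voxel centre; the default
#'   centres the volume on the isocenter (0, 0, 0).
#' @param units unit tag, see [VoxelVolume-class].
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(array(rnorm(64), c(4, 4, 4)), spacing = 2, units = "HU")
#' v
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = NULL,
                        units = "HU") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  methods::new("VoxelVolume", data = data, spacing = as.numeric(spacing),
               origin = as.numeric(origin), units = units)
}

#' ConeBeamGeometry: circular cone-beam acquisition geometry
#'
#' Describes a full circular scan: source-axis distance (SAD),
#' source-detector distance (SDD), flat detector size/pitch, view angles,
#' and the unattenuated detector intensity I0. The detector is centred on
#' the central ray; pixel `(iu, iv)` (1-based) is offset
#' `(iu - (nu + 1)/2) * pitch` along the in-plane axis and
#' `(iv - (nv + 1)/2) * pitch` along the rotation axis.
#'
#' @slot sad numeric, source-axis distance in mm.
#' @slot sdd numeric, source-detector distance in mm (`sdd > sad > 0`).
#' @slot detPixels integer length-2, detector pixels `(nu, nv)`.
#' @slot pixelPitch numeric, detector pixel pitch in mm (square pixels).
#' @slot viewAngles numeric, strictly increasing gantry angles in degrees
#'   spanning a full turn (>= 360 - step).
#' @slot i0 numeric, unattenuated intensity (arbitrary units, > 0).
#' @name ConeBeamGeometry-class
#' @exportClass ConeBeamGeometry
setClass("ConeBeamGeometry",
  representation(sad = "numeric", sdd = "numeric", detPixels = "integer",
                 pixelPitch = "numeric", viewAngles = "numeric",
                 i0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@sdd > object@sad && object@sad > 0))
      msg <- c(msg, "need sdd > sad > 0")
    if (length(object@detPixels) != 2L || any(object@detPixels < 2L))
      msg <- c(msg, "detPixels must be two integers >= 2")
    if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
    ang <- object@viewAngles
    if (length(ang) < 4L || any(diff(ang) <= 0))
      msg <- c(msg, "viewAngles must be strictly increasing")
    else {
      step <- mean(diff(ang))
      if ((ang[length(ang)] - ang[1]) < 360 - step - 1e-6)
        msg <- c(msg, "viewAngles must span a full turn (>= 360 - step)")
    }
    if (object@i0 <= 0) msg <- c(msg, "i0 must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a ConeBeamGeometry
#'
#' Defaults describe the package's desk-scale linac-mounted-imager-like system:
#' SAD 1000 mm, SDD 1500 mm, a 384 x 144 detector at 1.552 mm pitch, and
#' 360 views at 1 degree spacing.
#'
#' @param sad,sdd source-axis / source-detector distances (mm).
#' @param detPixels detector size `(nu, nv)` in pixels.
#' @param pixelPitch detector pixel pitch (mm).
#' @param viewAngles gantry angles in degrees (full circular scan).
#' @param i0 unattenuated detector intensity.
#' @return A [ConeBeamGeometry-class] object.
#' @examples
#' geom <- ConeBeamGeometry(detPixels = c(64, 16), viewAngles = seq(0, 355, 5))
#' geom
#' @export
ConeBeamGeometry <- function(sad = 1000, sdd = 1500, detPixels = c(384, 144),
                             pixelPitch = 1.552,
                             viewAngles = seq(0, 359, by = 1), i0 = 1) {
  methods::new("ConeBeamGeometry", sad = as.numeric(sad), sdd = as.numeric(sdd),
               detPixels = as.integer(detPixels),
               pixelPitch = as.numeric(pixelPitch),
               viewAngles = as.numeric(viewAngles), i0 = as.numeric(i0))
}

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' ProjectionStack: per-view detector data plus geometry
#'
#' Holds the cone-beam projections of one scan, either in the intensity
#' domain (detector signal, strictly positive) or the line-integral domain
#' (`p = -log(I / I0)`, non-negative). Array layout is `nu x nv x nViews`.
#' When scatter was simulated, the additive scatter component is retained
#' in `scatterTruth` for validation.
#'
#' @slot data numeric array `nu x nv x nViews`.
#' @slot domain `"intensity"` or `"line_integral"`.
#' @slot geometry a [ConeBeamGeometry-class].
#' @slot scatterTruth same-shape array of simulated scatter, or `NULL`.
#' @name ProjectionStack-class
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(data = "array", domain = "character",
                 geometry = "ConeBeamGeometry", scatterTruth = "arrayOrNULL"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    g <- object@geometry
    if (length(d) != 3L)
      msg <- c(msg, "data must be a 3D array (nu x nv x nViews)")
    else {
      if (!all(d[1:2] == g@detPixels))
        msg <- c(msg, "detector dims inconsistent with geometry")
      if (d[3] != length(g@viewAngles))
        msg <- c(msg, "number of views inconsistent with geometry")
    }
    if (!(object@domain %in% c("intensity", "line_integral")))
      msg <- c(msg, "domain must be 'intensity' or 'line_integral'")
    if (object@domain == "intensity" && any(object@data <= 0))
      msg <- c(msg, "intensity data must be strictly positive")
    if (object@domain == "line_integral" && any(object@data < -1e-9))
      msg <- c(msg, "line-integral data must be non-negative")
    if (!is.null(object@scatterTruth) &&
        !identical(dim(object@scatterTruth), d))
      msg <- c(msg, "scatterTruth shape must match data")
    if (length(msg)) msg else TRUE
  })

#' Construct a ProjectionStack
#'
#' @param data numeric array `nu x nv x nViews`.
#' @param domain `"intensity"` or `"line_integral"`.
#' @param geometry a [ConeBeamGeometry-class].
#' @param scatterTruth optional same-shape array of known scatter.
#' @return A [ProjectionStack-class].
#' @export
ProjectionStack <- function(data, domain, geometry, scatterTruth = NULL) {
  methods::new("ProjectionStack", data = data, domain = domain,
               geometry = geometry, scatterTruth = scatterTruth)
}

#' TissueLACTable: per-class reference attenuation values
#'
#' Reference linear attenuation coefficients (1/mm) for the four tissue
#' classes extracted from the planning-CT histogram, plus water and the
#' (optional) applicator. HU windows define the segmentation: values
#' outside every window are unclassified (treated as air downstream, with
#' zero filtration weight).
#'
#' @slot muAir,muFat,muMuscle,muBone numeric LACs (1/mm), strictly
#'   increasing in that order.
#' @slot muW numeric, LAC of water (1/mm).
#' @slot muApplicator numeric, LAC used to fill applicator voxels.
#' @slot huWindows named list of `c(lo, hi)` HU intervals for
#'   `air`, `fat`, `muscle`, `bone` (pairwise disjoint).
#' @name TissueLACTable-class
#' @exportClass TissueLACTable
setClass("TissueLACTable",
  representation(muAir = "numeric", muFat = "numeric", muMuscle = "numeric",
                 muBone = "numeric", muW = "numeric",
                 muApplicator = "numeric", huWindows = "list"),
  validity = function(object) {
    msg <- character()
    mus <- c(object@muAir, object@muFat, object@muMuscle, object@muBone)
    if (any(diff(mus) <= 0))
      msg <- c(msg, "need muAir < muFat < muMuscle < muBone")
    if (object@muW <= 0) msg <- c(msg, "muW must be > 0")
    w <- object@huWindows
    if (!all(c("air", "fat", "muscle", "bone") %in% names(w)))
      msg <- c(msg, "huWindows must name air, fat, muscle, bone")
    else {
      iv <- do.call(rbind, w[c("air", "fat", "muscle", "bone")])
      if (any(iv[, 1] > iv[, 2])) msg <- c(msg, "each window needs lo <= hi")
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
        msg <- c(msg, "huWindows must be pairwise disjoint")
    }
    if (length(msg)) msg else TRUE
  })

#' Default HU segmentation windows
#'
#' Air `[-1024, -500]`, adipose `[-125, -60]`, muscle `[15, 85]`, and bone
#' `(190, Inf)`. HU values outside every window are unclassified.
#'
#' @return Named list of `c(lo, hi)` intervals.
#' @export
defaultHuWindows <- function() {
  list(air = c(-1024, -500), fat = c(-125, -60), muscle = c(15, 85),
       bone = c(190 + 1e-9, Inf))
}

#' Construct a TissueLACTable
#'
#' @param muAir,muFat,muMuscle,muBone class LACs (1/mm).
#' @param muW water LAC (1/mm).
#' @param muApplicator applicator fill LAC (1/mm).
#' @param huWindows segmentation windows, see [defaultHuWindows()].
#' @return A [TissueLACTable-class].
#' @export
TissueLACTable <- function(muAir, muFat, muMuscle, muBone, muW = 0.02,
                           muApplicator = huToLacValue(2500, muW),
                           huWindows = defaultHuWindows()) {
  methods::new("TissueLACTable", muAir = muAir, muFat = muFat,
               muMuscle = muMuscle, muBone = muBone, muW = muW,
               muApplicator = muApplicator, huWindows = huWindows)
}

#' CorrectionResult: output and intermediates of the six-step correction
#'
#' Returned by [correctCBCT()]. Keeps every intermediate of the pipeline so
#' each stage can be inspected and tested: the uniform scatter estimate,
#' the first-pass reconstruction, the tissue labels and template, the raw
#' and smoothed scatter-ratio fields, the binary sampling mask with its
#' thresholds, and the final corrected volume in LAC and HU.
#'
#' @slot cbctFc final corrected volume (LAC) ([VoxelVolume-class]).
#' @slot cbctFcHu final corrected volume in HU.
#' @slot cbctC first-pass (uniform-scatter-corrected) reconstruction, LAC.
#' @slot sBar numeric, the uniform scatter estimate (intensity units).
#' @slot labels tissue-class label volume (`units = "label"`).
#' @slot confident logical array: TRUE where the voxel HU fell inside a
#'   segmentation window.
#' @slot template the piecewise-constant template volume (LAC).
#' @slot ratio raw scatter-ratio field r = template / cbctC.
#' @slot ratioSmooth smoothed ratio field r_f from local filtration.
#' @slot mask binary sampling mask f.
#' @slot rMax,gMax numeric, the Eq.-style intensity and gradient cutoffs.
#' @slot lacTable the [TissueLACTable-class] used.
#' @name CorrectionResult-class
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  representation(cbctFc = "VoxelVolume", cbctFcHu = "VoxelVolume",
                 cbctC = "VoxelVolume", sBar = "numeric",
                 labels = "VoxelVolume", confident = "array",
                 template = "VoxelVolume", ratio = "VoxelVolume",
                 ratioSmooth = "VoxelVolume", mask = "VoxelVolume",
                 rMax = "numeric", gMax = "numeric",
                 lacTable = "TissueLACTable"))

#' GammaResult: 3D local gamma map and pass rate
#'
#' @slot gammaMap [VoxelVolume-class] of gamma values (NA below threshold).
#' @slot passRate percent of evaluated voxels with gamma <= 1.
#' @slot nEvaluated number of reference voxels at or above threshold.
#' @slot criteria named numeric: `dd` (%), `dta` (mm), `threshold` (Gy).
#' @name GammaResult-class
#' @exportClass GammaResult
setClass("GammaResult",
  representation(gammaMap = "VoxelVolume", passRate = "numeric",
                 nEvaluated = "integer", criteria = "numeric"),
  validity = function(object) {
    if (object@passRate < 0 || object@passRate > 100)
      "passRate must be in [0, 100]" else TRUE
  })

#' DVHResult: dose-volume histogram metrics
#'
#' @slot d90 Gy, minimum dose received by the best-covered 90% of the
#'   structure.
#' @slot d2cc Gy, minimum dose of the hottest 2 cm^3 (NA when the
#'   structure is smaller than 2 cm^3 and the metric is undefined).
#' @slot volumeCc structure volume in cm^3.
#' @name DVHResult-class
#' @exportClass DVHResult
setClass("DVHResult",
  representation(d90 = "numeric", d2cc = "numeric", volumeCc = "numeric"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume [%s]: %d x %d x %d voxels, spacing %s mm\n",
              object@units, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, range [%.4g, %.4g]\n",
              paste(format(object@origin, digits = 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "ConeBeamGeometry", function(object) {
  cat(sprintf(paste0("ConeBeamGeometry: SAD %.0f mm, SDD %.0f mm, detector ",
                     "%d x %d @ %.3f mm, %d views [%g..%g] deg, I0 = %g\n"),
              object@sad, object@sdd, object@detPixels[1], object@detPixels[2],
              object@pixelPitch, length(object@viewAngles),
              min(object@viewAngles), max(object@viewAngles), object@i0))
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProjectionStack [%s]: %d views of %d x %d%s\n", object@domain,
              d[3], d[1], d[2],
              if (is.null(object@scatterTruth)) "" else " (+ scatter truth)"))
  show(object@geometry)
})

setMethod("show", "TissueLACTable", function(object) {
  cat("TissueLACTable (1/mm):\n")
  cat(sprintf("  air %.5f | fat %.5f | muscle %.5f | bone %.5f\n",
              object@muAir, object@muFat, object@muMuscle, object@muBone))
  cat(sprintf("  water %.5f | applicator %.5f\n", object@muW,
              object@muApplicator))
})

setMethod("show", "CorrectionResult", function(object) {
  cat("CorrectionResult\n")
  cat(sprintf("  s_bar = %.4g (intensity), r_max = %.4g, G_max = %.4g\n",
              object@sBar, object@rMax, object@gMax))
  cat("  corrected volume: "); show(object@cbctFcHu)
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf(
    "GammaResult (%g%%, %g mm, threshold %g Gy): pass rate %.2f%% (n = %d)\n",
    object@criteria[["dd"]], object@criteria[["dta"]],
    object@criteria[["threshold"]], object@passRate, object@nEvaluated))
})

setMethod("show", "DVHResult", function(object) {
  cat(sprintf("DVHResult: D90 = %.3f Gy, D2cc = %s Gy, volume %.2f cm^3\n",
              object@d90,
              if (is.na(object@d2cc)) "NA" else sprintf("%.3f", object@d2cc),
              object@volumeCc))
})

# ---- accessor methods -------------------------------------------------------

#' @rdname volume-accessors
setMethod("volArray", "VoxelVolume", function(x) x@data)
#' @rdname volume-accessors
setMethod("spacingMm", "VoxelVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("originMm", "VoxelVolume", function(x) x@origin)
#' @rdname volume-accessors
setMethod("volUnits", "VoxelVolume", function(x) x@units)
#' @rdname volume-accessors
setMethod("volArray", "ProjectionStack", function(x) x@data)
#' @rdname projection-accessors
setMethod("projDomain", "ProjectionStack", function(x) x@domain)
#' @rdname projection-accessors
setMethod("geometry", "ProjectionStack", function(x) x@geometry)
#' @rdname projection-accessors
setMethod("scatterTruth", "ProjectionStack", function(x) x@scatterTruth)
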