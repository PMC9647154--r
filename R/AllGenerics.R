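#' Accessors for volume and projection containers
#'
#' `volArray` returns the raw numeric array, `spacingMm` the per-axis voxel
#' (or pixel) spacing in mm, `originMm` the world coordinate of the first
#' voxel centre, and `volUnits` the unit tag (`"HU"`, `"LAC"`, `"Gy"`,
#' `"label"`, `"ratio"`, or `"mask"`).
#'
#' @param x a [VoxelVolume-class] or [ProjectionStack-class] object.
#' @return `volArray` an array; `spacingMm`/`originMm` numeric vectors;
#'   `volUnits` a character scalar.
#' @name volume-accessors
#' @aliases volArray spacingMm originMm volUnits
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2))
#' volArray(v)[1, 1, 1]
#' spacingMm(v)
#' @export
setGeneric("volArray", function(x) standardGeneric("volArray"))

#' @rdname volume-accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname volume-accessors
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname volume-accessors
#' @export
setGeneric("volUnits", function(x) standardGeneric("volUnits"))

#' Accessors for projection stacks
#'
#' `projDomain` returns `"intensity"` or `"line_integral"`; `geometry` the
#' [ConeBeamGeometry-class]; `scatterTruth` the simulated scatter component
#' (or `NULL` when the stack carries none).
#'
#' @param x a [ProjectionStack-class].
#' @return See description.
#' @name projection-accessors
#' @aliases projDomain geometry scatterTruth
#' @export
setGeneric("projDomain", function(x) standardGeneric("projDomain"))

#' @rdname projection-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname projection-accessors
#' @export
setGeneric("scatterTruth", function(x) standardGeneric("scatterTruth"))
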