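#' Read and write volumes
#'
#' Volumes round-trip losslessly with their spacing and origin through
#' NIfTI (`.nii`, `.nii.gz`, via RNifti) or MetaImage (`.mha`, local raw
#' block). HU and label volumes are stored as 16-bit signed integers
#' (HU data is rounded to whole units on write); everything else is
#' stored as 32-bit float.
#'
#' @param vol a [VoxelVolume-class].
#' @param path file path ending in `.nii`, `.nii.gz`, or `.mha`.
#' @param units unit tag to attach on read (the formats carry geometry,
#'   not units).
#' @return `readVolume` a [VoxelVolume-class]; `writeVolume` the path,
#'   invisibly.
#' @name volume-io
#' @export
writeVolume <- function(vol, path) {
  stopifnot(methods::is(vol, "VoxelVolume"))
  int16 <- volUnits(vol) %in% c("HU", "label")
  a <- volArray(vol)
  if (int16) a <- round(a)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(if (int16) array(as.integer(a), dim(a)) else a,
                           datatype = if (int16) "int16" else "float")
    mat <- diag(4)
    mat[1, 1] <- spacingMm(vol)[1]
    mat[2, 2] <- spacingMm(vol)[2]
    mat[3, 3] <- spacingMm(vol)[3]
    mat[1:3, 4] <- originMm(vol)
    RNifti::sform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    writeMha(a, spacingMm(vol), originMm(vol), path, int16)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path, units = "HU") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    mat <- RNifti::xform(img)
    sp <- c(sqrt(sum(mat[1:3, 1]^2)), sqrt(sum(mat[1:3, 2]^2)),
            sqrt(sum(mat[1:3, 3]^2)))
    or <- mat[1:3, 4]
    VoxelVolume(array(as.numeric(img), dim(img)), sp, or, units = units)
  } else if (grepl("\\.mha$", path)) {
    m <- readMha(path)
    VoxelVolume(m$data, m$spacing, m$origin, units = units)
  } else stop("unsupported volume format: ", path)
}

# Minimal MetaImage writer/reader (3D, local uncompressed raw block).
writeMha <- function(a, spacing, origin, path, int16) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("DimSize =", paste(dim(a), collapse = " ")),
           paste("ElementType =", if (int16) "MET_SHORT" else "MET_FLOAT"),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (int16) writeBin(as.integer(a), con, size = 2L, endian = "little")
  else writeBin(as.numeric(a), con, size = 4L, endian = "little")
}

readMha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readHeaderLine(con)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data blocks are supported")
  if (!identical(hdr[["CompressedData"]], "False"))
    stop("compressed MetaImage is not supported")
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  n <- prod(dm)
  type <- hdr[["ElementType"]]
  data <- if (type == "MET_SHORT")
    readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
  else if (type == "MET_FLOAT")
    readBin(con, "numeric", n, size = 4L, endian = "little")
  else stop("unsupported MetaImage ElementType: ", type)
  list(data = array(as.numeric(data), dm),
       spacing = as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]),
       origin = as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]))
}

readHeaderLine <- function(con) {
  chars <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || ch == "\n") break
    chars <- c(chars, ch)
  }
  sub("\r$", "", paste(chars, collapse = ""))
}

#' Read and write projection stacks
#'
#' A projection stack is stored as a NIfTI array (`nu x nv x nViews`)
#' next to a JSON sidecar (`<path>.json`) holding the full geometry, the
#' domain tag, and I0. Scatter truth, when present, goes to
#' `<stem>_scatter.nii.gz`.
#'
#' @param stack a [ProjectionStack-class].
#' @param path `.nii` / `.nii.gz` path for the data array.
#' @param expectDomain optional: error if the stored domain differs
#'   (guards against feeding intensities to the reconstructor).
#' @return `readProjections` a [ProjectionStack-class];
#'   `writeProjections` the path, invisibly.
#' @name projection-io
#' @export
writeProjections <- function(stack, path) {
  stopifnot(methods::is(stack, "ProjectionStack"))
  g <- geometry(stack)
  img <- RNifti::asNifti(volArray(stack), datatype = "float")
  RNifti::writeNifti(img, path)
  side <- list(domain = projDomain(stack), sad = g@sad, sdd = g@sdd,
               detPixels = g@detPixels, pixelPitch = g@pixelPitch,
               viewAngles = g@viewAngles, i0 = g@i0,
               hasScatterTruth = !is.null(scatterTruth(stack)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(scatterTruth(stack))) {
    sImg <- RNifti::asNifti(scatterTruth(stack), datatype = "float")
    RNifti::writeNifti(sImg, scatterPath(path))
  }
  invisible(path)
}

scatterPath <- function(path)
  sub("\\.nii(\\.gz)?$", "_scatter.nii.gz", path)

#' @rdname projection-io
#' @export
readProjections <- function(path, expectDomain = NULL) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expectDomain) && !identical(side$domain, expectDomain))
    stop("projection stack is in the '", side$domain, "' domain, expected '",
         expectDomain, "'")
  g <- ConeBeamGeometry(sad = side$sad, sdd = side$sdd,
                        detPixels = side$detPixels,
                        pixelPitch = side$pixelPitch,
                        viewAngles = side$viewAngles, i0 = side$i0)
  a <- RNifti::readNifti(path)
  st <- NULL
  if (isTRUE(side$hasScatterTruth)) {
    st <- RNifti::readNifti(scatterPath(path))
    st <- array(as.numeric(st), dim(st))
  }
  ProjectionStack(array(as.numeric(a), dim(a)), side$domain, g,
                  scatterTruth = st)
}

#' Run configuration
#'
#' The benchmark run configuration: phantom, geometry, scatter and noise
#' model, correction parameters, dwell plan, dose grid, gamma criteria,
#' and the master seed. `readRunConfig`/`writeRunConfig` round-trip the
#' configuration through YAML; unknown keys are rejected against the
#' default template.
#'
#' @return `defaultRunConfig()`: a nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    phantom = list(gridShape = c(256, 192, 96), voxelSize = 1.5,
                   bodyAxes = c(340, 200), textureSd = 8,
                   priorNoiseSd = 5),
    applicator = list(huValue = 2500),
    geometry = list(sad = 1000, sdd = 1500, detPixels = c(384, 144),
                    pixelPitch = 1.552, nViews = 360, i0 = 1),
    scatter = list(spr = 0.15, blurSigmaMm = 250),
    noise = list(photonsPerI0 = 1e5),
    recon = list(zDim = 80, filter = "ramlak"),
    correction = defaultCorrectionConfig()[
      c("muW", "objectRule", "scatterPercentile", "softCutEps", "floorFrac",
        "sBarCapFrac", "epsFloor", "maskPercentile", "sigmaMm",
        "applicatorMarginMm", "denomFloor", "fallback", "applicatorHu",
        "segmentSource")],
    plan = list(n = 10, stepMm = 5, dwellTimeS = 30, strength = 25),
    dose = list(dim = c(64, 64, 100), spacing = c(2.5, 2.5, 1)),
    gamma = list(criteria = list(c(1, 1), c(2, 1), c(2, 2)),
                 thresholds = c(3, 6, 9, 12)))
}

#' @rdname defaultRunConfig
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  checkKeys(cfg, defaultRunConfig(), "config")
  utils::modifyList(defaultRunConfig(), cfg)
}

checkKeys <- function(x, template, where) {
  if (!is.list(x) || !is.list(template)) return(invisible(TRUE))
  extra <- setdiff(names(x), names(template))
  if (length(extra))
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
  for (k in intersect(names(x), names(template)))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      checkKeys(x[[k]], template[[k]], paste0(where, "$", k))
  invisible(TRUE)
}
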