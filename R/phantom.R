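#' Digital female-pelvis phantom
#'
#' Seeded generator of a voxelized pelvis phantom for brachytherapy imaging
#' studies: an elliptical body cross-section of 340 mm x 200 mm containing
#' a muscle-equivalent background, a peripheral adipose shell, two pelvic
#' bone blocks (cortical shell material and a denser cancellous-core
#' material, mimicking the polymer inserts of physical phantoms), and
#' organ-mimicking inserts (bladder, uterus, rectum, intestine) whose mean
#' HU values follow a registered-CT census of such a phantom
#' (organ inserts around 191-199 HU, muscle background around 130 HU,
#' adipose around -112 HU). All shapes are analytic ellipsoids, elliptic
#' cylinders, or shells, so structure volumes are known exactly.
#'
#' Note that the muscle background mean (130 HU) deliberately lies outside
#' the muscle segmentation window of [defaultHuWindows()]: the physical
#' muscle substitute materials used in such phantoms are denser than
#' patient muscle, so the bulk of the phantom is a "gap class" that the
#' correction never samples directly. See the methods vignette.
#'
#' @name phantom
NULL

#' Default phantom specification
#'
#' @param gridShape voxel grid `(nx, ny, nz)`.
#' @param voxelSize voxel size in mm (scalar or length 3).
#' @param bodyAxes full body-ellipse axes in mm (in-plane), default
#'   `c(340, 200)`.
#' @param textureSd default Gaussian texture noise per structure (HU).
#' @return A list with fields `gridShape`, `voxelSize`, `bodyAxes`,
#'   `structures` (ordered list of analytic shapes; later entries take
#'   priority where shapes overlap) and `labels` (name -> integer code).
#'   Each structure has `name`, `type` (`ellipsoid`, `ecylinder`, `shell`),
#'   geometric parameters in mm, `hu` mean and `sd` texture noise.
#' @examples
#' spec <- defaultPhantomSpec(gridShape = c(64, 48, 16), voxelSize = 6)
#' names(spec$labels)
#' @export
defaultPhantomSpec <- function(gridShape = c(256, 192, 96), voxelSize = 1.5,
                               bodyAxes = c(340, 200), textureSd = 8) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  a <- bodyAxes[1] / 2; b <- bodyAxes[2] / 2
  structures <- list(
    list(name = "muscle", type = "ecylinder", center = c(0, 0),
         semi = c(a, b), hu = 130, sd = textureSd),
    list(name = "adipose", type = "shell", center = c(0, 0),
         semi = c(a, b), innerScale = 0.86, hu = -112, sd = textureSd),
    list(name = "bone_cortical", type = "ecylinder", center = c(100, 5),
         semi = c(10, 13), hu = 350, sd = textureSd),
    list(name = "bone_cortical", type = "ecylinder", center = c(-100, 5),
         semi = c(10, 13), hu = 350, sd = textureSd),
    list(name = "bone_cancellous", type = "ecylinder", center = c(100, 5),
         semi = c(6, 8), hu = 950, sd = textureSd),
    list(name = "bone_cancellous", type = "ecylinder", center = c(-100, 5),
         semi = c(6, 8), hu = 950, sd = textureSd),
    list(name = "bladder", type = "ellipsoid", center = c(0, -45, 0),
         semi = c(30, 22, 30), hu = 191, sd = textureSd),
    list(name = "uterus", type = "ellipsoid", center = c(0, 2, 0),
         semi = c(18, 18, 35), hu = 196, sd = textureSd),
    list(name = "rectum", type = "cylinder", center = c(0, 55),
         radius = 12, hu = 199, sd = textureSd),
    list(name = "intestine", type = "ellipsoid", center = c(50, -28, 10),
         semi = c(18, 14, 25), hu = 193, sd = textureSd))
  labels <- c(air = 0L, muscle = 1L, adipose = 2L, bone_cortical = 3L,
              bone_cancellous = 4L, bladder = 5L, uterus = 6L, rectum = 7L,
              intestine = 8L, applicator = 9L)
  list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
       bodyAxes = bodyAxes, structures = structures, labels = labels,
       airHu = -1000)
}

#' Default applicator specification
#'
#' A straight intrauterine tandem channel along the rotation axis, high-HU
#' (titanium-like) fill.
#'
#' @param huValue applicator HU (>= 2000 by default).
#' @return List with `channel` (2 x 3 matrix of mm end points), `radius`
#'   (mm) and `huValue`.
#' @export
defaultApplicatorSpec <- function(huValue = 2500) {
  list(channel = rbind(c(0, 2, -30), c(0, 2, 32)), radius = 3,
       huValue = huValue)
}

# Logical membership mask of one analytic structure on the phantom grid.
structureMaskOnGrid <- function(st, dim, spacing, origin) {
  co <- gridCoords(dim, spacing, origin)
  if (st$type == "ellipsoid") {
    q <- outer(outer((co$x - st$center[1])^2 / st$semi[1]^2,
                     (co$y - st$center[2])^2 / st$semi[2]^2, "+"),
               (co$z - st$center[3])^2 / st$semi[3]^2, "+")
    q <= 1
  } else if (st$type == "ecylinder") {
    q2 <- outer((co$x - st$center[1])^2 / st$semi[1]^2,
                (co$y - st$center[2])^2 / st$semi[2]^2, "+")
    array(q2 <= 1, dim)
  } else if (st$type == "cylinder") {
    q2 <- outer((co$x - st$center[1])^2, (co$y - st$center[2])^2, "+")
    array(q2 <= st$radius^2, dim)
  } else if (st$type == "shell") {
    q2 <- outer((co$x - st$center[1])^2 / st$semi[1]^2,
                (co$y - st$center[2])^2 / st$semi[2]^2, "+")
    array(q2 <= 1 & q2 > st$innerScale^2, dim)
  } else stop("unknown structure type: ", st$type)
}

#' Generate the voxelized phantom
#'
#' Rasterizes the analytic structures of a phantom specification into a
#' label volume and a ground-truth HU volume. Voxels outside the body
#' ellipse are air at -1000 HU. Within each structure the HU value is the
#' structure mean plus seeded Gaussian texture noise; with the seed fixed
#' the output is bit-reproducible. Structures later in the list overwrite
#' earlier ones where they overlap (the declared priority order).
#'
#' @param spec a specification from [defaultPhantomSpec()].
#' @param seed integer seed for the texture noise.
#' @return List with `label` and `hu`, both [VoxelVolume-class] objects on
#'   the same centred grid.
#' @examples
#' ph <- makePelvisPhantom(defaultPhantomSpec(c(48, 36, 8), 6), seed = 1)
#' table(volArray(ph$label))[1:3]
#' @export
makePelvisPhantom <- function(spec = defaultPhantomSpec(), seed = 1) {
  dim <- spec$gridShape; spacing <- spec$voxelSize
  origin <- -(dim - 1) / 2 * spacing
  label <- array(spec$labels[["air"]], dim)
  hu <- array(spec$airHu, dim)
  set.seed(seed)
  for (st in spec$structures) {
    m <- structureMaskOnGrid(st, dim, spacing, origin)
    if (!any(m)) stop("structure '", st$name, "' rasterizes to zero voxels")
    label[m] <- spec$labels[[st$name]]
    n <- sum(m)
    hu[m] <- st$hu + if (st$sd > 0) stats::rnorm(n, 0, st$sd) else 0
  }
  # guard: every structure must lie inside the body ellipse
  a <- spec$bodyAxes[1] / 2; b <- spec$bodyAxes[2] / 2
  co <- gridCoords(dim, spacing, origin)
  body <- array(outer(co$x^2 / a^2, co$y^2 / b^2, "+") <= 1 + 1e-9, dim)
  if (any(label != spec$labels[["air"]] & !body))
    stop("a structure extends outside the body ellipse")
  list(label = VoxelVolume(label, spacing, origin, units = "label"),
       hu = VoxelVolume(hu, spacing, origin, units = "HU"))
}

#' Emulate a high-quality planning CT from the ground truth
#'
#' The planning-CT prior is modelled as the ground-truth HU volume plus
#' i.i.d. Gaussian noise: high resolution, no scatter, no cupping.
#'
#' @param hu ground-truth HU [VoxelVolume-class].
#' @param noiseSd Gaussian noise standard deviation in HU (>= 0).
#' @param seed integer seed.
#' @return An HU [VoxelVolume-class] on the same grid.
#' @export
makePlanningCT <- function(hu, noiseSd = 5, seed = 1) {
  stopifnot(noiseSd >= 0, volUnits(hu) == "HU")
  a <- volArray(hu)
  if (noiseSd > 0) {
    set.seed(seed)
    a <- a + array(stats::rnorm(length(a), 0, noiseSd), dim(a))
  }
  VoxelVolume(a, spacingMm(hu), originMm(hu), units = "HU")
}

#' Insert a high-HU applicator tube
#'
#' Voxels within `radius` of the channel polyline are set to the
#' applicator HU and label. The channel must lie inside the body.
#'
#' @param label,hu phantom volumes from [makePelvisPhantom()].
#' @param appSpec from [defaultApplicatorSpec()].
#' @param spec the phantom specification (for label codes and body check).
#' @return List with updated `label` and `hu` volumes.
#' @export
insertApplicator <- function(label, hu, appSpec = defaultApplicatorSpec(),
                             spec = defaultPhantomSpec()) {
  spacing <- spacingMm(hu)
  if (appSpec$radius < min(spacing))
    stop("applicator radius must be at least one voxel")
  dim <- dim(volArray(hu)); origin <- originMm(hu)
  a <- spec$bodyAxes[1] / 2; b <- spec$bodyAxes[2] / 2
  pts <- appSpec$channel
  if (any(pts[, 1]^2 / a^2 + pts[, 2]^2 / b^2 > 1))
    stop("applicator channel extends outside the body")
  co <- gridCoords(dim, spacing, origin)
  m <- array(FALSE, dim)
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    v <- p1 - p0; L2 <- sum(v^2)
    X <- array(rep(co$x, times = dim[2] * dim[3]), dim)
    Y <- array(rep(rep(co$y, each = dim[1]), times = dim[3]), dim)
    Z <- array(rep(co$z, each = dim[1] * dim[2]), dim)
    t <- pmin(pmax(((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] +
                      (Z - p0[3]) * v[3]) / L2, 0), 1)
    d2 <- (X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
      (Z - (p0[3] + t * v[3]))^2
    m <- m | (d2 <= appSpec$radius^2)
  }
  la <- volArray(label); ha <- volArray(hu)
  la[m] <- spec$labels[["applicator"]]
  ha[m] <- appSpec$huValue
  list(label = VoxelVolume(la, spacing, origin, units = "label"),
       hu = VoxelVolume(ha, spacing, origin, units = "HU"))
}

#' Table-style ROI catalog for the phantom
#'
#' Ten spherical ROIs mirroring the census used in pelvis-phantom image
#' quality studies: six muscle ROIs spread over the background, one
#' adipose ROI in the peripheral shell, and one ROI each in the bladder,
#' uterus and rectum. The rectum ROI is the CNR target and one central
#' muscle ROI the CNR background.
#'
#' @param label phantom label [VoxelVolume-class] (applicator inserted or
#'   not).
#' @param spec the phantom specification used to generate `label`.
#' @return A data.frame with columns `name`, `tissue`, `x`, `y`, `z`,
#'   `radius` (mm), `role` (`target`, `background`, or empty). Errors if a
#'   requested structure is absent or an ROI is not entirely inside its
#'   structure.
#' @export
roiCatalog <- function(label, spec = defaultPhantomSpec()) {
  rois <- rbind(
    data.frame(name = paste0("muscle_", 1:6), tissue = "muscle",
               x = c(0, 0, 60, -60, -55, 55), y = c(-78, 32, 40, 40, -35, -55),
               z = 0, radius = 7, role = c("", "background", rep("", 4))),
    data.frame(name = "adipose", tissue = "adipose", x = 0, y = 93, z = 0,
               radius = 5, role = ""),
    data.frame(name = "bladder", tissue = "bladder", x = 0, y = -45, z = 0,
               radius = 10, role = ""),
    data.frame(name = "uterus", tissue = "uterus", x = 10, y = 2, z = 0,
               radius = 6, role = ""),
    data.frame(name = "rectum", tissue = "rectum", x = 0, y = 55, z = 0,
               radius = 7, role = "target"))
  la <- volArray(label)
  dim <- dim(la); spacing <- spacingMm(label); origin <- originMm(label)
  for (i in seq_len(nrow(rois))) {
    code <- spec$labels[[rois$tissue[i]]]
    if (is.null(code) || !any(la == code))
      stop("structure '", rois$tissue[i], "' absent from the label volume")
    m <- sphereMask(dim, spacing, origin,
                    c(rois$x[i], rois$y[i], rois$z[i]), rois$radius[i])
    if (!any(m)) stop("ROI '", rois$name[i], "' contains no voxels")
    if (!all(la[m] == code))
      stop("ROI '", rois$name[i], "' is not entirely inside its structure")
  }
  rois
}

#' Analytic structure mask on an arbitrary grid
#'
#' Evaluates the named phantom structure's analytic shape on a target grid
#' (e.g. a dose grid), giving exact masks without resampling a label
#' volume.
#'
#' @param spec phantom specification.
#' @param name structure name (all same-name shapes are combined).
#' @param dim,spacing,origin target grid description.
#' @return Logical array of dimension `dim`.
#' @export
structureMask <- function(spec, name, dim, spacing, origin) {
  sts <- Filter(function(s) s$name == name, spec$structures)
  if (!length(sts)) stop("no structure named '", name, "'")
  m <- array(FALSE, dim)
  for (st in sts) m <- m | structureMaskOnGrid(st, dim, spacing, origin)
  m
}
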