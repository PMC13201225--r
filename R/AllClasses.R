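#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib vesselmorph3d, .registration = TRUE
NULL

#' VoxelSpacing: physical size of a voxel in nanometres
#'
#' Anisotropic voxel pitch along x, y and z. In-plane isotropy (`sx == sy`)
#' is required because all per-slice (2D) operations assume it; the default
#' (8, 8, 33) nm is the analysis resolution of down-sampled serial-section EM.
#'
#' @slot sx,sy,sz Numeric, nm per voxel along each axis.
#' @export
setClass("VoxelSpacing",
         representation(sx = "numeric", sy = "numeric", sz = "numeric"))

setValidity("VoxelSpacing", function(object) {
  s <- c(object@sx, object@sy, object@sz)
  if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
    return("sx, sy, sz must be single, strictly positive numbers")
  if (object@sx != object@sy)
    return("in-plane isotropy required: sx must equal sy")
  TRUE
})

#' Construct a VoxelSpacing
#'
#' @param sx,sy,sz nm per voxel along x, y, z. Default `(8, 8, 33)`.
#' @return A [VoxelSpacing-class] object.
#' @examples
#' voxelSpacing()          # 8 x 8 x 33 nm
#' voxelSpacing(4, 4, 33)  # full-resolution in-plane pitch
#' @export
voxelSpacing <- function(sx = 8, sy = sx, sz = 33) {
  new("VoxelSpacing", sx = as.numeric(sx), sy = as.numeric(sy),
      sz = as.numeric(sz))
}

#' @describeIn VoxelSpacing-class numeric vector `c(sx, sy, sz)`
#' @param x,object A `VoxelSpacing`.
#' @param ... ignored.
#' @export
setMethod("as.numeric", "VoxelSpacing", function(x, ...)
  c(x@sx, x@sy, x@sz))

setMethod("show", "VoxelSpacing", function(object)
  cat(sprintf("VoxelSpacing: %g x %g x %g nm\n",
              object@sx, object@sy, object@sz)))

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' LabelVolume: a 3D grid of schema class codes
#'
#' Final 26-class voxel segmentation of a capillary crop. The array is stored
#' with dimensions `(nx, ny, nz)` = (x, y, z); z is the vessel's longitudinal
#' axis. `origin` records the voxel offset of the crop in dataset coordinates
#' so reported coordinates can be mapped back.
#'
#' @slot grid Integer array `(nx, ny, nz)` of codes 0--25 (see [labelSchema]).
#' @slot spacing A [VoxelSpacing-class].
#' @slot origin Integer length-3 voxel offset of the crop (x, y, z).
#' @export
setClass("LabelVolume",
         representation(grid = "array", spacing = "VoxelSpacing",
                        origin = "integer"))

setValidity("LabelVolume", function(object) {
  g <- object@grid
  if (length(dim(g)) != 3L) return("grid must be a 3D array (x, y, z)")
  if (!is.integer(g)) return("grid must be an integer array")
  bad <- unique(g[g < 0L | g > 25L])
  if (length(bad))
    return(paste0("invalid schema codes present: ",
                  paste(sort(bad), collapse = ", ")))
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Construct a LabelVolume
#'
#' @param grid 3D integer array of schema codes, axes (x, y, z).
#' @param spacing A [VoxelSpacing-class] (default 8 x 8 x 33 nm).
#' @param origin Integer length-3 crop offset in dataset voxel coordinates.
#' @return A [LabelVolume-class].
#' @export
LabelVolume <- function(grid, spacing = voxelSpacing(),
                        origin = c(0L, 0L, 0L)) {
  storage.mode(grid) <- "integer"
  new("LabelVolume", grid = grid, spacing = spacing,
      origin = as.integer(origin))
}

#' IntensityVolume: 8-bit grayscale EM image co-registered with labels
#'
#' @slot grid Integer array `(nx, ny, nz)` with values in 0--255.
#' @slot spacing A [VoxelSpacing-class].
#' @slot origin Integer length-3 crop offset.
#' @export
setClass("IntensityVolume",
         representation(grid = "array", spacing = "VoxelSpacing",
                        origin = "integer"))

setValidity("IntensityVolume", function(object) {
  g <- object@grid
  if (length(dim(g)) != 3L) return("grid must be a 3D array (x, y, z)")
  if (min(g) < 0 || max(g) > 255) return("intensities must lie in [0, 255]")
  TRUE
})

#' Construct an IntensityVolume
#' @param grid 3D array of 8-bit intensities (0--255).
#' @param spacing A [VoxelSpacing-class].
#' @param origin Integer length-3 crop offset.
#' @return An [IntensityVolume-class].
#' @export
IntensityVolume <- function(grid, spacing = voxelSpacing(),
                            origin = c(0L, 0L, 0L)) {
  storage.mode(grid) <- "integer"
  new("IntensityVolume", grid = grid, spacing = spacing,
      origin = as.integer(origin))
}

#' SemanticVolume: raw 7-class semantic prediction
#'
#' Output of a semantic segmentation model before post-processing
#' (see [semanticSchema]). The optional `interior` mask marks voxels inside
#' the vessel's outer basement-membrane boundary; it is populated by
#' [removeExterior] and consumed by [fillCytosol] / [assignCellTypes].
#'
#' @slot grid Integer array of codes 0--6.
#' @slot spacing A [VoxelSpacing-class].
#' @slot interior Logical array of the same shape, or NULL before
#'   exterior removal.
#' @export
setClass("SemanticVolume",
         representation(grid = "array", spacing = "VoxelSpacing",
                        interior = "arrayOrNULL"))

setValidity("SemanticVolume", function(object) {
  g <- object@grid
  if (length(dim(g)) != 3L) return("grid must be a 3D array (x, y, z)")
  if (min(g) < 0L || max(g) > 6L) return("semantic codes must lie in 0..6")
  if (!is.null(object@interior) &&
      !identical(dim(object@interior), dim(g)))
    return("interior mask must match grid dimensions")
  TRUE
})

#' Construct a SemanticVolume
#' @param grid 3D integer array of semantic codes 0--6.
#' @param spacing A [VoxelSpacing-class].
#' @param interior Optional logical array marking intra-vessel voxels.
#' @return A [SemanticVolume-class].
#' @export
SemanticVolume <- function(grid, spacing = voxelSpacing(), interior = NULL) {
  storage.mode(grid) <- "integer"
  new("SemanticVolume", grid = grid, spacing = spacing, interior = interior)
}

#' PegSet: detected peg-and-socket components with morphometrics
#'
#' One row of `table` per 26-connected peg component: `id`, `peg_type`
#' (PC-EC / EC-PC / EC-EC), `host`, `recipient`, `n_voxels`, `volume_nm3`,
#' `z_length_nm`, `max_xy_diameter_nm`, `aspect_ratio`, `axial_position_um`,
#' and voxel-centroid coordinates. `voxels` holds the matching voxel index
#' matrices (columns x, y, z).
#'
#' @slot table data.frame of per-peg metrics.
#' @slot voxels list of integer matrices (one per peg).
#' @slot spacing A [VoxelSpacing-class].
#' @export
setClass("PegSet",
         representation(table = "data.frame", voxels = "list",
                        spacing = "VoxelSpacing"))

setValidity("PegSet", function(object) {
  if (nrow(object@table) != length(object@voxels))
    return("table rows and voxel list must have equal length")
  TRUE
})

#' PhantomGroundTruth: generator parameters and true quantities
#'
#' Ground truth emitted alongside a synthetic vessel phantom, for
#' parameter-recovery testing: per-slice and mean PC coverage, the basement
#' membrane thickness by surface domain, the planted peg table (with true arc
#' distance to the nearest PC edge), the planted ELP table, the ER socket-bias
#' factor, and the PC nucleus axial area profile.
#'
#' @slot coverage data.frame `(slice, fraction)`.
#' @slot meanCoverage numeric, mean planted arc coverage fraction.
#' @slot thicknessByDomain named numeric (nm) for soma / process / non-covered.
#' @slot pegs data.frame of planted pegs.
#' @slot elps data.frame of planted ELPs.
#' @slot erSocketBias numeric bias factor.
#' @slot nucleusAreaProfile data.frame `(slice, area_um2)` for the PC nucleus.
#' @slot params list, the generating parameters.
#' @export
setClass("PhantomGroundTruth",
         representation(coverage = "data.frame", meanCoverage = "numeric",
                        thicknessByDomain = "numeric", pegs = "data.frame",
                        elps = "data.frame", erSocketBias = "numeric",
                        nucleusAreaProfile = "data.frame", params = "list"))

## ---- generics & accessors ---------------------------------------------------

#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @describeIn LabelVolume-class the raw integer array
#' @param x A volume object.
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@grid)
#' @describeIn IntensityVolume-class the raw integer array
#' @export
setMethod("voxelData", "IntensityVolume", function(x) x@grid)
#' @describeIn SemanticVolume-class the raw integer array
#' @export
setMethod("voxelData", "SemanticVolume", function(x) x@grid)

#' @describeIn LabelVolume-class the voxel spacing
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @describeIn IntensityVolume-class the voxel spacing
#' @export
setMethod("spacing", "IntensityVolume", function(x) x@spacing)
#' @describeIn SemanticVolume-class the voxel spacing
#' @export
setMethod("spacing", "SemanticVolume", function(x) x@spacing)
#' @describeIn PegSet-class the voxel spacing
#' @export
setMethod("spacing", "PegSet", function(x) x@spacing)

#' @describeIn LabelVolume-class crop origin in dataset voxel coordinates
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)
#' @describeIn IntensityVolume-class crop origin
#' @export
setMethod("origin", "IntensityVolume", function(x) x@origin)

#' @export
setGeneric("pegTable", function(x) standardGeneric("pegTable"))
#' @describeIn PegSet-class data.frame of per-peg metrics
#' @param x A `PegSet`.
#' @export
setMethod("pegTable", "PegSet", function(x) x@table)

#' @export
setGeneric("pegVoxels", function(x, i) standardGeneric("pegVoxels"))
#' @describeIn PegSet-class voxel coordinates (columns x, y, z) of peg `i`
#' @param i Peg index.
#' @export
setMethod("pegVoxels", "PegSet", function(x, i) x@voxels[[i]])

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@grid)
  cl <- sort(unique(as.vector(object@grid)))
  cat(sprintf("LabelVolume: %d x %d x %d voxels @ %g x %g x %g nm\n",
              d[1], d[2], d[3], object@spacing@sx, object@spacing@sy,
              object@spacing@sz))
  cat("  classes present:", paste(cl, collapse = " "), "\n")
  cat("  origin:", paste(object@origin, collapse = ", "), "\n")
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("IntensityVolume: %d x %d x %d voxels, range [%d, %d]\n",
              d[1], d[2], d[3], min(object@grid), max(object@grid)))
})

setMethod("show", "SemanticVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("SemanticVolume: %d x %d x %d voxels (7-class)%s\n",
              d[1], d[2], d[3],
              if (is.null(object@interior)) "" else ", interior marked"))
})

setMethod("show", "PegSet", function(object) {
  tb <- object@table
  cat(sprintf("PegSet: %d pegs (PC-EC %d, EC-PC %d, EC-EC %d)\n",
              nrow(tb), sum(tb$peg_type == "PC-EC"),
              sum(tb$peg_type == "EC-PC"), sum(tb$peg_type == "EC-EC")))
  if (nrow(tb)) print(utils::head(tb, 5))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf(
    "PhantomGroundTruth: mean coverage %.1f%%, %d pegs, %d ELPs\n",
    100 * object@meanCoverage, nrow(object@pegs), nrow(object@elps)))
})
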