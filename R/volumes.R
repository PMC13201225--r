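## Volume I/O: multi-page TIFF (one page per z slice) plus a JSON sidecar
## carrying spacing, origin, axis order and schema version.

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, spacing, origin, kind) {
  meta <- list(kind = kind, axes = "xyz",
               spacing_nm = as.numeric(spacing),
               origin_voxels = as.integer(origin),
               schema_version = 1L)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

.writePages <- function(grid, path, bits, maxval) {
  pages <- lapply(seq_len(dim(grid)[3]),
                  function(k) grid[, , k] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
}

.readPages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  g <- array(0L, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) g[, , k] <- as.integer(pages[[k]])
  g
}

#' Write a LabelVolume to a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per z slice; `path.json` records spacing, origin and
#' schema version. The round trip through [readLabelVolume] is voxelwise
#' exact.
#'
#' @param vol A [LabelVolume-class].
#' @param path Output TIFF file path.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  .writePages(vol@grid, path, bits = 16L, maxval = 65535)
  .writeSidecar(path, spacing(vol), origin(vol), "label")
  invisible(path)
}

#' Read a LabelVolume from a multi-page TIFF
#'
#' Codes outside the 0--25 schema are a hard error naming the offending
#' codes. Spacing/origin come from the JSON sidecar when present, else from
#' the arguments.
#'
#' @param path TIFF file path.
#' @param spacing Fallback [VoxelSpacing-class] if no sidecar exists.
#' @param origin Fallback origin.
#' @return A [LabelVolume-class].
#' @export
readLabelVolume <- function(path, spacing = voxelSpacing(),
                            origin = c(0L, 0L, 0L)) {
  if (!file.exists(path)) stop("cannot read label volume: ", path)
  g <- .readPages(path)
  bad <- sort(unique(g[g < 0L | g > 25L]))
  if (length(bad))
    stop("label volume contains codes outside the 0-25 schema: ",
         paste(bad, collapse = ", "))
  meta <- .readSidecar(path)
  if (!is.null(meta)) {
    spacing <- voxelSpacing(meta$spacing_nm[1], meta$spacing_nm[2],
                            meta$spacing_nm[3])
    origin <- meta$origin_voxels
  }
  LabelVolume(g, spacing = spacing, origin = origin)
}

#' Write an IntensityVolume to an 8-bit multi-page TIFF
#' @param vol An [IntensityVolume-class].
#' @param path Output TIFF file path.
#' @return `path`, invisibly.
#' @export
writeIntensityVolume <- function(vol, path) {
  stopifnot(is(vol, "IntensityVolume"))
  .writePages(vol@grid, path, bits = 8L, maxval = 255)
  .writeSidecar(path, spacing(vol), origin(vol), "intensity")
  invisible(path)
}

#' Read an IntensityVolume from an 8-bit multi-page TIFF
#' @param path TIFF file path.
#' @param spacing Fallback [VoxelSpacing-class] if no sidecar exists.
#' @param origin Fallback origin.
#' @return An [IntensityVolume-class].
#' @export
readIntensityVolume <- function(path, spacing = voxelSpacing(),
                                origin = c(0L, 0L, 0L)) {
  if (!file.exists(path)) stop("cannot read intensity volume: ", path)
  g <- .readPages(path)
  meta <- .readSidecar(path)
  if (!is.null(meta)) {
    spacing <- voxelSpacing(meta$spacing_nm[1], meta$spacing_nm[2],
                            meta$spacing_nm[3])
    origin <- meta$origin_voxels
  }
  IntensityVolume(g, spacing = spacing, origin = origin)
}
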