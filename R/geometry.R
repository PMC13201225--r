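#' Inclusive 3D bounding box in voxel coordinates
#'
#' Both ends are inclusive, so a box spanning z 600--1519 contains 920 axial
#' slices.
#'
#' @param x_lo,x_hi,y_lo,y_hi,z_lo,z_hi Integer voxel indices, `lo <= hi`.
#' @return A named list of class `"BoundingBox"`.
#' @export
boundingBox <- function(x_lo, x_hi, y_lo, y_hi, z_lo, z_hi) {
  b <- list(x_lo = as.integer(x_lo), x_hi = as.integer(x_hi),
            y_lo = as.integer(y_lo), y_hi = as.integer(y_hi),
            z_lo = as.integer(z_lo), z_hi = as.integer(z_hi))
  if (b$x_lo > b$x_hi || b$y_lo > b$y_hi || b$z_lo > b$z_hi)
    stop("bounding box must satisfy lo <= hi on every axis")
  class(b) <- "BoundingBox"
  b
}

#' Dataset bounding boxes of the three analysed vessels
#'
#' Voxel-coordinate bounding boxes (full-resolution dataset coordinates,
#' inclusive on both ends) of the three capillary crops V1--V3.
#'
#' @return Named list of [boundingBox] objects.
#' @examples
#' axialLengthUm(vesselBoundingBoxes()$V1)  # 30.36
#' @export
vesselBoundingBoxes <- function() {
  list(
    V1 = boundingBox(249800L, 252000L, 175000L, 177200L, 600L, 1519L),
    V2 = boundingBox(207300L, 209100L, 161130L, 162930L, 0L, 999L),
    V3 = boundingBox(329300L, 330700L, 187700L, 189350L, 500L, 1529L)
  )
}

#' Axial (longitudinal) length of a bounding box in micrometres
#'
#' `(z_hi - z_lo + 1) * sz`, converted to um. The section pitch, not the
#' in-plane pitch, sets the length because vessels are oriented along z.
#'
#' @param bbox A [boundingBox].
#' @param spacing A [VoxelSpacing-class]; default 8 x 8 x 33 nm.
#' @return Length in micrometres.
#' @export
axialLengthUm <- function(bbox, spacing = voxelSpacing()) {
  stopifnot(inherits(bbox, "BoundingBox"))
  (bbox$z_hi - bbox$z_lo + 1) * spacing@sz / 1000
}

#' Physical volume of a voxel mask
#'
#' @param mask Logical (or 0/1) array.
#' @param spacing A [VoxelSpacing-class].
#' @return Volume in cubic nanometres: `sum(mask) * sx * sy * sz`.
#' @export
physicalVolumeNm3 <- function(mask, spacing = voxelSpacing()) {
  sum(mask != 0) * spacing@sx * spacing@sy * spacing@sz
}

#' Exact anisotropic Euclidean distance transform
#'
#' Distance (in nm) from every voxel to the nearest source voxel, with each
#' axis weighted by its physical pitch. Exact (separable parabolic envelope),
#' not a chamfer approximation, so a +1 z-step at 8 x 8 x 33 nm spacing is
#' exactly 33 nm.
#'
#' @param mask Logical/0-1 array (2D or 3D) of source voxels; must be
#'   non-empty.
#' @param spacing A [VoxelSpacing-class]. For 2D input only `sx`, `sy` apply.
#' @return Numeric array of distances in nm, zero exactly on source voxels.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' d <- anisotropicEDT(m, voxelSpacing(8, 8, 33))
#' d[3, 3, 4]  # 33
#' @export
anisotropicEDT <- function(mask, spacing = voxelSpacing()) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array or matrix")
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stop("mask must be 2D or 3D")
  if (!any(mask != 0)) stop("empty source mask: distance field undefined")
  out <- .cpp_edt(as.integer(mask != 0), as.integer(d),
                  as.numeric(spacing))
  array(out, dim(mask))
}

## ---- internal grid utilities -----------------------------------------------

## distance field without the S4 ceremony (mask may be empty -> all Inf)
.edt <- function(mask, sp) {
  d <- dim(mask); if (length(d) == 2L) d <- c(d, 1L)
  if (!any(mask)) return(array(Inf, dim(mask)))
  array(.cpp_edt(as.integer(mask), as.integer(d), as.numeric(sp)), dim(mask))
}

## 2D distance field in pixel units (in-plane isotropy assumed)
.edt2px <- function(mask) {
  d <- dim(mask)
  if (!any(mask)) return(array(Inf, d))
  array(.cpp_edt(as.integer(mask), as.integer(c(d, 1L)), c(1, 1, 1)), d)
}

## connected components: conn = 26 (3D) or 8 (2D / per-slice, pass one slice)
.label <- function(mask, conn = 26L) {
  d <- dim(mask); if (length(d) == 2L) d <- c(d, 1L)
  lab <- .cpp_label(as.integer(mask), as.integer(d), as.integer(conn))
  n <- attr(lab, "n")
  lab <- array(lab, dim(mask))
  attr(lab, "n") <- n
  lab
}

## per-slice 8-connected labeling with labels unique across slices
.labelSlices <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  off <- 0L
  for (k in seq_len(d[3])) {
    lk <- .label(mask[, , k], conn = 8L)
    nk <- attr(lk, "n")
    idx <- lk != 0L
    out[, , k][idx] <- lk[idx] + off
    off <- off + nk
  }
  attr(out, "n") <- off
  out
}

## shift a 2D matrix by (di, dj), padding with `fill`
.shift2 <- function(m, di, dj, fill = FALSE) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  si <- max(1, 1 - di):min(n1, n1 - di)
  sj <- max(1, 1 - dj):min(n2, n2 - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

## TRUE where the 2D mask has an 8-neighbour equal to `what` (padded value
## `pad` acts as the outside of the image)
.hasNeighbor2 <- function(test, conn = 8L, pad = TRUE) {
  offs <- if (conn == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  acc <- matrix(FALSE, nrow(test), ncol(test))
  for (r in seq_len(nrow(offs)))
    acc <- acc | .shift2(test, offs[r, 1], offs[r, 2], fill = pad)
  acc
}

## 8-connected boundary pixels of a 2D mask (pixel in mask with an
## 8-neighbour outside it; image border counts as outside)
.perim8 <- function(mask) {
  mask & .hasNeighbor2(!mask, conn = 8L, pad = TRUE)
}

## 6-connected 3D boundary: voxels of `mask` with a face neighbour in `other`
.touches6 <- function(mask, other) {
  d <- dim(mask)
  acc <- array(FALSE, d)
  shift3 <- function(a, dv) {
    out <- array(FALSE, d)
    sx <- max(1, 1 - dv[1]):min(d[1], d[1] - dv[1])
    sy <- max(1, 1 - dv[2]):min(d[2], d[2] - dv[2])
    sz <- max(1, 1 - dv[3]):min(d[3], d[3] - dv[3])
    out[sx + dv[1], sy + dv[2], sz + dv[3]] <- a[sx, sy, sz]
    out
  }
  for (dv in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    acc <- acc | shift3(other, dv)
  mask & acc
}

## count exposed faces (towards `other`) per voxel of mask, by axis:
## returns list(x=, y=, z=) integer arrays
.exposedFaces <- function(mask, other) {
  d <- dim(mask)
  shift3 <- function(a, dv, pad = FALSE) {
    out <- array(pad, d)
    sx <- max(1, 1 - dv[1]):min(d[1], d[1] - dv[1])
    sy <- max(1, 1 - dv[2]):min(d[2], d[2] - dv[2])
    sz <- max(1, 1 - dv[3]):min(d[3], d[3] - dv[3])
    out[sx + dv[1], sy + dv[2], sz + dv[3]] <- a[sx, sy, sz]
    out
  }
  list(
    x = (shift3(other, c(1, 0, 0)) + shift3(other, c(-1, 0, 0))) * mask,
    y = (shift3(other, c(0, 1, 0)) + shift3(other, c(0, -1, 0))) * mask,
    z = (shift3(other, c(0, 0, 1)) + shift3(other, c(0, 0, -1))) * mask
  )
}

## 2D disk morphology via exact pixel-unit EDT (in-plane isotropy)
.erode2 <- function(mask, r) {
  if (!any(!mask)) return(mask)
  .edt2px(!mask) > r
}
.dilate2 <- function(mask, r) {
  if (!any(mask)) return(mask)
  .edt2px(mask) <= r
}
.open2 <- function(mask, r) .dilate2(.erode2(mask, r), r)
.close2 <- function(mask, r) {
  ## pad so closing cannot leak across the image border
  p <- ceiling(r) + 1L
  d <- dim(mask)
  big <- matrix(FALSE, d[1] + 2 * p, d[2] + 2 * p)
  big[p + seq_len(d[1]), p + seq_len(d[2])] <- mask
  cl <- .erode2(.dilate2(big, r), r)
  cl[p + seq_len(d[1]), p + seq_len(d[2])]
}

## fill enclosed complement regions of a 2D mask smaller than max_px
.fillSmallHoles <- function(mask, max_px = 2000L) {
  comp <- !mask
  lab <- .label(comp, conn = 4L)
  n <- attr(lab, "n")
  if (!n) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[comp], nbins = n)
  fill <- setdiff(which(sizes < max_px), border)
  if (length(fill)) mask[array(lab %in% fill, dim(mask))] <- TRUE
  mask
}

## voxel index matrix (x, y, z columns) of a mask
.whichVox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("x", "y", "z")[seq_len(ncol(w))]
  w
}

## max pairwise in-plane distance (Feret) between pixel centres, via the
## convex hull; `xy` is an n x 2 matrix in pixel units
.feretPx <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n == 1L) return(0)
  if (n == 2L) return(sqrt(sum((xy[1, ] - xy[2, ])^2)))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hp <- xy[h, , drop = FALSE]
  dd <- as.matrix(stats::dist(hp))
  max(dd)
}
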