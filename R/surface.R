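## Surface morphometrics: pericyte coverage, basement-membrane thickness
## mapping, the three-domain surface partition, and ELP volume per unit
## surface area.

#' Smoothed EC mask for coverage measurement
#'
#' The EC surface is smoothed for perimeter analysis by adding PC-peg voxels
#' to the EC mask (filling the sockets) and removing EC-peg voxels (which
#' protrude into the PC). EC-EC junction and EC-EC peg voxels, which are
#' interior to the EC shell, are filled as well so the abluminal perimeter
#' stays simple; on junction-free volumes the mask equals the EC classes
#' plus PC pegs exactly.
#'
#' @param vol A [LabelVolume-class].
#' @return Logical array.
#' @export
smoothedEcMask <- function(vol) {
  g <- voxelData(vol)
  keep <- c(setdiff(classGroup("EC_CELL"), classGroup("PEG_EC")),
            classGroup("PEG_PC"), 18L)
  array(g %in% keep, dim(g))
}

#' Pericyte coverage of the abluminal EC surface
#'
#' Per slice, the perimeter pixels of the smoothed EC mask (pixels with an
#' 8-neighbour outside the mask) are classified: pixels whose nearest
#' non-mask neighbourhood contains lumen are luminal and excluded; the
#' remaining (abluminal) pixels count as PC-covered when the nearest PC
#' voxel in the same slice lies within the coverage radius. The default
#' radius is the slice's estimated EC-PC interface BM thickness plus
#' `radius_slack_px` in-plane pitches (the paper-scale criterion "PC within
#' one interface thickness"); `coverage_radius_nm` overrides it.
#'
#' @param vol A [LabelVolume-class].
#' @param coverage_radius_nm Fixed coverage radius in nm, or `NA` to use the
#'   per-slice interface-thickness estimate.
#' @param radius_slack_px Pitches added to the interface-thickness estimate
#'   (default 1.25, calibrated on phantoms).
#' @param fallback_radius_nm Radius used when a slice has no measurable
#'   EC-PC interface.
#' @param gap_close_px Closing radius (pixels) bridging junction seams and
#'   socket wedges in the EC mask before tracing the perimeter.
#' @return list of class `"CoverageProfile"`: `per_slice` data.frame
#'   (slice, n_perimeter, n_covered, percent, perimeter_nm, radius_nm),
#'   `mean_percent` (mean over slices with EC), and `excluded_slices`.
#' @export
pcCoverage <- function(vol, coverage_radius_nm = NA, radius_slack_px = 1.25,
                       fallback_radius_nm = 200, gap_close_px = 18) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  sx <- sp@sx
  ecMask <- smoothedEcMask(vol)
  pcCls <- classGroup("PC_CELL")
  bmCls <- classGroup("BM")
  excluded <- integer(0)
  rows <- NULL
  for (k in seq_len(d[3])) {
    gm <- g[, , k]
    em <- ecMask[, , k]
    if (!any(em)) { excluded <- c(excluded, k); next }
    ## bridge junction seams/wedges that interrupt the EC shell, so the
    ## traced contour does not detour into them
    if (gap_close_px > 0) em <- .close2(em, gap_close_px)
    ## abluminal perimeter = the outer boundary contour of the EC mask
    ## (the luminal boundary is the annulus' inner contour and is not
    ## traced); an ordered contour lets the edge overshoot be trimmed
    path <- .mooreTrace(em)
    if (nrow(path) < 8) { excluded <- c(excluded, k); next }
    ## if an unbridged gap leaves the shell open, the traced contour also
    ## runs along the lumen: such pixels are luminal, not abluminal
    lumAdj <- .hasNeighbor2(gm == 4L, conn = 8L, pad = FALSE)
    abl <- !(lumAdj[path] | (gm == 4L)[path])
    if (!any(abl)) { excluded <- c(excluded, k); next }
    pcHere <- matrix(gm %in% pcCls, d[1], d[2])
    dPC <- .edt2px(pcHere) * sx
    rad <- coverage_radius_nm
    t_if <- .interfaceThicknessNm(gm, em, pcHere, bmCls, sx)
    if (is.na(rad)) {
      rad <- if (is.na(t_if)) fallback_radius_nm
             else t_if + radius_slack_px * sx
    }
    covered <- dPC[path] <= rad + 1e-9
    ## trim the geometric overshoot at each covered-run end: a perimeter
    ## pixel just beyond the PC edge still sees the PC within
    ## sqrt(rad^2 - d0^2) of arc, d0 being the radial pixel distance
    if (any(covered) && !all(covered)) {
      d0 <- if (is.na(t_if)) rad else t_if + sx
      trim <- floor(sqrt(max(rad^2 - d0^2, 0)) / sx)
      if (trim > 0) covered <- .trimCyclicRuns(covered, trim)
    }
    ## arc-length weighting: digital contours carry more pixels per radian
    ## on diagonal stretches, so pixel counting would bias the percentage
    steps <- .arcStepsNm(rbind(path, path[1, , drop = FALSE]), sx)
    npix <- nrow(path)
    w <- (steps + c(steps[npix], steps[-npix])) / 2
    tot <- sum(w[abl]); cov_nm <- sum(w[covered & abl])
    rows <- rbind(rows, data.frame(
      slice = k, n_perimeter = sum(abl), n_covered = sum(covered & abl),
      percent = 100 * cov_nm / tot, perimeter_nm = tot, radius_nm = rad))
  }
  if (is.null(rows))
    stop("no slice contains an EC mask; cannot measure coverage")
  out <- list(per_slice = rows, mean_percent = mean(rows$percent),
              excluded_slices = excluded)
  class(out) <- "CoverageProfile"
  out
}

## shorten every maximal cyclic run of TRUE by `trim` elements at each end
.trimCyclicRuns <- function(x, trim) {
  n <- length(x)
  ## rotate so position 1 is FALSE, trim linearly, rotate back
  z <- which(!x)[1]
  rot <- if (z == 1) x else c(x[z:n], x[seq_len(z - 1)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    len <- r$lengths[i]
    k <- min(trim, len %/% 2)
    if (k > 0) {
      rot[starts[i]:(starts[i] + k - 1)] <- FALSE
      rot[(ends[i] - k + 1):ends[i]] <- FALSE
    }
  }
  if (z == 1) rot else c(rot[(n - z + 2):n], rot[seq_len(n - z + 1)])
}

## estimate the EC-PC interface BM thickness in a slice: twice the upper
## quantile of the cell-distance field over BM pixels close to both cells
.interfaceThicknessNm <- function(gm, em, pcHere, bmCls, sx) {
  bm <- matrix(gm %in% bmCls, nrow(gm), ncol(gm))
  if (!any(bm) || !any(pcHere)) return(NA_real_)
  dEC <- .edt2px(em) * sx
  dPC <- .edt2px(pcHere) * sx
  iface <- bm & dEC <= 4 * sx & dPC <= 4 * sx
  if (sum(iface) < 8) return(NA_real_)
  cells <- em | pcHere
  dCell <- .edt2px(cells) * sx
  2 * stats::quantile(dCell[iface], 0.95, names = FALSE)
}

#' Basement-membrane thickness sampled on the outer surface
#'
#' The anisotropic distance field from the cell mask (EC and PC including
#' all organelles and pegs) is sampled at the outer-perimeter BM voxels
#' (BM or BM-ELP voxels 6-adjacent to background in 3D).
#'
#' @param vol A [LabelVolume-class].
#' @return list of class `"SurfaceThickness"`: `voxels` (n x 3 matrix),
#'   `thickness_nm`, `mean_nm`.
#' @export
bmThicknessSurface <- function(vol) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  bm <- array(g %in% classGroup("BM"), d)
  if (!any(bm)) stop("no basement-membrane voxels present")
  cells <- array(g %in% c(classGroup("EC_CELL"), classGroup("PC_CELL")), d)
  dist <- .edt(cells, sp)
  surf <- .touches6(bm, array(g == 0L, d))
  vox <- .whichVox(surf)
  th <- dist[surf]
  list(voxels = vox, thickness_nm = th, mean_nm = mean(th))
}

#' Partition the outer BM surface into soma / process / non-covered domains
#'
#' Each outer-surface voxel is assigned to the nearest of three source
#' regions by anisotropic distance: the PC soma, the PC processes (PC minus
#' soma), and the EC (non-covered). Ties break with priority
#' soma > process > non-covered. Deterministic and total.
#'
#' @param vol A [LabelVolume-class].
#' @param soma_mask Logical array of PC-soma voxels (ground truth for
#'   phantoms via [phantomSomaMask]; on real data a PC-nucleus dilation
#'   heuristic, see [somaMaskFromNucleus]).
#' @return list of class `"SurfaceDomainMap"`: `voxels`, `domain` (factor
#'   soma/process/non_covered), `thickness_nm`, `area_nm2` (per-voxel
#'   exposed-face area), and `summary` data.frame per domain.
#' @export
partitionSurface <- function(vol, soma_mask) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  bm <- array(g %in% classGroup("BM"), d)
  if (!any(bm)) stop("no basement-membrane voxels present")
  bg <- array(g == 0L, d)
  surf <- .touches6(bm, bg)
  vox <- .whichVox(surf)

  pcAll <- array(g %in% classGroup("PC_CELL"), d)
  ecAll <- array(g %in% classGroup("EC_CELL"), d)
  soma <- pcAll & soma_mask
  proc <- pcAll & !soma
  dSoma <- if (any(soma)) .edt(soma, sp) else array(Inf, d)
  dProc <- if (any(proc)) .edt(proc, sp) else array(Inf, d)
  dEC <- if (any(ecAll)) .edt(ecAll, sp) else array(Inf, d)

  ds <- cbind(soma = dSoma[surf], process = dProc[surf],
              non_covered = dEC[surf])
  ## ties break by fixed priority soma > process > non-covered: max.col
  ## with ties.method "first" on the negated distances
  pick <- max.col(-ds, ties.method = "first")
  domain <- factor(c("soma", "process", "non_covered")[pick],
                   levels = c("soma", "process", "non_covered"))

  cells <- ecAll | pcAll
  th <- .edt(cells, sp)[surf]

  fa <- .exposedFaces(bm & surf, bg)
  areaArr <- fa$x * sp@sy * sp@sz + fa$y * sp@sx * sp@sz +
    fa$z * sp@sx * sp@sy
  area <- areaArr[surf]

  summ <- data.frame(
    domain = levels(domain),
    n_voxels = as.integer(table(domain)),
    mean_thickness_nm = as.numeric(tapply(th, domain, mean)),
    area_um2 = as.numeric(tapply(area, domain, sum)) / 1e6)
  out <- list(voxels = vox, domain = domain, thickness_nm = th,
              area_nm2 = area, summary = summ)
  class(out) <- "SurfaceDomainMap"
  out
}

#' Heuristic soma mask from the PC nucleus
#'
#' PC voxels within `radius_nm` of the PC nucleus, for use on real data
#' where no ground-truth soma extent exists.
#'
#' @param vol A [LabelVolume-class].
#' @param radius_nm Dilation radius (default 1000 nm).
#' @return Logical array.
#' @export
somaMaskFromNucleus <- function(vol, radius_nm = 1000) {
  g <- voxelData(vol)
  d <- dim(g)
  nuc <- array(g == 6L, d)
  if (!any(nuc)) stop("no PC nucleus present")
  dn <- .edt(nuc, spacing(vol))
  array(g %in% classGroup("PC_CELL"), d) & dn <= radius_nm
}

#' ELP volume per unit surface area, by surface domain
#'
#' Each 26-connected component of the BM-ELP class (17) is assigned to the
#' domain whose source region is nearest its centroid; per domain, the total
#' ELP volume is divided by the domain's exposed-face surface area.
#'
#' @param vol A [LabelVolume-class].
#' @param domains A `SurfaceDomainMap` from [partitionSurface].
#' @param soma_mask The soma mask used for the partition.
#' @return data.frame (domain, n_elps, elp_volume_um3, area_um2,
#'   elp_per_area_um) where `elp_per_area_um` is um^3 per um^2.
#' @export
elpVolumePerArea <- function(vol, domains, soma_mask) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  vv <- sp@sx * sp@sy * sp@sz
  res <- domains$summary[, c("domain", "area_um2")]
  res$n_elps <- 0L
  res$elp_volume_um3 <- 0
  m <- array(g == 17L, d)
  if (any(m)) {
    pcAll <- array(g %in% classGroup("PC_CELL"), d)
    ecAll <- array(g %in% classGroup("EC_CELL"), d)
    soma <- pcAll & soma_mask
    proc <- pcAll & !soma
    dSoma <- if (any(soma)) .edt(soma, sp) else array(Inf, d)
    dProc <- if (any(proc)) .edt(proc, sp) else array(Inf, d)
    dEC <- if (any(ecAll)) .edt(ecAll, sp) else array(Inf, d)
    lab <- .label(m, conn = 26L)
    vox <- .whichVox(m)
    ids <- lab[m]
    for (id in seq_len(attr(lab, "n"))) {
      v <- vox[ids == id, , drop = FALSE]
      cen <- pmax(1, pmin(round(colMeans(v)),  d))
      ci <- matrix(cen, 1)
      dd <- c(dSoma[ci], dProc[ci], dEC[ci])
      dom <- c("soma", "process", "non_covered")[which.min(dd)]
      i <- match(dom, res$domain)
      res$n_elps[i] <- res$n_elps[i] + 1L
      res$elp_volume_um3[i] <- res$elp_volume_um3[i] + nrow(v) * vv / 1e9
    }
  }
  res$elp_per_area_um <- ifelse(res$area_um2 > 0,
                                res$elp_volume_um3 / res$area_um2, 0)
  res
}

#' Detect ELPs from image intensity inside the BM mask
#'
#' For volumes whose annotation lacks the ELP class: bright voxels
#' (intensity strictly above `threshold`) inside the BM mask whose
#' 26-connected component has at least `min_voxels` voxels are relabeled
#' as class 17. An extension of the annotation schema using the
#' electron-lucency threshold.
#'
#' @param vol A [LabelVolume-class].
#' @param img A co-registered [IntensityVolume-class].
#' @param threshold Intensity threshold (strict inequality), default 180.
#' @param min_voxels Minimum component size.
#' @return A [LabelVolume-class] with class 17 populated.
#' @export
detectELPs <- function(vol, img, threshold = 180, min_voxels = 8) {
  g <- voxelData(vol)
  d <- dim(g)
  if (!identical(d, dim(voxelData(img))))
    stop("label and intensity volumes have different shapes")
  cand <- array(g == 1L & voxelData(img) > threshold, d)
  if (any(cand)) {
    lab <- .label(cand, conn = 26L)
    sizes <- tabulate(lab[cand], nbins = attr(lab, "n"))
    keep <- which(sizes >= min_voxels)
    g[cand & array(lab %in% keep, d)] <- 17L
  }
  LabelVolume(g, spacing = spacing(vol), origin = origin(vol))
}
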