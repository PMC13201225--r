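## Peg edge-distance coordinate system and distributions, and peg-to-EC-
## nucleus proximity mapping.

#' Edge coordinate system of the PC's lumen-facing boundary in one slice
#'
#' For each PC section (8-connected component of the PC mask, pegs
#' excluded) that does not fully wrap the vessel, the section boundary is
#' traced, its lumen-facing part extracted (boundary pixels nearer the
#' lumen than the vessel exterior), and an arc-length coordinate
#' accumulated along it. Each arc pixel's position value is its distance to
#' the nearer of the two arc endpoints (the PC "edges"), so the maximum
#' available position is half the arc length.
#'
#' @param vol A [LabelVolume-class].
#' @param slice Slice index.
#' @param smooth_window Moving-average window (pixels) of the polyline
#'   smoothing used for arc-length measurement.
#' @param socket_close_px Closing radius (pixels) that bridges EC-peg
#'   socket openings on the PC boundary.
#' @return list of class `"EdgeCoordinateSystem"`: `sections`, each with
#'   `pixels` (n x 2), `position_nm`, `arc_length_nm`; plus
#'   `skipped_annular` (count of fully wrapping sections).
#' @export
buildEdgeCoordinates <- function(vol, slice, smooth_window = 5L,
                                 socket_close_px = 7) {
  g <- voxelData(vol)
  sp <- spacing(vol)
  sx <- sp@sx
  gm <- g[, , slice]
  pcCls <- setdiff(classGroup("PC_CELL"), classGroup("PEG_PC"))
  pc <- matrix(gm %in% pcCls, nrow(gm), ncol(gm))
  ## EC-peg sockets indent the PC section: close over the socket openings
  ## and fill the enclosed holes, so the lumen-facing boundary runs across
  ## socket mouths instead of detouring into them
  if (any(pc)) pc <- .close2(pc, socket_close_px)
  pc <- .fillSmallHoles(pc, max_px = 2000L)
  lum <- matrix(gm == 4L, nrow(gm), ncol(gm))
  out <- list(sections = list(), skipped_annular = 0L, slice = slice)
  class(out) <- "EdgeCoordinateSystem"
  if (!any(pc) || !any(lum)) return(out)
  dLum <- .edt2px(lum)
  dBg <- .edt2px(matrix(gm == 0L, nrow(gm), ncol(gm)))
  lab <- .label(pc, conn = 8L)
  for (id in seq_len(attr(lab, "n"))) {
    sec <- lab == id
    dim(sec) <- dim(pc)
    if (sum(sec) < 8) next
    path <- .mooreTrace(sec)
    if (nrow(path) < 6) next
    ## a boundary pixel faces the lumen when it is nearer the lumen than
    ## the vessel exterior
    facing <- dLum[path] < dBg[path]
    if (all(facing) || !any(facing)) { ## degenerate classification
      out$skipped_annular <- out$skipped_annular + 1L
      next
    }
    ## longest cyclic run of lumen-facing pixels
    run <- .longestCyclicRun(facing)
    if (is.null(run)) { out$skipped_annular <- out$skipped_annular + 1L; next }
    arc <- path[run, , drop = FALSE]
    steps <- .arcStepsNm(arc, sx, window = smooth_window)
    cum <- c(0, cumsum(steps))
    L <- cum[length(cum)]
    pos <- pmin(cum, L - cum)
    out$sections[[length(out$sections) + 1L]] <-
      list(pixels = arc, position_nm = pos, arc_length_nm = L)
  }
  out
}

## indices of the longest run of TRUE in a cyclic logical vector, or NULL
## if the vector is all TRUE (no endpoints)
.longestCyclicRun <- function(x) {
  n <- length(x)
  if (all(x)) return(NULL)
  xx <- c(x, x)
  r <- rle(xx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths <= n & starts <= n)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  idx <- (starts[best]:ends[best] - 1L) %% n + 1L
  idx
}

#' Peg distances from the nearest PC edge, with the available-position
#' distribution
#'
#' Each PC-EC peg is mapped to its socket opening: the nearest lumen-facing
#' PC boundary pixel (in the slice of the peg's centroid) to the peg's
#' voxels, whose edge-coordinate position becomes the peg's observed edge
#' distance. The available-position distribution pools the positions of
#' every lumen-facing boundary pixel over all slices (arc-length weighting).
#' Both distributions share the same bins and are probability-normalized.
#'
#' @param vol A [LabelVolume-class].
#' @param pegs A [PegSet-class] (PC-EC pegs are used).
#' @param bin_um Histogram bin width in um (default 0.1).
#' @param smooth_window Passed to [buildEdgeCoordinates].
#' @return list of class `"EdgeDistanceDistribution"`: `observed_um`,
#'   `available_um`, `breaks_um`, `observed_prob`, `available_prob`,
#'   `observed_cum`, `available_cum`, `excluded_pegs`.
#' @export
pegEdgeDistances <- function(vol, pegs, bin_um = 0.1, smooth_window = 5L) {
  stopifnot(is(pegs, "PegSet"))
  tb <- pegTable(pegs)
  pcIdx <- which(tb$peg_type == "PC-EC")
  if (!length(pcIdx))
    stop("no PC-EC pegs present: edge-distance distribution undefined")
  d <- dim(voxelData(vol))
  ecs <- vector("list", d[3])
  getEcs <- function(k) {
    if (is.null(ecs[[k]])) ecs[[k]] <<-
        buildEdgeCoordinates(vol, k, smooth_window = smooth_window)
    ecs[[k]]
  }
  observed <- numeric(0)
  excluded <- integer(0)
  for (i in pcIdx) {
    v <- pegVoxels(pegs, i)
    zc <- round(mean(v[, 3]))
    zc <- max(1, min(d[3], zc))
    ec <- getEcs(zc)
    if (!length(ec$sections)) { excluded <- c(excluded, i); next }
    vz <- v[v[, 3] == zc, 1:2, drop = FALSE]
    if (!nrow(vz)) vz <- v[, 1:2, drop = FALSE]
    best <- Inf; bestPos <- NA_real_
    for (sec in ec$sections) {
      px <- sec$pixels
      for (q in seq_len(nrow(vz))) {
        dd <- sqrt((px[, 1] - vz[q, 1])^2 + (px[, 2] - vz[q, 2])^2)
        m <- which.min(dd)
        if (dd[m] < best) { best <- dd[m]; bestPos <- sec$position_nm[m] }
      }
    }
    if (!is.finite(best)) excluded <- c(excluded, i)
    else observed <- c(observed, bestPos / 1000)
  }
  available <- numeric(0)
  for (k in seq_len(d[3])) {
    ec <- getEcs(k)
    for (sec in ec$sections)
      available <- c(available, sec$position_nm / 1000)
  }
  if (!length(available))
    stop("no PC arcs with edges found in any slice")
  hi <- max(available, observed, 0) + bin_um
  breaks <- seq(0, ceiling(hi / bin_um) * bin_um, by = bin_um)
  ho <- graphics::hist(observed, breaks = breaks, plot = FALSE)
  ha <- graphics::hist(available, breaks = breaks, plot = FALSE)
  op <- if (length(observed)) ho$counts / sum(ho$counts)
        else rep(NA_real_, length(ho$counts))
  ap <- ha$counts / sum(ha$counts)
  out <- list(observed_um = observed, available_um = available,
              breaks_um = breaks, observed_prob = op, available_prob = ap,
              observed_cum = cumsum(op), available_cum = cumsum(ap),
              excluded_pegs = excluded)
  class(out) <- "EdgeDistanceDistribution"
  out
}

#' Proximity of PC pegs to the EC nucleus surface
#'
#' The anisotropic distance from the PC-peg mask is sampled on the EC
#' nucleus boundary voxels (value-per-surface-voxel export for external
#' rendering), and the number of distinct PC pegs in contact with the
#' nucleus surface (within `contact_tol_nm`) is counted.
#'
#' @param vol A [LabelVolume-class].
#' @param pegs Optional [PegSet-class]; if missing, PC-peg components are
#'   labeled from the volume.
#' @param contact_tol_nm Contact tolerance; default one in-plane pitch.
#' @return list: `surface_voxels`, `distance_nm` (Inf when no pegs exist),
#'   `contact_count`, `n_pegs`.
#' @export
pegNucleusProximity <- function(vol, pegs = NULL, contact_tol_nm = NULL) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  if (is.null(contact_tol_nm)) contact_tol_nm <- sp@sx
  nuc <- array(g == 5L, d)
  if (!any(nuc)) stop("no EC nucleus present")
  surf <- .touches6(nuc, array(g != 5L, d))
  vox <- .whichVox(surf)
  pegMask <- array(g %in% classGroup("PEG_PC"), d)
  if (!any(pegMask)) {
    return(list(surface_voxels = vox,
                distance_nm = rep(Inf, nrow(vox)),
                contact_count = 0L, n_pegs = 0L))
  }
  dist <- .edt(pegMask, sp)[surf]
  dNuc <- .edt(nuc, sp)
  if (is.null(pegs)) {
    lab <- .label(pegMask, conn = 26L)
    n <- attr(lab, "n")
    pvox <- .whichVox(pegMask)
    ids <- lab[pegMask]
    comps <- lapply(seq_len(n), function(id) pvox[ids == id, , drop = FALSE])
  } else {
    tb <- pegTable(pegs)
    comps <- lapply(which(tb$peg_type == "PC-EC"),
                    function(i) pegVoxels(pegs, i))
  }
  contact <- vapply(comps, function(v) min(dNuc[v]) <= contact_tol_nm + 1e-9,
                    logical(1))
  list(surface_voxels = vox, distance_nm = dist,
       contact_count = sum(contact), n_pegs = length(comps))
}
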