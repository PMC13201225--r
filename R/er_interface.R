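## PC-ER contact statistics over the three PC surface categories, and
## EC-PC interface skeleton intensity analysis with the electron-lucency
## threshold.

#' Categorize the PC plasma-membrane surface
#'
#' PC boundary voxels (6-adjacent to non-PC) fall into three categories:
#' `socket` when within `socket_px` in-plane pitches of an EC-peg
#' component; otherwise `lumen_facing` when nearer the lumen than the
#' exterior (the per-slice medial split of the PC section: the locus where
#' the lumen and background distance fields are equal is the section's
#' medial line); otherwise `abluminal`.
#'
#' @param vol A [LabelVolume-class].
#' @param socket_px Socket shell reach in in-plane pitches (default 2).
#' @return list of class `"PcSurfaceCategories"`: `voxels`, `category`
#'   (factor lumen_facing/abluminal/socket).
#' @export
categorizePcSurface <- function(vol, socket_px = 2) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  sx <- sp@sx
  pc <- array(g %in% classGroup("PC_CELL"), d)
  if (!any(pc)) stop("no PC voxels present")
  surf <- .touches6(pc, !pc)
  vox <- .whichVox(surf)

  pegEC <- array(g %in% c(classGroup("PEG_EC"), classGroup("PEG_ECEC")), d)
  dPeg <- if (any(pegEC)) .edt(pegEC, sp)[surf] else rep(Inf, nrow(vox))

  ## per-slice lumen vs background distance comparison
  lumNear <- rep(FALSE, nrow(vox))
  for (k in unique(vox[, 3])) {
    gm <- g[, , k]
    lum <- matrix(gm == 4L, d[1], d[2])
    bgm <- matrix(gm == 0L, d[1], d[2])
    dl <- .edt2px(lum)
    db <- .edt2px(bgm)
    sel <- vox[, 3] == k
    ij <- vox[sel, 1:2, drop = FALSE]
    lumNear[sel] <- dl[ij] < db[ij]
  }
  category <- factor(ifelse(dPeg <= socket_px * sx + 1e-9, "socket",
                     ifelse(lumNear, "lumen_facing", "abluminal")),
                     levels = c("lumen_facing", "abluminal", "socket"))
  out <- list(voxels = vox, category = category)
  class(out) <- "PcSurfaceCategories"
  out
}

#' PC-ER proximity and contact statistics per surface category
#'
#' The anisotropic distance from the PC ER mask (including peg-internal PC
#' ER) is sampled at every categorized PC surface voxel; direct contact is
#' a distance of at most `contact_tol_nm` (default one in-plane pitch).
#' Per-vessel values are means over all voxels of a category.
#'
#' @param vol A [LabelVolume-class].
#' @param cats A `PcSurfaceCategories` from [categorizePcSurface].
#' @param contact_tol_nm Contact tolerance in nm.
#' @return data.frame (category, n_voxels, mean_distance_nm,
#'   contact_percent).
#' @export
erContactStats <- function(vol, cats, contact_tol_nm = NULL) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  if (is.null(contact_tol_nm)) contact_tol_nm <- sp@sx
  er <- array(g %in% classGroup("PC_ER"), d)
  if (!any(er)) stop("PC ER class is empty: contact statistics undefined")
  dd <- .edt(er, sp)
  v <- dd[cats$voxels]
  data.frame(
    category = levels(cats$category),
    n_voxels = as.integer(table(cats$category)),
    mean_distance_nm = as.numeric(tapply(v, cats$category, mean)),
    contact_percent = as.numeric(tapply(v <= contact_tol_nm + 1e-9,
                                        cats$category,
                                        function(x) 100 * mean(x))))
}

#' Skeletonize the EC-PC interface of one slice
#'
#' The interface mask (BM or BM-ELP voxels within `halfwidth_px` in-plane
#' pitches of both cells) is thinned to a 1-pixel centerline (Zhang-Suen),
#' dangling branches shorter than `prune_px` pixels are pruned, and the
#' centerline is ordered by tracing with arc length accumulated from
#' physical step lengths. The EC-EC junction class is not part of the
#' interface.
#'
#' @param vol A [LabelVolume-class].
#' @param slice Slice index.
#' @param halfwidth_px Cell-proximity reach defining the interface mask.
#' @param prune_px Minimum kept branch length in pixels.
#' @param smooth_window Polyline smoothing window for arc length.
#' @return data.frame (slice, chain, idx, x, y, arc_nm); zero rows when the
#'   slice has no interface. A `closed` attribute flags ring-shaped chains.
#' @export
skeletonizeInterface <- function(vol, slice, halfwidth_px = 8,
                                 prune_px = 5, smooth_window = 5L) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  sx <- sp@sx
  gm <- g[, , slice]
  bm <- matrix(gm %in% c(1L, 17L), d[1], d[2])
  emptyRes <- data.frame(slice = integer(0), chain = integer(0),
                         idx = integer(0), x = integer(0), y = integer(0),
                         arc_nm = numeric(0))
  if (!any(bm)) return(emptyRes)
  ec <- matrix(gm %in% classGroup("EC_CELL"), d[1], d[2])
  pc <- matrix(gm %in% classGroup("PC_CELL"), d[1], d[2])
  if (!any(ec) || !any(pc)) return(emptyRes)
  iface <- bm & .edt2px(ec) <= halfwidth_px & .edt2px(pc) <= halfwidth_px
  if (!any(iface)) return(emptyRes)
  sk <- .cpp_thin(iface)
  sk <- .pruneSkeleton(sk, min_len = prune_px)
  if (!any(sk)) return(emptyRes)
  chains <- .orderChains(sk)
  rows <- NULL
  closed <- logical(0)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    steps <- .arcStepsNm(ch, sx, window = smooth_window)
    arc <- c(0, cumsum(steps))
    isClosed <- nrow(ch) > 3 &&
      max(abs(ch[1, ] - ch[nrow(ch), ])) <= 1L
    closed <- c(closed, isClosed)
    rows <- rbind(rows, data.frame(
      slice = slice, chain = ci, idx = seq_len(nrow(ch)),
      x = ch[, 1], y = ch[, 2], arc_nm = arc))
  }
  attr(rows, "closed") <- closed
  rows
}

#' Skeletonize the EC-PC interface of every slice
#'
#' @param vol A [LabelVolume-class].
#' @param ... Passed to [skeletonizeInterface].
#' @return data.frame of all slices' centerlines.
#' @export
interfaceSkeleton <- function(vol, ...) {
  d <- dim(voxelData(vol))
  out <- NULL
  for (k in seq_len(d[3])) {
    r <- skeletonizeInterface(vol, k, ...)
    if (nrow(r)) out <- rbind(out, r)
  }
  if (is.null(out))
    stop("no EC-PC interface found in any slice")
  out
}

#' Attach image intensity and peg domains to an interface skeleton
#'
#' Each centerline voxel receives the 8-bit intensity of the co-registered
#' image and an interface domain: `EC_peg` when within `shell_px` in-plane
#' pitches of an EC-peg component, `PC_peg` likewise, else `non_peg`.
#'
#' @param skel data.frame from [interfaceSkeleton] / [skeletonizeInterface].
#' @param img An [IntensityVolume-class].
#' @param vol The matching [LabelVolume-class].
#' @param shell_px Peg-shell reach in in-plane pitches (default 2).
#' @return The skeleton data.frame with `intensity` and `domain` columns.
#' @export
interfaceIntensity <- function(skel, img, vol, shell_px = 2) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  sx <- sp@sx
  if (!identical(dim(voxelData(img)), d))
    stop("label and intensity volumes have different shapes")
  idx <- cbind(skel$x, skel$y, skel$slice)
  skel$intensity <- voxelData(img)[idx]
  pegEC <- array(g %in% c(classGroup("PEG_EC"), classGroup("PEG_ECEC")), d)
  pegPC <- array(g %in% classGroup("PEG_PC"), d)
  dEC <- if (any(pegEC)) .edt(pegEC, sp)[idx] else rep(Inf, nrow(skel))
  dPC <- if (any(pegPC)) .edt(pegPC, sp)[idx] else rep(Inf, nrow(skel))
  skel$domain <- factor(ifelse(dEC <= shell_px * sx + 1e-9, "EC_peg",
                        ifelse(dPC <= shell_px * sx + 1e-9, "PC_peg",
                               "non_peg")),
                        levels = c("EC_peg", "PC_peg", "non_peg"))
  skel
}

#' Fraction of interface centerline voxels exceeding the lucency threshold
#'
#' Per interface domain, 100 x (number of centerline voxels with intensity
#' strictly greater than `threshold`) / (domain voxel count). A voxel at
#' exactly the threshold does not count. Domains absent from the skeleton
#' are reported as `NA`, not 0.
#'
#' @param skel Skeleton data.frame with intensities ([interfaceIntensity]).
#' @param threshold Lucency threshold (default 180).
#' @return data.frame (domain, n_voxels, n_bright, percent).
#' @export
elpFractionByDomain <- function(skel, threshold = 180) {
  if (is.null(skel$intensity))
    stop("skeleton has no intensities: run interfaceIntensity() first")
  doms <- levels(skel$domain)
  n <- as.integer(table(skel$domain))
  bright <- vapply(doms, function(dm)
    sum(skel$intensity[skel$domain == dm] > threshold), integer(1))
  data.frame(domain = doms, n_voxels = n, n_bright = bright,
             percent = ifelse(n > 0, 100 * bright / n, NA_real_))
}
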