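## Post-processing of raw semantic predictions into the final 26-class label
## volume: exterior removal, cytosol filling, lumen-contact cell typing with
## a 3D continuity pass, and junction / peg-and-socket relabeling.

#' Remove everything outside the vessel's outer BM boundary
#'
#' Per slice, all non-BM voxels 4-connected to the image border (the
#' parenchyma, including falsely predicted lumen or organelles there) are set
#' to background. Slices whose BM ring is not closed are first repaired by
#' morphological ring closing with a structuring radius up to
#' `repair_radius`; slices that remain open are left untouched and reported
#' in the `"flagged_slices"` attribute of the result, never guessed.
#'
#' @param sem A [SemanticVolume-class].
#' @param repair_radius Maximum closing radius (pixels) for BM ring repair.
#' @return A [SemanticVolume-class] with exterior cleared and the `interior`
#'   slot populated; attribute `flagged_slices` lists unrepairable slices.
#' @export
removeExterior <- function(sem, repair_radius = 3) {
  stopifnot(is(sem, "SemanticVolume"))
  g <- voxelData(sem)
  d <- dim(g)
  interior <- array(FALSE, d)
  flagged <- integer(0)
  for (k in seq_len(d[3])) {
    sl <- g[, , k]
    bm <- sl == 1L
    inn <- .interiorOfRing(bm)
    if (is.null(inn)) {
      repaired <- FALSE
      for (r in seq_len(repair_radius)) {
        bm2 <- .close2(bm, r)
        inn <- .interiorOfRing(bm2)
        if (!is.null(inn)) {
          sl[bm2 & !bm] <- 1L
          bm <- bm2
          repaired <- TRUE
          break
        }
      }
      if (!repaired) {
        flagged <- c(flagged, k)
        interior[, , k] <- TRUE   # leave slice untouched, conservatively
        next
      }
    }
    sl[!inn & !bm] <- 0L
    interior[, , k] <- inn | bm
    g[, , k] <- sl
  }
  out <- SemanticVolume(g, spacing = spacing(sem), interior = interior)
  attr(out, "flagged_slices") <- flagged
  out
}

## non-BM pixels enclosed by the BM ring, or NULL if the ring is open
## (every non-BM pixel reachable from the border)
.interiorOfRing <- function(bm) {
  nonbm <- !bm
  lab <- .label(nonbm, conn = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  inn <- nonbm & !(lab %in% border)
  dim(inn) <- dim(bm)
  if (!any(inn)) NULL else inn
}

#' Cytosol mask of a post-processed semantic volume
#'
#' Interior voxels not assigned to BM, lumen or organelles -- i.e. the
#' filled cytosol of both cells.
#'
#' @param sem A [SemanticVolume-class] with interior marked.
#' @return Logical array.
#' @export
cytosolMask <- function(sem) {
  if (is.null(sem@interior))
    stop("run removeExterior() first: interior is not marked")
  sem@interior & voxelData(sem) == 0L
}

#' Fill intra-vessel holes as cytosol
#'
#' Every interior voxel that carries no BM / lumen / organelle prediction
#' becomes cytosol. With the 7-class schema cytosol shares code 0 with
#' background, so the fill is realised by the interior mask: after this step
#' [cytosolMask] is the definitive filled cytosol and downstream stages use
#' it. Idempotent.
#'
#' @param sem A [SemanticVolume-class] after [removeExterior].
#' @return The [SemanticVolume-class], with interior verified.
#' @export
fillCytosol <- function(sem) {
  if (is.null(sem@interior))
    stop("run removeExterior() first: interior is not marked")
  sem
}

#' Assign cell types by lumen contact with a 3D continuity pass
#'
#' Per 2D slice, each 8-connected cytosol region touching the lumen becomes
#' EC, every other region PC. A 3D continuity pass then relabels each
#' 26-connected cytosol component by its across-slice majority, which
#' recovers EC pegs that are detached from the lumen in individual slices.
#' Organelles inherit the cell class of the cytosol they are embedded in.
#'
#' @param sem A [SemanticVolume-class] after [removeExterior] /
#'   [fillCytosol].
#' @return A [LabelVolume-class] with classes 0--16 populated (junction and
#'   peg classes are produced by [relabelJunctionsAndPegs]). Attribute
#'   `unresolved_regions` counts organelle components whose host could not
#'   be determined by adjacency (they fall back to nearest-cell distance).
#' @export
assignCellTypes <- function(sem) {
  g <- voxelData(sem)
  d <- dim(g)
  sp <- spacing(sem)
  cyt <- cytosolMask(sem)

  ## per-slice initial EC/PC call
  ecInit <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    ck <- cyt[, , k]
    if (!any(ck)) next
    lab <- .label(ck, conn = 8L)
    lumAdj <- .hasNeighbor2(g[, , k] == 2L, conn = 8L, pad = FALSE)
    ids <- lab[ck & lumAdj]
    if (length(ids)) {
      ecIds <- unique(ids[ids != 0L])
      ecInit[, , k] <- ck & matrix(lab %in% ecIds, d[1], d[2])
    }
  }

  ## 3D continuity: majority vote within each 26-connected component
  lab3 <- .label(cyt, conn = 26L)
  idx <- which(cyt)
  comp <- lab3[idx]
  ecv <- ecInit[idx]
  ecFrac <- tapply(ecv, comp, mean)
  ecComp <- as.integer(names(ecFrac))[ecFrac > 0.5]
  isEC <- array(FALSE, d)
  isEC[idx] <- comp %in% ecComp

  out <- array(0L, d)
  out[g == 1L] <- 1L
  out[g == 2L] <- 4L
  out[cyt] <- ifelse(isEC[cyt], 2L, 3L)

  ## organelles inherit their host cell
  orgMap <- list("3" = c(5L, 6L), "4" = c(7L, 8L), "5" = c(11L, 12L),
                 "6" = c(13L, 14L))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  unresolved <- 0L
  pending <- list()
  for (cls in names(orgMap)) {
    m <- g == as.integer(cls)
    if (!any(m)) next
    lab <- .label(m, conn = 26L)
    vox <- .whichVox(m)
    ids <- lab[m]
    for (id in seq_len(attr(lab, "n"))) {
      v <- vox[ids == id, , drop = FALSE]
      cl <- .neighborClasses(out, v, offs, d)
      nec <- sum(cl == 2L); npc <- sum(cl == 3L)
      if (nec + npc == 0L) {
        pending[[length(pending) + 1L]] <- list(cls = cls, v = v)
        next
      }
      out[v] <- orgMap[[cls]][if (nec >= npc) 1L else 2L]
    }
  }
  ## second pass: contact with already-assigned organelles, then distance
  if (length(pending)) {
    ecAll <- array(out %in% classGroup("EC_CELL"), d)
    pcAll <- array(out %in% classGroup("PC_CELL"), d)
    dEC <- if (any(ecAll)) .edt(ecAll, sp) else array(Inf, d)
    dPC <- if (any(pcAll)) .edt(pcAll, sp) else array(Inf, d)
    for (pd in pending) {
      v <- pd$v
      cl <- .neighborClasses(out, v, offs, d)
      nec <- sum(cl %in% classGroup("EC_CELL"))
      npc <- sum(cl %in% classGroup("PC_CELL"))
      if (nec + npc == 0L) {
        unresolved <- unresolved + 1L
        nec <- sum(1 / (1 + dEC[v])); npc <- sum(1 / (1 + dPC[v]))
      }
      out[v] <- orgMap[[pd$cls]][if (nec >= npc) 1L else 2L]
    }
  }

  res <- LabelVolume(out, spacing = sp)
  attr(res, "unresolved_regions") <- unresolved
  res
}

## classes of the 26-neighbourhood of a voxel set (excluding the set itself)
.neighborClasses <- function(arr, vox, offs, d) {
  res <- integer(0)
  inSet <- array(FALSE, d)
  inSet[vox] <- TRUE
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) next
    keep <- !inSet[nb]
    res <- c(res, arr[nb[keep, , drop = FALSE]])
  }
  res
}

#' Relabel EC-EC junctions and peg-and-socket components
#'
#' Two conversions on a cell-typed label volume. (1) BM voxels lying between
#' EC cytosol on both sides (bridged by a per-slice morphological closing of
#' the EC mask) become the EC-EC junction class 18; this covers junctions of
#' an EC both with neighbours and with itself. (2) Cytosol protrusions that
#' cross the interface into the other cell's socket become peg classes:
#' protrusions are the residue of a per-slice morphological opening of each
#' cell's cytosol mask, and a 26-connected residue component is a peg when it
#' is mostly detached from its own cell's remaining cytosol (own-adjacency
#' fraction at most `own_frac_max`) and lies within `reach_px` in-plane
#' pitches of the other cell (or, for EC components adjacent to class 18, of
#' EC again across the junction -> EC-EC peg). ER and mitochondria embedded
#' in a peg move to the peg-organelle classes 21--24 and count towards the
#' peg's volume.
#'
#' @param vol A [LabelVolume-class] from [assignCellTypes] (or already
#'   relabeled; the operation is idempotent).
#' @param r_close Closing radius (px) for junction bridging. Deliberately
#'   conservative: narrow seams convert, wide junction wedges (e.g. around
#'   EC-EC peg sockets) may partially remain BM, which downstream
#'   measurements tolerate.
#' @param r_open Opening radius (px) for protrusion extraction; slightly
#'   larger than the expected peg radius.
#' @param reach_px Socket reach towards the recipient cell, in-plane pitches.
#' @param own_frac_max Maximum fraction of component voxels allowed to touch
#'   their own cell's non-peg cytosol.
#' @param min_voxels Minimum component size considered.
#' @param min_junction_voxels Minimum 3D size of a junction-candidate
#'   component.
#' @return list with `vol` (relabeled [LabelVolume-class]) and `pegs`
#'   (a [PegSet-class] with one record per peg, including metrics).
#' @export
relabelJunctionsAndPegs <- function(vol, r_close = 3, r_open = 6,
                                    reach_px = 2.5, own_frac_max = 0.25,
                                    min_voxels = 40,
                                    min_junction_voxels = 50) {
  stopifnot(is(vol, "LabelVolume"))
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  sx <- sp@sx

  ## ---- (1) EC-EC junction ---------------------------------------------------
  cand <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    ec <- g[, , k] == 2L
    if (!any(ec)) next
    cand[, , k] <- .close2(ec, r_close) & g[, , k] == 1L
  }
  if (any(cand)) {
    lab <- .label(cand, conn = 26L)
    sizes <- tabulate(lab[cand], nbins = attr(lab, "n"))
    keep <- which(sizes >= min_junction_voxels)
    g[cand & array(lab %in% keep, d)] <- 18L
  }

  ## ---- (2) peg detection ----------------------------------------------------
  ## Protrusions are cytosol voxels lying deeper than `deep_px` in-plane
  ## pitches from the cell's morphological core (per-slice opening). The
  ## depth requirement detaches embedded peg shafts from the thin opening
  ## shavings that line curved boundaries and the junction slit. Components
  ## must additionally contain a disk of inscribed radius >= `fat_px`
  ## pitches in some slice (pegs are solid cylinders, shavings are skins).
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  deep_px <- r_open * 5 / 12   # 2.5 px at the default opening radius 6
  fat_px <- 2.5
  ambiguous <- 0L
  ## cell "mass" masks: cytosol plus intracellular organelles (organelles
  ## are interior to the cell and must not cut the mask for the opening)
  ecMass <- c(2L, classGroup("EC_ORG"))
  pcMass <- c(3L, classGroup("PC_ORG"))
  for (cell in c("EC", "PC")) {
    ownCls <- if (cell == "EC") 2L else 3L
    ownMass <- if (cell == "EC") ecMass else pcMass
    otherMass <- if (cell == "EC") pcMass else ecMass
    massA <- array(g %in% ownMass, d)
    if (!any(massA)) next
    core <- array(FALSE, d)
    for (k in seq_len(d[3]))
      core[, , k] <- .open2(massA[, , k], r_open)
    if (!any(core)) next
    dCore <- .edt(core, sp)
    prot <- massA & !core & dCore > deep_px * sx
    if (!any(prot)) next
    ## erosion-split: candidate components must survive a per-slice
    ## erosion (peg shafts are solid; thin residue ribbons along the
    ## junction slit or socket margins are not), then labels grow back
    ## over the unsplit residue so each shaft keeps its full voxel set
    eroded <- array(FALSE, d)
    for (k in seq_len(d[3]))
      eroded[, , k] <- .erode2(prot[, , k], 1.5)
    if (!any(eroded)) next
    labE <- .label(eroded, conn = 26L)
    labFull <- array(0L, d)
    labFull[eroded] <- labE[eroded]
    for (it in 1:3) {
      grow <- prot & labFull == 0L
      if (!any(grow)) break
      for (r in seq_len(nrow(offs))) {
        sh <- .shift3Int(labFull, offs[r, ])
        fill <- grow & labFull == 0L & sh > 0L
        labFull[fill] <- sh[fill]
      }
    }
    n <- attr(labE, "n")
    if (!n) next
    keepMask <- labFull > 0L
    vox <- .whichVox(keepMask)
    ids <- labFull[keepMask]
    otherArr <- array(g %in% otherMass, d)
    dOther <- if (any(otherArr)) .edt(otherArr, sp) else array(Inf, d)
    massCheck <- array(g %in% ownMass, d)
    for (id in seq_len(n)) {
      v <- vox[ids == id, , drop = FALSE]
      if (nrow(v) < min_voxels) next
      if (.inscribedPx(v) < fat_px) next
      inComp <- array(FALSE, d)
      inComp[v] <- TRUE
      cl <- .neighborClasses(g, v, offs, d)
      touches18 <- any(cl == 18L)
      ## fraction of component voxels with a neighbour in the own cell's
      ## remaining mass
      ownFrac <- .voxelsTouchingMask(massCheck, v, offs, d, inComp) /
        nrow(v)
      if (ownFrac > own_frac_max) next
      reach <- min(dOther[v]) <= reach_px * sx + 1e-9
      newCls <- if (reach) {
        if (cell == "EC") 19L else 20L
      } else if (cell == "EC" && touches18) 25L else NA_integer_
      if (is.na(newCls)) next
      ## relabel the cytosol voxels of the component; embedded organelles
      ## are converted by the peg-organelle step below
      cyt <- v[g[v] == ownCls, , drop = FALSE]
      if (nrow(cyt)) g[cyt] <- newCls
    }
  }

  ## ---- (3) organelles inside pegs -------------------------------------------
  orgToPeg <- list(c(7L, 21L), c(8L, 22L), c(11L, 23L), c(12L, 24L))
  pegCyt <- array(g %in% c(19L, 20L, 25L), d)
  if (any(pegCyt)) {
    for (op in orgToPeg) {
      m <- g == op[1]
      if (!any(m)) next
      lab <- .label(m, conn = 26L)
      vox <- .whichVox(m)
      ids <- lab[m]
      for (id in seq_len(attr(lab, "n"))) {
        v <- vox[ids == id, , drop = FALSE]
        inComp <- array(FALSE, d)
        inComp[v] <- TRUE
        cl <- .neighborClasses(g, v, offs, d)
        nPeg <- sum(cl %in% c(19L, 20L, 25L))
        nCyt <- sum(cl %in% c(2L, 3L))
        if (nPeg > 0 && nPeg >= nCyt) g[v] <- op[2]
      }
    }
  }

  out <- LabelVolume(g, spacing = sp, origin = origin(vol))
  pegs <- .buildPegSet(out)
  attr(out, "ambiguous_pegs") <- ambiguous
  list(vol = out, pegs = pegs)
}

## shift a 3D integer array by an offset vector, padding with zero
.shift3Int <- function(a, dv) {
  d <- dim(a)
  out <- array(0L, d)
  sx <- max(1, 1 - dv[1]):min(d[1], d[1] - dv[1])
  sy <- max(1, 1 - dv[2]):min(d[2], d[2] - dv[2])
  sz <- max(1, 1 - dv[3]):min(d[3], d[3] - dv[3])
  out[sx + dv[1], sy + dv[2], sz + dv[3]] <- a[sx, sy, sz]
  out
}

## largest in-plane inscribed radius (pixels) over the slices of a
## voxel-set footprint
.inscribedPx <- function(v) {
  best <- 0
  for (z in unique(v[, 3])) {
    xy <- v[v[, 3] == z, 1:2, drop = FALSE]
    xr <- range(xy[, 1]); yr <- range(xy[, 2])
    m <- matrix(FALSE, xr[2] - xr[1] + 3, yr[2] - yr[1] + 3)
    m[cbind(xy[, 1] - xr[1] + 2, xy[, 2] - yr[1] + 2)] <- TRUE
    dd <- .edt2px(!m)
    best <- max(best, max(dd[m]))
  }
  best
}

## number of component voxels having >= 1 neighbour inside `mask` but
## outside the component
.voxelsTouchingMask <- function(mask, v, offs, d, inComp) {
  touch <- rep(FALSE, nrow(v))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(v, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    val <- rep(FALSE, nrow(v))
    val[ok] <- mask[nb[ok, , drop = FALSE]] & !inComp[nb[ok, , drop = FALSE]]
    touch <- touch | val
  }
  sum(touch)
}

## assemble a PegSet from the peg classes of a relabeled volume
.buildPegSet <- function(vol) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  groups <- list("EC-PC" = c(19L, 21L, 23L),
                 "PC-EC" = c(20L, 22L, 24L),
                 "EC-EC" = 25L)
  tab <- NULL
  voxList <- list()
  for (ty in names(groups)) {
    m <- array(g %in% groups[[ty]], d)
    if (!any(m)) next
    lab <- .label(m, conn = 26L)
    vox <- .whichVox(m)
    ids <- lab[m]
    for (id in seq_len(attr(lab, "n"))) {
      v <- vox[ids == id, , drop = FALSE]
      met <- pegMetrics(v, sp)
      row <- data.frame(peg_type = ty,
                        donor = if (ty == "PC-EC") "PC" else "EC",
                        recipient = if (ty == "EC-PC") "PC" else "EC",
                        met, stringsAsFactors = FALSE)
      tab <- rbind(tab, row)
      voxList[[length(voxList) + 1L]] <- v
    }
  }
  if (is.null(tab)) {
    tab <- data.frame(peg_type = character(0), donor = character(0),
                      recipient = character(0), n_voxels = integer(0),
                      volume_nm3 = numeric(0), z_length_nm = numeric(0),
                      max_xy_diameter_nm = numeric(0),
                      aspect_ratio = numeric(0),
                      axial_position_um = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0))
  }
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  new("PegSet", table = tab, voxels = voxList, spacing = sp)
}

#' Morphometrics of one peg component
#'
#' Volume = voxel count x voxel volume (peg-internal organelle classes are
#' part of the component); z length = slice span x sz; max x-y diameter =
#' the largest per-slice Feret (maximum pairwise centre distance) plus one
#' in-plane pitch, so a single-voxel footprint has diameter one pitch rather
#' than zero; aspect ratio = z length / max x-y diameter; axial position =
#' centroid z in um.
#'
#' @param vox Integer matrix of voxel coordinates (columns x, y, z).
#' @param spacing A [VoxelSpacing-class].
#' @return One-row data.frame of metrics.
#' @export
pegMetrics <- function(vox, spacing = voxelSpacing()) {
  stopifnot(nrow(vox) > 0)
  sx <- spacing@sx; sz <- spacing@sz
  zr <- range(vox[, 3])
  zlen <- (zr[2] - zr[1] + 1) * sz
  fer <- 0
  for (z in unique(vox[, 3])) {
    xy <- vox[vox[, 3] == z, 1:2, drop = FALSE]
    fer <- max(fer, .feretPx(xy))
  }
  dia <- fer * sx + sx
  data.frame(n_voxels = nrow(vox),
             volume_nm3 = nrow(vox) * sx * sx * sz,
             z_length_nm = zlen,
             max_xy_diameter_nm = dia,
             aspect_ratio = zlen / dia,
             axial_position_um = mean(vox[, 3]) * sz / 1000,
             cx = mean(vox[, 1]), cy = mean(vox[, 2]),
             cz = mean(vox[, 3]))
}

#' Run the full post-processing chain
#'
#' [removeExterior] -> [fillCytosol] -> [assignCellTypes] ->
#' [relabelJunctionsAndPegs].
#'
#' @param sem A [SemanticVolume-class].
#' @param ... Passed to [relabelJunctionsAndPegs].
#' @return list with `vol` (final [LabelVolume-class]), `pegs`
#'   ([PegSet-class]) and `flagged_slices`.
#' @export
postprocessChain <- function(sem, ...) {
  sem <- removeExterior(sem)
  flagged <- attr(sem, "flagged_slices")
  sem <- fillCytosol(sem)
  vol <- assignCellTypes(sem)
  res <- relabelJunctionsAndPegs(vol, ...)
  list(vol = res$vol, pegs = res$pegs, flagged_slices = flagged)
}
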