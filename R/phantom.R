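## Synthetic vessel phantom generator.
##
## The phantom is a z-oriented tube: lumen core, EC annulus, an EC-PC
## interface BM layer, a PC arc of prescribed angular coverage with a soma
## bulge, and an outer BM shell with a prescribed thickness field (thinner
## over the soma). Pegs are z-elongated cylinders embedded in the recipient
## cell behind a one-voxel BM (or junction-class) sheath and connected to the
## donor through a one-slice neck carved across the interface. ELPs, nuclei,
## mitochondria and a PC ER tubule network continuous with the nuclear
## envelope are carved on top, and a co-registered 8-bit grayscale rendering
## is produced in which BM is dark and ELPs are bright (> 180/255).

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.angDist <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)

#' Specify one planted peg-and-socket junction
#'
#' @param type One of `"PC-EC"` (PC peg in EC socket), `"EC-PC"`, `"EC-EC"`.
#' @param z Central slice index, or `NA` to draw at generation time.
#' @param theta Angular position (radians), or `NA` to draw a feasible one.
#' @param radius_nm Cylinder radius in nm (in-plane).
#' @param z_extent Number of slices spanned.
#' @return A one-row data.frame.
#' @export
pegSpec <- function(type = c("PC-EC", "EC-PC", "EC-EC"), z = NA,
                    theta = NA, radius_nm = 40, z_extent = 9) {
  type <- match.arg(type)
  data.frame(type = type, z = z, theta = theta, radius_nm = radius_nm,
             z_extent = as.integer(z_extent), stringsAsFactors = FALSE)
}

#' Specify one planted electron-lucent pocket
#'
#' @param location `"bm"` (within the outer basement membrane) or
#'   `"interface"` (at the EC-PC interface).
#' @param theta Angular position (radians).
#' @param z Central slice.
#' @param r_nm In-plane blob radius (ignored for bands).
#' @param rz_slices Half z-extent in slices (ignored for bands).
#' @param band If `TRUE`, an angular band spanning all slices of the
#'   interface (interface location only), used to plant a known centerline
#'   fraction.
#' @param theta_halfwidth Angular half-width of a band (radians).
#' @return A one-row data.frame.
#' @export
elpSpec <- function(location = c("bm", "interface"), theta = 0, z = NA,
                    r_nm = 60, rz_slices = 2, band = FALSE,
                    theta_halfwidth = 0.1) {
  location <- match.arg(location)
  data.frame(location = location, theta = theta, z = z, r_nm = r_nm,
             rz_slices = as.integer(rz_slices), band = band,
             theta_halfwidth = theta_halfwidth, stringsAsFactors = FALSE)
}

#' Parameters of a synthetic vessel phantom
#'
#' Defaults describe a "V1-like" desk-scale capillary: 64% pericyte coverage,
#' a soma with thinned overlying BM (50 nm vs 100 nm elsewhere), three peg
#' types, interface and BM ELPs, and a PC ER network. Geometry is in nm;
#' slices are voxel indices along z.
#'
#' @param shape Integer vector `(nx, ny, nz)` of grid dimensions.
#' @param spacing A [VoxelSpacing-class].
#' @param lumen_radius Lumen radius, nm.
#' @param ec_thickness EC annulus thickness, nm.
#' @param interface_thickness EC-PC interface BM thickness, nm.
#' @param pc_thickness PC process thickness, nm.
#' @param bm_thickness_base Outer BM thickness away from the soma, nm.
#' @param bm_thickness_soma Outer BM thickness over the soma, nm.
#' @param pc_coverage Target PC coverage as an angular arc fraction, 0--1.
#' @param pc_arc_center Angular centre of the PC arc, radians.
#' @param soma `NULL` or list(`theta_halfwidth`, `z_range` (slices),
#'   `extra_thickness` nm); the soma is centred on `pc_arc_center`.
#' @param junction `NULL` (seamless) or list(`theta`, `amplitude` of the
#'   "S" wiggle in radians, `halfwidth_px`).
#' @param peg_specs data.frame of [pegSpec] rows.
#' @param elp_specs data.frame of [elpSpec] rows.
#' @param er list(`n_tubules`, `socket_bias`): number of baseline ER
#'   tubules and the socket-contact bias factor (1 = unbiased; b > 1 plants
#'   a socket-hugging tubule per EC peg with probability 1 - 1/b).
#' @param nuclei list(`ec = list(theta, z, semi_nm)`,
#'   `pc = list(z, semi_nm, lobe_offset_slices)`); `NULL` entries omit that
#'   nucleus. The PC nucleus is centred in the soma; `lobe_offset_slices > 0`
#'   makes a two-lobed nucleus from two overlapping ellipsoids offset in z.
#' @param n_mito Integer length-2: mitochondria planted in (EC, PC).
#' @param intensity list(`sd`, `elp_range`, `nonelp_max`): grayscale model.
#' @param seed RNG seed; identical seed and parameters give bytewise
#'   identical volumes.
#' @return A list of class `"PhantomParams"`.
#' @export
phantomParams <- function(shape = c(276L, 276L, 40L),
                          spacing = voxelSpacing(),
                          lumen_radius = 440,
                          ec_thickness = 120,
                          interface_thickness = 32,
                          pc_thickness = 120,
                          bm_thickness_base = 100,
                          bm_thickness_soma = 50,
                          pc_coverage = 0.64,
                          pc_arc_center = pi,
                          soma = list(theta_halfwidth = 0.55,
                                      z_range = c(8L, 32L),
                                      extra_thickness = 160),
                          junction = list(theta = 0, amplitude = 0.12,
                                          halfwidth_px = 1),
                          peg_specs = rbind(
                            pegSpec("PC-EC"), pegSpec("PC-EC"),
                            pegSpec("PC-EC"), pegSpec("EC-PC"),
                            pegSpec("EC-EC")),
                          elp_specs = rbind(
                            elpSpec("bm", theta = pi + 1.4, z = 10),
                            elpSpec("bm", theta = pi - 1.6, z = 30),
                            elpSpec("interface", theta = pi + 0.8, z = 20,
                                    r_nm = 70, rz_slices = 2)),
                          er = list(n_tubules = 6, socket_bias = 1),
                          nuclei = list(
                            ec = list(theta = pi / 2, z = 20,
                                      semi_nm = c(40, 300, 400)),
                            pc = list(z = NA, semi_nm = c(90, 90, 400),
                                      lobe_offset_slices = 0L)),
                          n_mito = c(2L, 2L),
                          intensity = list(sd = 10, elp_range = c(200, 240),
                                           nonelp_max = 178),
                          seed = 1L) {
  p <- list(shape = as.integer(shape), spacing = spacing,
            lumen_radius = lumen_radius, ec_thickness = ec_thickness,
            interface_thickness = interface_thickness,
            pc_thickness = pc_thickness,
            bm_thickness_base = bm_thickness_base,
            bm_thickness_soma = bm_thickness_soma,
            pc_coverage = pc_coverage, pc_arc_center = pc_arc_center,
            soma = soma, junction = junction, peg_specs = peg_specs,
            elp_specs = elp_specs, er = er, nuclei = nuclei,
            n_mito = as.integer(n_mito), intensity = intensity,
            seed = as.integer(seed))
  class(p) <- "PhantomParams"
  .validatePhantomParams(p)
  p
}

.validatePhantomParams <- function(p) {
  if (p$pc_coverage < 0 || p$pc_coverage > 1)
    stop("pc_coverage must lie in [0, 1]")
  pos <- c(lumen = p$lumen_radius, ec = p$ec_thickness,
           iface = p$interface_thickness, pc = p$pc_thickness,
           bm_base = p$bm_thickness_base, bm_soma = p$bm_thickness_soma)
  if (any(pos <= 0)) stop("all radii and thicknesses must be positive")
  sx <- p$spacing@sx
  rmax <- p$lumen_radius + p$ec_thickness + p$interface_thickness +
    p$pc_thickness + p$bm_thickness_base +
    (if (!is.null(p$soma)) p$soma$extra_thickness else 0)
  half <- (min(p$shape[1:2]) / 2 - 2) * sx
  if (rmax > half)
    stop("phantom geometry does not fit the grid: outer radius ", rmax,
         " nm exceeds available half-extent ", half, " nm")
  if (!is.null(p$soma)) {
    if (p$pc_coverage < 1 &&
        p$soma$theta_halfwidth > p$pc_coverage * pi)
      stop("soma angular extent exceeds the PC arc")
    if (p$pc_coverage == 0) stop("soma requires pc_coverage > 0")
  }
  ps <- p$peg_specs
  if (!is.null(ps) && nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      s <- ps[i, ]
      if (s$type == "EC-EC" && is.null(p$junction))
        stop("peg spec ", i, ": EC-EC peg requested in a seamless vessel ",
             "(no EC-EC junction exists)")
      if (s$type %in% c("PC-EC", "EC-PC") && p$pc_coverage == 0)
        stop("peg spec ", i, ": ", s$type,
             " peg requires pericyte coverage > 0")
      host_t <- if (s$type == "EC-PC") p$pc_thickness else p$ec_thickness
      if (2 * s$radius_nm + 4 * sx > host_t)
        stop("peg spec ", i, ": peg of radius ", s$radius_nm,
             " nm (plus sheath) does not fit in its ", host_t,
             " nm thick host layer")
      if (!is.na(s$z) &&
          (s$z - s$z_extent %/% 2 < 3 ||
           s$z + s$z_extent %/% 2 > p$shape[3] - 2))
        stop("peg spec ", i, ": z extent (including its sealing caps) ",
             "leaves the volume")
    }
  }
  invisible(p)
}

#' Remove the EC-EC junction from phantom parameters (seamless vessel)
#'
#' A seamless capillary is built by a single EC with no self-junction, hence
#' no EC-EC junction class and no EC-EC pegs. Requesting an EC-EC peg in
#' seamless mode is an error.
#'
#' @param params A `PhantomParams` list.
#' @return Modified parameters with `junction = NULL`.
#' @export
seamlessMode <- function(params) {
  if (!is.null(params$peg_specs) && nrow(params$peg_specs) &&
      any(params$peg_specs$type == "EC-EC"))
    stop("seamless mode forbids EC-EC peg specs (no junction exists)")
  params$junction <- NULL
  .validatePhantomParams(params)
  params
}

## carve an ellipsoid aligned with the (radial, tangential, z) frame at
## angular position `theta0`; returns logical array over the full grid
.ellipsoidMask <- function(dims, sp, cx, cy, r0, theta0, z0, semi_nm) {
  sx <- sp@sx; sz <- sp@sz
  ## centre in voxel coordinates
  x0 <- cx + r0 * cos(theta0) / sx
  y0 <- cy + r0 * sin(theta0) / sx
  rx <- ceiling(max(semi_nm[1:2]) / sx) + 1L
  rz <- ceiling(semi_nm[3] / sz) + 1L
  xs <- max(1, floor(x0 - rx)):min(dims[1], ceiling(x0 + rx))
  ys <- max(1, floor(y0 - rx)):min(dims[2], ceiling(y0 + rx))
  zs <- max(1, floor(z0 - rz)):min(dims[3], ceiling(z0 + rz))
  out <- array(FALSE, dims)
  ur <- c(cos(theta0), sin(theta0))      # radial unit vector
  ut <- c(-sin(theta0), cos(theta0))     # tangential unit vector
  dx <- (xs - x0) * sx
  dy <- (ys - y0) * sx
  DX <- matrix(dx, length(xs), length(ys))
  DY <- matrix(dy, length(xs), length(ys), byrow = TRUE)
  U <- DX * ur[1] + DY * ur[2]
  V <- DX * ut[1] + DY * ut[2]
  base <- (U / semi_nm[1])^2 + (V / semi_nm[2])^2
  for (z in zs) {
    dz <- (z - z0) * sz
    out[xs, ys, z] <- base + (dz / semi_nm[3])^2 <= 1
  }
  out
}

#' Generate a synthetic vessel phantom with ground truth
#'
#' @param params A `PhantomParams` list from [phantomParams].
#' @return list with elements `label` ([LabelVolume-class]), `intensity`
#'   ([IntensityVolume-class]) and `truth` ([PhantomGroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomParams(seed = 7))
#' ph$truth
#' @export
generatePhantom <- function(params) {
  stopifnot(inherits(params, "PhantomParams"))
  .validatePhantomParams(params)
  .withSeed(params$seed, .generatePhantomImpl(params))
}

.generatePhantomImpl <- function(p) {
  dims <- p$shape
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  sp <- p$spacing
  sx <- sp@sx; sz <- sp@sz
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  R_L <- p$lumen_radius
  R_ECo <- R_L + p$ec_thickness
  R_PCi <- R_ECo + p$interface_thickness

  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  DX <- (X - cx) * sx
  DY <- (Y - cy) * sx
  R <- sqrt(DX^2 + DY^2)
  TH <- atan2(DY, DX)

  covFrac <- p$pc_coverage
  covered <- if (covFrac >= 1) matrix(TRUE, nx, ny)
             else if (covFrac <= 0) matrix(FALSE, nx, ny)
             else .angDist(TH, p$pc_arc_center) <= covFrac * pi
  arcHW <- covFrac * pi

  somaAng <- if (is.null(p$soma)) matrix(FALSE, nx, ny)
             else covered & (.angDist(TH, p$pc_arc_center) <=
                             p$soma$theta_halfwidth)

  buildSlice <- function(somaActive) {
    sa <- somaActive & somaAng
    t_pc <- p$pc_thickness + ifelse(sa, p$soma$extra_thickness %||% 0, 0)
    t_out <- ifelse(sa, p$bm_thickness_soma, p$bm_thickness_base)
    cls <- matrix(0L, nx, ny)
    cls[R < R_L] <- 4L
    cls[R >= R_L & R < R_ECo] <- 2L
    inCov <- covered & R >= R_ECo
    cls[inCov & R < R_PCi] <- 1L
    cls[inCov & R >= R_PCi & R < R_PCi + t_pc] <- 3L
    cls[inCov & R >= R_PCi + t_pc & R < R_PCi + t_pc + t_out] <- 1L
    nc <- (!covered) & R >= R_ECo & R < R_ECo + p$bm_thickness_base
    cls[nc] <- 1L
    ## BM caps over the PC arc's angular end faces, so the outer BM shell
    ## stays closed where coverage ends
    if (covFrac > 0 && covFrac < 1) {
      capW <- p$bm_thickness_base / pmax(R, sx)   # radians
      capz <- (!covered) &
        .angDist(TH, p$pc_arc_center) <= covFrac * pi + capW &
        R >= R_ECo & R < R_PCi + p$pc_thickness + p$bm_thickness_base
      cls[capz] <- 1L
    }
    ## likewise over the soma bulge's angular side walls
    if (any(sa)) {
      capW <- p$bm_thickness_base / pmax(R, sx)
      rTop <- R_PCi + p$pc_thickness + p$soma$extra_thickness +
        p$bm_thickness_soma
      capz <- covered & !sa &
        .angDist(TH, p$pc_arc_center) <= p$soma$theta_halfwidth + capW &
        R >= R_ECo & R < rTop & cls == 0L
      cls[capz] <- 1L
    }
    ## safety net: any residual background pixel 8-adjacent to cytosol
    ## becomes a 1-px BM wall, so the exterior can never reach the cells
    leak <- cls == 0L & .hasNeighbor2(cls == 2L | cls == 3L, pad = FALSE)
    cls[leak] <- 1L
    if (!is.null(p$junction)) {
      thj <- p$junction$theta +
        p$junction$amplitude * sin(pi * (R - R_L) / p$ec_thickness)
      jm <- R >= R_L & R < R_ECo &
        .angDist(TH, thj) * pmax(R, sx) <= p$junction$halfwidth_px * sx
      cls[jm] <- 18L
    }
    cls
  }

  tplProc <- buildSlice(FALSE)
  tplSoma <- if (is.null(p$soma)) tplProc else buildSlice(TRUE)
  g <- array(0L, dims)
  somaZ <- if (is.null(p$soma)) rep(FALSE, nz)
           else seq_len(nz) >= p$soma$z_range[1] &
                seq_len(nz) <= p$soma$z_range[2]
  for (k in seq_len(nz)) g[, , k] <- if (somaZ[k]) tplSoma else tplProc

  ## ---- nuclei ---------------------------------------------------------------
  nucProfile <- data.frame(slice = integer(0), area_um2 = numeric(0))
  if (!is.null(p$nuclei$pc) && !is.null(p$soma)) {
    nn <- p$nuclei$pc
    zc <- if (is.na(nn$z)) round(mean(p$soma$z_range)) else nn$z
    r0 <- R_PCi + (p$pc_thickness + p$soma$extra_thickness) / 2
    off <- nn$lobe_offset_slices %||% 0L
    m <- .ellipsoidMask(dims, sp, cx, cy, r0, p$pc_arc_center, zc - off,
                        nn$semi_nm)
    if (off > 0)
      m <- m | .ellipsoidMask(dims, sp, cx, cy, r0, p$pc_arc_center,
                              zc + off, nn$semi_nm)
    g[m & g == 3L] <- 6L
  }
  if (!is.null(p$nuclei$ec)) {
    nn <- p$nuclei$ec
    m <- .ellipsoidMask(dims, sp, cx, cy, (R_L + R_ECo) / 2, nn$theta,
                        nn$z, nn$semi_nm)
    g[m & g == 2L] <- 5L
  }

  ## ---- pegs -----------------------------------------------------------------
  pegGT <- data.frame()
  pegVoxList <- list()
  ps <- p$peg_specs
  used <- data.frame(theta = numeric(0), z = numeric(0), zext = numeric(0))
  ## junction angular position at the mid-EC-annulus radius (where the "S"
  ## wiggle is at its extremum), needed to keep pegs clear of the seam
  thjMid <- if (is.null(p$junction)) NA_real_
            else p$junction$theta + p$junction$amplitude
  if (!is.null(ps) && nrow(ps)) for (i in seq_len(nrow(ps))) {
    s <- ps[i, ]
    rpx <- s$radius_nm / sx
    ## keep sockets at least two opening radii apart so neighbouring
    ## sockets never share a morphological margin
    minSep <- (2 * rpx + 16) * sx / R_ECo
    okTheta <- function(cand, zc) {
      ## collide only when both the angles are close and the z ranges
      ## (including caps) overlap
      if (nrow(used)) {
        zclash <- abs(zc - used$z) <= (s$z_extent + used$zext) / 2 + 3
        if (any(.angDist(cand, used$theta) <= minSep & zclash))
          return(FALSE)
      }
      ## both peg types cross the EC annulus (shaft or neck): keep clear of
      ## the junction seam and the EC nucleus
      if (s$type %in% c("PC-EC", "EC-PC")) {
        if (!is.na(thjMid) &&
            .angDist(cand, thjMid) <=
              p$junction$amplitude + (s$radius_nm + 6 * sx) / R_ECo)
          return(FALSE)
        if (!is.null(p$nuclei$ec) &&
            .angDist(cand, p$nuclei$ec$theta) <=
              (p$nuclei$ec$semi_nm[2] + s$radius_nm + 6 * sx) / R_ECo)
          return(FALSE)
      }
      ## keep interface pegs clear of the soma bulge (its stepped walls
      ## produce morphological residue that must not merge with peg shafts)
      if (s$type %in% c("PC-EC", "EC-PC") && !is.null(p$soma) &&
          .angDist(cand, p$pc_arc_center) <=
            p$soma$theta_halfwidth + (s$radius_nm + 10 * sx) / R_PCi)
        return(FALSE)
      TRUE
    }
    th <- s$theta
    zc <- s$z
    if (is.na(th)) {
      margin <- (s$radius_nm + 4 * sx) / R_PCi + 0.08
      for (try in 1:400) {
        zlo <- 3 + s$z_extent %/% 2
        zhi <- nz - 2 - s$z_extent %/% 2
        if (s$type == "EC-EC") {
          ## EC-EC pegs line the junction seam in z slots one extent apart;
          ## the two seam sides use staggered slots so that pegs facing
          ## each other across the seam never share a z range (their
          ## socket wedges would otherwise cut each other's neck)
          side <- sample(c(-1, 1), 1)
          slots <- seq(zlo, zhi, by = s$z_extent + 4)
          if (side < 0) {
            slots <- slots + (s$z_extent + 4) %/% 2
            slots <- slots[slots <= zhi]
          }
          if (!length(slots)) slots <- zhi
          zcand <- if (!is.na(s$z)) s$z
                   else if (length(slots) == 1) slots
                   else sample(slots, 1)
          cand <- thjMid +
            side * ((s$radius_nm + 4 * sx) / ((R_L + R_ECo) / 2) + 0.02 +
                    stats::runif(1, 0, 0.35))
        } else {
          zcand <- if (!is.na(s$z)) s$z else sample(zlo:zhi, 1)
          cand <- if (covFrac >= 1) stats::runif(1, -pi, pi)
                  else p$pc_arc_center +
                    stats::runif(1, -1, 1) * (arcHW - margin)
        }
        if (okTheta(cand, zcand)) { th <- cand; zc <- zcand; break }
      }
      if (is.na(th)) stop("peg spec ", i, ": could not place peg without ",
                          "overlap; reduce peg count or size")
    }
    if (is.na(zc)) zc <- sample((3 + s$z_extent %/% 2):
                                (nz - 2 - s$z_extent %/% 2), 1)
    used <- rbind(used, data.frame(theta = th, z = zc, zext = s$z_extent))

    if (s$type %in% c("PC-EC", "EC-PC") && covFrac < 1 &&
        .angDist(th, p$pc_arc_center) + (s$radius_nm + 3 * sx) / R_PCi >
          arcHW)
      stop("peg spec ", i, ": peg at theta ", round(th, 3),
           " does not lie on the EC-PC interface (outside the PC arc)")

    carved <- .carvePeg(g, p, s, th, zc, R, TH, cx, cy)
    g <- carved$g
    vox <- carved$vox
    pegVoxList[[length(pegVoxList) + 1L]] <- vox
    nvox <- nrow(vox)
    zlen <- (diff(range(vox[, 3])) + 1L) * sz
    fer <- .feretPx(vox[, 1:2, drop = FALSE]) * sx + sx
    arcD <- NA_real_
    if (s$type == "PC-EC" && covFrac < 1) {
      thA <- p$pc_arc_center - arcHW
      thB <- p$pc_arc_center + arcHW
      arcD <- (R_PCi + sx / 2) * min(.angDist(th, thA), .angDist(th, thB))
    }
    pegGT <- rbind(pegGT, data.frame(
      id = nrow(pegGT) + 1L, type = s$type, theta = th, z_center = zc,
      radius_nm = s$radius_nm, z_extent = s$z_extent, n_voxels = nvox,
      volume_nm3 = nvox * sx * sx * sz, z_length_nm = zlen,
      max_xy_diameter_nm = fer, aspect_ratio = zlen / fer,
      arc_dist_nm = arcD, stringsAsFactors = FALSE))
  }

  ## ---- mitochondria (after pegs; kept clear of peg shafts and sheaths) ------
  mitoSemi <- c(35, 70, 120)
  mitoOK <- function(th, zc) {
    if (!nrow(pegGT)) return(TRUE)
    dth <- .angDist(th, pegGT$theta)
    all(dth * R_ECo > pegGT$radius_nm + mitoSemi[2] + 4 * sx |
        abs(zc - pegGT$z_center) > pegGT$z_extent / 2 + mitoSemi[3] / sz + 2)
  }
  if (p$n_mito[1] > 0) for (i in seq_len(p$n_mito[1])) {
    for (try in 1:50) {
      th <- stats::runif(1, -pi, pi)
      zc <- sample(3:(nz - 3), 1)
      ## EC mitochondria keep clear of the junction zone: an organelle over
      ## an EC-EC peg's neck corridor would sever its donor connection
      if (!is.na(thjMid) && .angDist(th, thjMid) <= 0.75) next
      if (mitoOK(th, zc)) break
    }
    m <- .ellipsoidMask(dims, sp, cx, cy, (R_L + R_ECo) / 2, th, zc,
                        mitoSemi)
    g[m & g == 2L] <- 11L
  }
  if (p$n_mito[2] > 0 && covFrac > 0) for (i in seq_len(p$n_mito[2])) {
    for (try in 1:50) {
      th <- p$pc_arc_center + stats::runif(1, -0.8, 0.8) * arcHW
      zc <- sample(3:(nz - 3), 1)
      if (mitoOK(th, zc)) break
    }
    m <- .ellipsoidMask(dims, sp, cx, cy, R_PCi + p$pc_thickness / 2, th,
                        zc, mitoSemi * 0.8)
    g[m & g == 3L] <- 12L
  }

  ## ---- ELPs -----------------------------------------------------------------
  elpGT <- data.frame()
  es <- p$elp_specs
  if (!is.null(es) && nrow(es)) for (i in seq_len(nrow(es))) {
    s <- es[i, ]
    if (s$location == "interface" &&
        covFrac < 1 && covFrac > 0 &&
        .angDist(s$theta, p$pc_arc_center) >= arcHW)
      stop("ELP spec ", i, ": interface ELP placed outside the PC arc")
    before <- sum(g == 17L)
    if (isTRUE(s$band)) {
      bm <- covered & R >= R_ECo & R < R_PCi &
        .angDist(TH, s$theta) <= s$theta_halfwidth
      for (k in seq_len(nz)) {
        sl <- g[, , k]
        sl[bm & sl %in% c(1L, 18L)] <- 17L
        g[, , k] <- sl
      }
      dom <- "interface"
    } else if (s$location == "interface") {
      r0 <- (R_ECo + R_PCi) / 2
      m <- .ellipsoidMask(dims, sp, cx, cy, r0, s$theta, s$z,
                          c(p$interface_thickness / 2 + 2 * sx, s$r_nm,
                            s$rz_slices * sz))
      g[m & (g %in% c(1L, 2L, 3L))] <- 17L
      dom <- "interface"
    } else {
      covHere <- covFrac >= 1 ||
        (covFrac > 0 && .angDist(s$theta, p$pc_arc_center) < arcHW)
      somaHere <- !is.null(p$soma) &&
        .angDist(s$theta, p$pc_arc_center) <= p$soma$theta_halfwidth &&
        !is.na(s$z) && s$z >= p$soma$z_range[1] && s$z <= p$soma$z_range[2]
      t_pc <- p$pc_thickness +
        if (somaHere) p$soma$extra_thickness else 0
      t_out <- if (somaHere) p$bm_thickness_soma else p$bm_thickness_base
      r0 <- if (covHere) R_PCi + t_pc + t_out / 2 else R_ECo + t_out / 2
      m <- .ellipsoidMask(dims, sp, cx, cy, r0, s$theta, s$z,
                          c(min(s$r_nm, t_out / 2), s$r_nm,
                            s$rz_slices * sz))
      g[m & g == 1L] <- 17L
      dom <- if (!covHere) "non_covered"
             else if (somaHere) "soma" else "process"
    }
    nvox <- sum(g == 17L) - before
    elpGT <- rbind(elpGT, data.frame(
      id = i, location = s$location, domain = dom, band = isTRUE(s$band),
      theta = s$theta, n_voxels = nvox, volume_nm3 = nvox * sx * sx * sz,
      arc_frac = if (isTRUE(s$band)) s$theta_halfwidth / arcHW else NA_real_,
      stringsAsFactors = FALSE))
  }

  ## ---- PC ER network --------------------------------------------------------
  if (covFrac > 0 && !is.null(p$er) && !is.null(p$soma)) {
    g <- .carveER(g, p, cx, cy, pegGT, pegVoxList, arcHW)
  }

  ## ---- ground truth odds and ends -------------------------------------------
  if (any(g == 6L)) {
    cnt <- vapply(seq_len(nz), function(k) sum(g[, , k] == 6L), numeric(1))
    nucProfile <- data.frame(slice = seq_len(nz),
                             area_um2 = cnt * sx * sx / 1e6)
  }

  truth <- new("PhantomGroundTruth",
               coverage = data.frame(slice = seq_len(nz),
                                     fraction = rep(covFrac, nz)),
               meanCoverage = covFrac,
               thicknessByDomain = c(soma = p$bm_thickness_soma,
                                     process = p$bm_thickness_base,
                                     non_covered = p$bm_thickness_base),
               pegs = pegGT, elps = elpGT,
               erSocketBias = p$er$socket_bias %||% 1,
               nucleusAreaProfile = nucProfile,
               params = unclass(p))

  lab <- LabelVolume(g, spacing = sp)
  img <- .renderIntensity(g, p)
  list(label = lab, intensity = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Carve one peg: a z-cylinder embedded in the recipient cell behind a
## 1-voxel sheath of BM (or junction class for EC-EC pegs), joined to the
## donor cell by a one-slice neck across the interface. Caps and neck walls
## facing the recipient are sealed so donor and recipient cytosol never
## become connected.
.carvePeg <- function(g, p, s, th, zc, R, TH, cx, cy) {
  sp <- p$spacing; sx <- sp@sx
  R_L <- p$lumen_radius
  R_ECo <- R_L + p$ec_thickness
  R_PCi <- R_ECo + p$interface_thickness
  rpx <- s$radius_nm / sx
  pegClass <- switch(s$type, "PC-EC" = 20L, "EC-PC" = 19L, "EC-EC" = 25L)
  sheathClass <- if (s$type == "EC-EC") 18L else 1L
  recipient <- switch(s$type, "PC-EC" = 2L, "EC-PC" = 3L, "EC-EC" = 2L)

  if (s$type == "EC-EC") {
    r_c <- (R_L + R_ECo) / 2
  } else if (s$type == "PC-EC") {
    r_c <- R_ECo - (s$radius_nm + 2 * sx)
  } else {
    r_c <- R_PCi + (s$radius_nm + 2 * sx)
  }
  x0 <- cx + r_c * cos(th) / sx
  y0 <- cy + r_c * sin(th) / sx

  nxg <- dim(g)[1]; nyg <- dim(g)[2]
  Dpx <- sqrt((matrix(seq_len(nxg), nxg, nyg) - x0)^2 +
              (matrix(seq_len(nyg), nxg, nyg, byrow = TRUE) - y0)^2)
  foot <- Dpx <= rpx
  sheath <- Dpx <= rpx + 1.45 & !foot

  z0 <- zc - s$z_extent %/% 2
  z1 <- z0 + s$z_extent - 1L
  zsAll <- max(1, z0 - 1):min(dim(g)[3], z1 + 1)

  ## neck corridor (applied at slice zc only); for EC-EC pegs also the
  ## full wedge between the junction seam and the cylinder, which becomes
  ## junction material (the recipient EC's socket) so no enclosed cytosol
  ## pockets are left beside the neck
  corridorFull <- NULL
  if (s$type == "EC-EC") {
    thj <- p$junction$theta +
      p$junction$amplitude * sin(pi * (r_c - R_L) / p$ec_thickness)
    phi <- ((TH - thj + pi) %% (2 * pi)) - pi
    phic <- ((th - thj + pi) %% (2 * pi)) - pi
    sgn <- if (phic >= 0) 1 else -1
    neck <- abs(R - r_c) <= 1.6 * sx & R >= R_L & R < R_ECo &
      phi * sgn <= abs(phic) & phi * sgn >= -2.5 * sx / r_c
    corridorFull <- R >= R_L & R < R_ECo &
      phi * sgn <= abs(phic) + (rpx + 2) * sx / r_c &
      phi * sgn >= -2.5 * sx / r_c
    recipSide <- phi * sgn > 0
  } else if (s$type == "PC-EC") {
    neck <- .angDist(TH, th) * pmax(R, sx) <= 1.6 * sx &
      R >= r_c + s$radius_nm * 0.6 & R <= R_PCi + 2.2 * sx
    recipSide <- NULL
  } else {
    neck <- .angDist(TH, th) * pmax(R, sx) <= 1.6 * sx &
      R <= r_c - s$radius_nm * 0.6 & R >= R_ECo - 2.2 * sx
    recipSide <- NULL
  }
  neckWall <- .hasNeighbor2(neck, pad = FALSE) & !neck

  voxAcc <- list()
  for (k in zsAll) {
    sl <- g[, , k]
    if (k >= z0 && k <= z1) {
      sl[sheath & sl == recipient] <- sheathClass
      conv <- foot & sl %in% c(1L, 2L, 3L, 18L)
      sl[conv] <- pegClass
      if (k == zc) {
        conv2 <- neck & sl %in% c(1L, 2L, 3L, 18L)
        sl[conv2] <- pegClass
        conv <- conv | conv2
        sealm <- neckWall & sl == recipient & !foot & !sheath
        if (s$type != "EC-EC") sl[sealm] <- sheathClass
        else sl[sealm & recipSide] <- 18L
        if (!is.null(corridorFull))
          sl[corridorFull & !neck & !neckWall & sl == recipient] <- 18L
      } else {
        ## seal the neck footprint and its walls above/below the neck
        ## slice (blocks 3D-diagonal contact with the recipient); for
        ## EC-EC pegs the whole junction-to-cylinder wedge is socket
        ## material
        nw <- neck | neckWall
        sl[nw & sl == recipient] <- sheathClass
        if (!is.null(corridorFull))
          sl[corridorFull & sl == recipient] <- 18L
      }
      wh <- which(conv, arr.ind = TRUE)
      if (nrow(wh)) voxAcc[[length(voxAcc) + 1L]] <-
        cbind(x = wh[, 1], y = wh[, 2], z = rep(k, nrow(wh)))
    } else {
      ## z caps: seal the cylinder ends with sheath material
      sl[(foot | sheath | neck | neckWall) & sl == recipient] <- sheathClass
    }
    g[, , k] <- sl
  }
  vox <- do.call(rbind, voxAcc)
  list(g = g, vox = vox)
}

## PC ER: tubule polylines at inner-third PC radius, all branching from a
## radial trunk that meets the PC nuclear envelope; with socket bias, rings
## hugging EC-peg sheaths are added
.carveER <- function(g, p, cx, cy, pegGT, pegVoxList, arcHW) {
  sp <- p$spacing; sx <- sp@sx
  nz <- dim(g)[3]
  R_PCi <- p$lumen_radius + p$ec_thickness + p$interface_thickness
  r_t <- R_PCi + 0.3 * p$pc_thickness
  thN <- p$pc_arc_center
  zN <- round(mean(p$soma$z_range))

  ## radial trunk from the tubule radius up to the nuclear envelope
  r_nuc <- R_PCi + (p$pc_thickness + (p$soma$extra_thickness %||% 0)) / 2
  for (rr in seq(r_t, r_nuc, by = sx)) {
    i <- round(cx + rr * cos(thN) / sx)
    j <- round(cy + rr * sin(thN) / sx)
    if (g[i, j, zN] == 3L) g[i, j, zN] <- 8L
  }

  ## baseline tubules stay clear of EC-peg sockets (including their sealed
  ## z caps, one section away); only the explicit socket-bias rings below
  ## may touch socket membranes
  dPegEC <- if (any(g == 19L)) .edt(array(g == 19L, dim(g)), sp)
            else NULL
  guard <- 2.6 * sp@sz
  canWrite <- function(i, j, k) {
    g[i, j, k] == 3L && (is.null(dPegEC) || dPegEC[i, j, k] > guard)
  }

  putPath <- function(g, thA, zA, thB, zB) {
    ## z leg then theta sweep, ~1-pixel steps, small radial wobble
    pts <- list()
    zsteps <- if (zA == zB) zA else seq(zA, zB, by = sign(zB - zA))
    for (z in zsteps) pts[[length(pts) + 1L]] <- c(thA, z)
    dth <- sx / r_t
    n <- max(2, ceiling(.angDist(thA, thB) / dth))
    sgn <- sign(((thB - thA + pi) %% (2 * pi)) - pi)
    for (q in seq_len(n))
      pts[[length(pts) + 1L]] <- c(thA + sgn * q * .angDist(thA, thB) / n,
                                   zB)
    for (ptq in seq_along(pts)) {
      pt <- pts[[ptq]]
      rw <- r_t + 1.5 * sx * sin(pt[1] * 9 + pt[2] * 0.7)
      i <- round(cx + rw * cos(pt[1]) / sx)
      j <- round(cy + rw * sin(pt[1]) / sx)
      k <- pt[2]
      if (i >= 1 && i <= dim(g)[1] && j >= 1 && j <= dim(g)[2] &&
          k >= 1 && k <= nz && canWrite(i, j, k))
        g[i, j, k] <- 8L
    }
    g
  }

  nt <- p$er$n_tubules %||% 6
  margin <- 0.1
  for (t in seq_len(nt)) {
    thB <- if (p$pc_coverage >= 1) stats::runif(1, -pi, pi)
           else p$pc_arc_center +
             stats::runif(1, -1, 1) * max(arcHW - margin, 0.05)
    zB <- sample(2:(nz - 1), 1)
    g <- putPath(g, thN, zN, thB, zB)
  }

  bias <- p$er$socket_bias %||% 1
  if (bias > 1 && nrow(pegGT)) {
    ecpc <- which(pegGT$type == "EC-PC")
    for (i in ecpc) {
      if (stats::runif(1) < 1 - 1 / bias) {
        g <- putPath(g, thN, zN, pegGT$theta[i], pegGT$z_center[i])
        ## ring of ER hugging the socket: PC voxels within 2 in-plane
        ## pitches of the peg component
        vox <- pegVoxList[[i]]
        sub <- c(range(vox[, 1]) + c(-5L, 5L), range(vox[, 2]) + c(-5L, 5L),
                 range(vox[, 3]))
        xs <- max(1, sub[1]):min(dim(g)[1], sub[2])
        ys <- max(1, sub[3]):min(dim(g)[2], sub[4])
        zs <- max(1, sub[5]):min(nz, sub[6])
        crop <- g[xs, ys, zs, drop = FALSE]
        m <- array(FALSE, dim(crop))
        pv <- vox
        pv[, 1] <- pv[, 1] - xs[1] + 1L
        pv[, 2] <- pv[, 2] - ys[1] + 1L
        pv[, 3] <- pv[, 3] - zs[1] + 1L
        m[pv] <- TRUE
        d <- .edt(m, sp)
        ring <- d <= 2 * sx + 1e-9 & crop == 3L
        crop[ring] <- 8L
        g[xs, ys, zs] <- crop
      }
    }
  }
  g
}

## grayscale rendering: per-class normal noise clipped below the ELP
## threshold; ELP voxels uniform and bright
.renderIntensity <- function(g, p) {
  means <- c(140, 90, 120, 125, 150, 105, 105, 85, 85, 85, 85, 60, 60,
             110, 110, 110, 110, 0, 90, 120, 125, 85, 85, 60, 60, 120)
  sds <- rep(p$intensity$sd, 26); sds[2] <- 15
  n <- length(g)
  v <- stats::rnorm(n, mean = means[as.vector(g) + 1L],
                    sd = sds[as.vector(g) + 1L])
  v <- pmin(pmax(v, 0), p$intensity$nonelp_max)
  isElp <- as.vector(g) == 17L
  if (any(isElp))
    v[isElp] <- stats::runif(sum(isElp), p$intensity$elp_range[1],
                             p$intensity$elp_range[2])
  img <- array(as.integer(round(v)), dim(g))
  IntensityVolume(img, spacing = p$spacing)
}

#' Ground-truth pericyte soma mask of a phantom
#'
#' PC voxels inside the soma's angular and axial extent, used as the
#' `soma_mask` input of [partitionSurface] when measuring phantoms.
#'
#' @param label The phantom's [LabelVolume-class].
#' @param truth The matching [PhantomGroundTruth-class].
#' @return Logical array.
#' @export
phantomSomaMask <- function(label, truth) {
  p <- truth@params
  g <- voxelData(label)
  dims <- dim(g)
  if (is.null(p$soma)) return(array(FALSE, dims))
  sx <- p$spacing@sx
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  X <- matrix(seq_len(dims[1]), dims[1], dims[2])
  Y <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  TH <- atan2((Y - cy) * sx, (X - cx) * sx)
  ang <- .angDist(TH, p$pc_arc_center) <= p$soma$theta_halfwidth
  out <- array(FALSE, dims)
  pcCls <- classGroup("PC_CELL")
  for (k in p$soma$z_range[1]:p$soma$z_range[2])
    out[, , k] <- ang & matrix(g[, , k] %in% pcCls, dims[1], dims[2])
  out
}

#' Degrade a final label volume to a 7-class semantic prediction
#'
#' Emulates a perfect semantic model output: peg/junction/cell identities
#' collapse back to the 7 semantic classes (cytosol of either cell and all
#' peg cytosol become background/cytosol; BM, ELPs and junctions become
#' basement membrane; Golgi joins ER as in the model's training).
#'
#' @param vol A [LabelVolume-class].
#' @return A [SemanticVolume-class].
#' @export
semanticFromLabel <- function(vol) {
  map <- integer(26)
  map[1 + c(0, 2, 3, 19, 20, 25)] <- 0L
  map[1 + c(1, 17, 18)] <- 1L
  map[1 + 4] <- 2L
  map[1 + c(5, 6)] <- 3L
  map[1 + c(7, 8, 9, 10, 21, 22)] <- 4L
  map[1 + c(11, 12, 23, 24)] <- 5L
  map[1 + c(13, 14, 15, 16)] <- 6L
  g <- array(map[voxelData(vol) + 1L], dim(voxelData(vol)))
  SemanticVolume(g, spacing = spacing(vol))
}

#' Preset phantom parameter sets
#'
#' Desk-scale analogues of the three analysed vessels: `"v1like"` (64%
#' coverage, EC-EC pegs outnumbering EC-PC pegs ~5:1), `"v2like"` (83%
#' coverage, two-lobed PC nucleus, a few EC-EC pegs), `"v3like"`/`"seamless"`
#' (84% coverage, single EC without a self-junction, hence no EC-EC pegs).
#' Peg counts are scaled to the phantom's short axial extent while keeping
#' the per-type ratios.
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @return A `PhantomParams` list.
#' @export
presetParams <- function(name = c("v1like", "v2like", "v3like", "seamless"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    v1like = phantomParams(
      pc_coverage = 0.64,
      peg_specs = rbind(pegSpec("PC-EC"), pegSpec("PC-EC"),
                        pegSpec("PC-EC"),
                        pegSpec("EC-PC"),
                        pegSpec("EC-EC"), pegSpec("EC-EC"),
                        pegSpec("EC-EC"), pegSpec("EC-EC"),
                        pegSpec("EC-EC")),
      seed = seed),
    v2like = phantomParams(
      pc_coverage = 0.83,
      soma = list(theta_halfwidth = 0.55, z_range = c(5L, 35L),
                  extra_thickness = 160),
      nuclei = list(ec = list(theta = pi / 2, z = 20,
                              semi_nm = c(40, 300, 400)),
                    pc = list(z = NA, semi_nm = c(90, 90, 300),
                              lobe_offset_slices = 6L)),
      peg_specs = rbind(pegSpec("PC-EC"), pegSpec("PC-EC"),
                        pegSpec("PC-EC"), pegSpec("PC-EC"),
                        pegSpec("EC-PC"), pegSpec("EC-PC"),
                        pegSpec("EC-EC")),
      seed = seed),
    v3like = ,
    seamless = seamlessMode(phantomParams(
      pc_coverage = 0.84,
      soma = list(theta_halfwidth = 0.55, z_range = c(5L, 35L),
                  extra_thickness = 160),
      nuclei = list(ec = list(theta = pi / 2, z = 20,
                              semi_nm = c(40, 300, 400)),
                    pc = list(z = NA, semi_nm = c(90, 90, 300),
                              lobe_offset_slices = 6L)),
      peg_specs = rbind(pegSpec("PC-EC"), pegSpec("PC-EC"),
                        pegSpec("PC-EC"), pegSpec("PC-EC"),
                        pegSpec("EC-PC"), pegSpec("EC-PC")),
      seed = seed)))
}
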