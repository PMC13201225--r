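## Axial composition profiles, nucleus shape profiling, and group
## statistics.

#' Axial cross-sectional area profiles by class group
#'
#' Per slice, the physical cross-sectional area of each class group: BM
#' (basement membrane, BM ELPs and EC-EC junctions), EC and PC (cytosol,
#' organelles and pegs, nuclei excluded), and the two nuclei. Summing a
#' group's areas times the section pitch reproduces its physical volume
#' exactly.
#'
#' @param vol A [LabelVolume-class].
#' @return data.frame (slice, z_um, bm_um2, ec_um2, pc_um2, ec_nucleus_um2,
#'   pc_nucleus_um2).
#' @export
axialClassAreas <- function(vol) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  apx <- sp@sx * sp@sy / 1e6   # um^2 per pixel
  groups <- list(
    bm_um2 = c(1L, 17L, 18L),
    ec_um2 = setdiff(classGroup("EC_CELL"), 5L),
    pc_um2 = setdiff(classGroup("PC_CELL"), 6L),
    ec_nucleus_um2 = 5L,
    pc_nucleus_um2 = 6L)
  out <- data.frame(slice = seq_len(d[3]),
                    z_um = seq_len(d[3]) * sp@sz / 1000)
  for (nm in names(groups)) {
    cnt <- vapply(seq_len(d[3]),
                  function(k) sum(g[, , k] %in% groups[[nm]]), numeric(1))
    out[[nm]] <- cnt * apx
  }
  out
}

#' Centroid-aligned axial area profile of a nucleus, with two-lobe dip
#' detection
#'
#' The per-slice cross-sectional area of the (largest) nucleus component,
#' with the axial coordinate shifted so the volume centroid sits at zero.
#' The rate of area change is computed by first differences after moving-
#' average smoothing. For a two-lobed nucleus the profile has two maxima;
#' the reported dip is the position of the minimum of the rate-of-change
#' curve between them. Unimodal profiles report `NA`.
#'
#' @param vol A [LabelVolume-class].
#' @param nucleus_class 5 (EC) or 6 (PC).
#' @param smooth_window Moving-average window (slices) before differencing.
#' @param prominence Minimum secondary-peak height as a fraction of the
#'   profile maximum.
#' @return list of class `"NucleusProfile"`: `profile` data.frame (slice,
#'   z_um, z_centered_um, area_um2, area_smooth_um2), `rate` data.frame
#'   (z_centered_um, dA_dz_um), `dip_z_centered_um` (`NA` if unimodal),
#'   `n_components`.
#' @export
nucleusProfile <- function(vol, nucleus_class = 6L, smooth_window = 5L,
                           prominence = 0.2) {
  g <- voxelData(vol)
  d <- dim(g)
  sp <- spacing(vol)
  m <- array(g == nucleus_class, d)
  if (!any(m)) stop("nucleus class ", nucleus_class, " is empty")
  lab <- .label(m, conn = 26L)
  n <- attr(lab, "n")
  if (n > 1L) {
    warning("nucleus has ", n, " components; using the largest")
    sizes <- tabulate(lab[m], nbins = n)
    m <- array(lab == which.max(sizes), d)
  }
  cnt <- vapply(seq_len(d[3]), function(k) sum(m[, , k]), numeric(1))
  area <- cnt * sp@sx * sp@sy / 1e6
  vox <- .whichVox(m)
  zc <- mean(vox[, 3])
  zum <- seq_len(d[3]) * sp@sz / 1000
  zcen <- (seq_len(d[3]) - zc) * sp@sz / 1000

  support <- which(cnt > 0)
  sl <- min(support):max(support)
  sm <- stats::filter(area[sl], rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm[is.na(sm)] <- area[sl][is.na(sm)]
  rate <- diff(sm) / (sp@sz / 1000)
  rateZ <- (zcen[sl][-1] + zcen[sl][-length(sl)]) / 2

  ## local maxima of the smoothed profile
  pk <- which(diff(sign(diff(sm))) < 0) + 1L
  pk <- pk[sm[pk] >= prominence * max(sm)]
  ## merge plateau-adjacent peaks: require a genuine valley between them
  dip <- NA_real_
  if (length(pk) >= 2L) {
    o <- order(sm[pk], decreasing = TRUE)
    p1 <- min(pk[o[1]], pk[o[2]]); p2 <- max(pk[o[1]], pk[o[2]])
    valley <- min(sm[p1:p2])
    if (valley <= (1 - 0.1) * min(sm[p1], sm[p2])) {
      seg <- p1:(p2 - 1L)
      dip <- rateZ[seg[which.min(rate[seg])]]
    }
  }
  out <- list(
    profile = data.frame(slice = seq_len(d[3]), z_um = zum,
                         z_centered_um = zcen, area_um2 = area),
    rate = data.frame(z_centered_um = rateZ, dA_dz_um = as.numeric(rate)),
    dip_z_centered_um = dip,
    n_components = n)
  class(out) <- "NucleusProfile"
  out
}

#' Kruskal-Wallis comparison with Dunn follow-up
#'
#' Rank-based Kruskal-Wallis test across groups; pairwise Dunn z tests
#' (tie-corrected) with Holm adjustment; significance markers at the
#' 0.05 / 0.01 / 0.001 / 0.0001 levels.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 1
#'   value).
#' @return list: `H`, `df`, `p_value`, `pairwise` data.frame (group1,
#'   group2, z, p_raw, p_adj, signif), `degenerate` (TRUE when all values
#'   are tied).
#' @export
groupCompare <- function(groups) {
  if (length(groups) < 2L)
    stop("need at least two groups to compare")
  if (any(!vapply(groups, length, integer(1))))
    stop("every group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups) %||% seq_along(groups),
                   vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L) {
    pw <- t(utils::combn(levels(gf), 2))
    return(list(H = 0, df = nlevels(gf) - 1L, p_value = 1,
                pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2],
                                      z = 0, p_raw = 1, p_adj = 1,
                                      signif = "ns"),
                degenerate = TRUE))
  }
  kw <- stats::kruskal.test(x, gf)
  ## Dunn z statistics with tie correction
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, gf, mean)
  nn <- tapply(r, gf, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  S <- N * (N + 1) / 12 - tieCorr
  pw <- t(utils::combn(levels(gf), 2))
  z <- numeric(nrow(pw)); praw <- numeric(nrow(pw))
  for (i in seq_len(nrow(pw))) {
    a <- pw[i, 1]; b <- pw[i, 2]
    se <- sqrt(S * (1 / nn[[a]] + 1 / nn[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    praw[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  padj <- stats::p.adjust(praw, method = "holm")
  marks <- cut(padj, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
               labels = c("****", "***", "**", "*", "ns"))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2], z = z,
                             p_raw = praw, p_adj = padj,
                             signif = as.character(marks)),
       degenerate = FALSE)
}
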