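test_that("edge coordinates parameterize the lumen-facing arc", {
  ph <- generatePhantom(phBare(seed = 3, pc_coverage = 0.6))
  ec <- buildEdgeCoordinates(ph$label, 10)
  expect_length(ec$sections, 1)
  sec <- ec$sections[[1]]
  ## maximum available position is half the arc length (min of two ends)
  expect_lt(abs(max(sec$position_nm) - sec$arc_length_nm / 2), 20)
  expect_true(all(sec$position_nm >= 0))
  expect_true(all(sec$position_nm <= sec$arc_length_nm / 2 + 1e-9))
  ## measured arc length close to the planted angular arc at the PC inner
  ## boundary radius
  p <- ph$truth@params
  L_true <- 0.6 * 2 * pi * (p$lumen_radius + p$ec_thickness +
                              p$interface_thickness)
  expect_lt(abs(sec$arc_length_nm - L_true) / L_true, 0.06)
})

test_that("a fully wrapping PC section is skipped as annular", {
  ph <- generatePhantom(phBare(seed = 3, pc_coverage = 1))
  ec <- buildEdgeCoordinates(ph$label, 10)
  expect_length(ec$sections, 0)
  expect_gte(ec$skipped_annular, 1)
})

test_that("digital circle arc length is within 5% of the true perimeter", {
  m <- matrix(FALSE, 160, 160)
  X <- matrix(1:160, 160, 160); Y <- t(X)
  disk <- (X - 80.5)^2 + (Y - 80.5)^2 <= 60^2
  path <- vesselmorph3d:::.mooreTrace(disk)
  L <- sum(vesselmorph3d:::.stepLengthsNm(rbind(path, path[1, ]), 1))
  expect_lt(abs(L / (2 * pi * 60) - 1), 0.05)
})

test_that("planted peg arc positions are recovered within one bin", {
  for (seed in c(2, 5, 8)) {
    ph <- generatePhantom(phantomParams(seed = seed))
    pegs <- vesselmorph3d:::.buildPegSet(ph$label)
    ed <- pegEdgeDistances(ph$label, pegs)
    want <- sort(ph$truth@pegs$arc_dist_nm[ph$truth@pegs$type == "PC-EC"])
    got <- sort(ed$observed_um * 1000)
    expect_length(got, length(want))
    expect_true(all(abs(got - want) <= 100))
  }
})

test_that("edge-distance distributions share bins and normalize", {
  ph <- generatePhantom(phantomParams(seed = 2))
  pegs <- vesselmorph3d:::.buildPegSet(ph$label)
  ed <- pegEdgeDistances(ph$label, pegs)
  expect_lt(abs(sum(ed$observed_prob) - 1), 1e-9)
  expect_lt(abs(sum(ed$available_prob) - 1), 1e-9)
  expect_true(all(diff(ed$observed_cum) >= -1e-12))
  expect_equal(ed$observed_cum[length(ed$observed_cum)], 1, tolerance = 1e-9)
  expect_equal(ed$available_cum[length(ed$available_cum)], 1,
               tolerance = 1e-9)
  ## identical binning by construction
  expect_length(ed$observed_prob, length(ed$available_prob))
  ## no PC-EC pegs -> explicit error
  ph2 <- generatePhantom(phBare(seed = 2))
  pegs2 <- vesselmorph3d:::.buildPegSet(ph2$label)
  expect_error(pegEdgeDistances(ph2$label, pegs2), "no PC-EC pegs")
})

test_that("pegs planted uniformly track the available distribution", {
  obs <- numeric(0); avail <- list()
  for (seed in c(4, 6, 9)) {
    set.seed(seed * 100)
    arcHW <- 0.64 * pi
    margin <- 0.25
    th <- pi + runif(4, -1, 1) * (arcHW - margin)
    p <- phBare(seed = seed, peg_specs = do.call(rbind, lapply(
      seq_along(th), function(i) pegSpec("PC-EC", z = c(7, 10, 12, 14)[i],
                                         theta = th[i]))))
    ph <- generatePhantom(p)
    pegs <- vesselmorph3d:::.buildPegSet(ph$label)
    ed <- pegEdgeDistances(ph$label, pegs)
    obs <- c(obs, ed$observed_um)
    avail[[length(avail) + 1]] <- ed$available_um
  }
  av <- unlist(avail)
  ## compare empirical cumulatives on a common grid; n = 12 pegs, so allow
  ## a generous Kolmogorov-style band
  qs <- seq(0.1, 1.4, by = 0.1)
  Fo <- ecdf(obs)(qs); Fa <- ecdf(av)(qs)
  expect_lt(max(abs(Fo - Fa)), 1.36 / sqrt(length(obs)) + 0.12)
})

test_that("peg-nucleus proximity counts contacts like brute force", {
  ph <- generatePhantom(phantomParams(seed = 5))
  pr <- pegNucleusProximity(ph$label)
  g <- voxelData(ph$label)
  ## brute-force check of the sampled distances on a subset
  set.seed(2)
  pick <- sample(nrow(pr$surface_voxels), 40)
  pegVox <- which(array(g %in% classGroup("PEG_PC"), dim(g)),
                  arr.ind = TRUE)
  for (q in pick) {
    p0 <- pr$surface_voxels[q, ]
    dd <- sweep(pegVox, 2, p0, "-")
    bf <- sqrt(min((dd[, 1] * 8)^2 + (dd[, 2] * 8)^2 + (dd[, 3] * 33)^2))
    expect_equal(pr$distance_nm[q], bf, tolerance = 1e-9)
  }
  ## brute-force contact count over components
  lab <- vesselmorph3d:::.label(array(g %in% classGroup("PEG_PC"), dim(g)),
                                conn = 26L)
  nuc <- which(g == 5L, arr.ind = TRUE)
  ids <- lab[lab != 0L]
  cnt <- 0L
  for (id in unique(ids)) {
    v <- which(lab == id, arr.ind = TRUE)
    best <- Inf
    for (r in seq_len(nrow(v))) {
      dd <- sweep(nuc, 2, v[r, ], "-")
      best <- min(best, min((dd[, 1] * 8)^2 + (dd[, 2] * 8)^2 +
                              (dd[, 3] * 33)^2))
    }
    if (sqrt(best) <= 8 + 1e-9) cnt <- cnt + 1L
  }
  expect_equal(pr$contact_count, cnt)
})

test_that("nucleus proximity handles missing nuclei and pegs", {
  ph <- generatePhantom(phBare(seed = 5))
  expect_error(pegNucleusProximity(ph$label), "no EC nucleus")
  ## nucleus present, no pegs: infinite sentinel distances, zero contacts
  p <- phBare(seed = 5)
  p$nuclei <- list(ec = list(theta = pi / 2, z = 10,
                             semi_nm = c(40, 300, 250)), pc = NULL)
  ph2 <- generatePhantom(p)
  pr <- pegNucleusProximity(ph2$label)
  expect_true(all(is.infinite(pr$distance_nm)))
  expect_equal(pr$contact_count, 0L)
})

test_that("a peg built against the nucleus registers a contact", {
  ## hand-built volume: lumen core, EC slab, nucleus, PC peg touching it
  d <- c(24, 24, 8)
  g <- array(2L, d)
  g[1:4, , ] <- 4L            # lumen
  g[10:14, 8:16, 3:6] <- 5L   # EC nucleus
  g[15, 10:12, 4:5] <- 20L    # PC peg face-adjacent to the nucleus
  vol <- LabelVolume(g)
  pr <- pegNucleusProximity(vol)
  expect_equal(pr$contact_count, 1L)
  expect_lte(min(pr$distance_nm), 8)
})
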