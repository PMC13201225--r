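test_that("exterior removal clears parenchyma predictions and is
           idempotent", {
  ph <- generatePhantom(phShort(seed = 3))
  sem <- semanticFromLabel(ph$label)
  g <- voxelData(sem)
  g[1:12, 1:12, 4] <- 2L      # false lumen blob in the parenchyma
  g[20:24, 20:24, 4] <- 5L    # false mitochondria
  sem2 <- SemanticVolume(g, spacing = spacing(sem))
  cl <- removeExterior(sem2)
  expect_length(attr(cl, "flagged_slices"), 0)
  expect_true(all(voxelData(cl)[1:12, 1:12, 4] == 0L))
  expect_true(all(voxelData(cl)[20:24, 20:24, 4] == 0L))
  ## interior untouched
  inVessel <- voxelData(sem) != 0L & voxelData(cl) != 0L
  expect_identical(voxelData(cl)[inVessel], voxelData(sem)[inVessel])
  cl2 <- removeExterior(cl)
  expect_identical(voxelData(cl2), voxelData(cl))
})

test_that("a slice with an open BM ring is repaired or flagged", {
  ## annular BM ring with a small breach (repairable by closing) and a
  ## slice with a wide breach (unrepairable, must be flagged)
  mk <- function(gapDeg) {
    d <- c(80, 80, 1)
    g <- array(0L, d)
    cx <- 40.5
    X <- matrix(1:80, 80, 80); Y <- t(X)
    r <- sqrt((X - cx)^2 + (Y - cx)^2)
    th <- atan2(Y - cx, X - cx)
    ring <- r >= 25 & r <= 30
    ring[abs(th) < gapDeg * pi / 180] <- FALSE
    g[, , 1][ring] <- 1L
    g[, , 1][r < 25] <- 2L   # lumen inside
    SemanticVolume(g)
  }
  ok <- removeExterior(mk(3))     # ~3 px gap: closing radius <= 3 repairs
  expect_length(attr(ok, "flagged_slices"), 0)
  bad <- removeExterior(mk(40))   # huge gap: cannot repair
  expect_identical(attr(bad, "flagged_slices"), 1L)
})

test_that("cytosol filling matches an independent flood-fill oracle", {
  ph <- generatePhantom(phShort(seed = 8))
  sem <- semanticFromLabel(ph$label)
  g <- voxelData(sem)
  ## delete some organelle predictions: they must become cytosol
  erase <- g == 5L
  g[erase] <- 0L
  sem <- SemanticVolume(g, spacing = spacing(sem))
  sem <- fillCytosol(removeExterior(sem))
  cyt <- cytosolMask(sem)
  expect_true(all(cyt[erase]))
  ## oracle: per-slice, zero-class pixels not 4-reachable from the border
  for (k in c(3, 10, 17)) {
    sl <- voxelData(sem)[, , k]
    free <- sl != 1L
    lab <- vesselmorph3d:::.label(free, conn = 4L)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    inner <- free & !(lab %in% border[border != 0])
    dim(inner) <- dim(sl)
    expect_identical(cyt[, , k], inner & sl == 0L)
  }
})

test_that("cell typing follows lumen contact with a 3D continuity pass", {
  p <- phBare(seed = 2, peg_specs = rbind(pegSpec("EC-PC", z = 10),
                                          pegSpec("PC-EC", z = 10)))
  ph <- generatePhantom(p)
  sem <- fillCytosol(removeExterior(semanticFromLabel(ph$label)))
  vol <- assignCellTypes(sem)
  g0 <- voxelData(ph$label)
  g1 <- voxelData(vol)
  ## annulus touching lumen -> EC; separated arc -> PC
  expect_true(all(g1[g0 == 2L] == 2L))
  expect_true(all(g1[g0 == 3L] == 3L))
  ## the EC-PC peg shaft is isolated from the lumen in most slices but must
  ## end up EC through 3D continuity
  expect_true(all(g1[g0 == 19L] == 2L))
  expect_true(all(g1[g0 == 20L] == 3L))
})

test_that("no PC-typed 2D region touches the lumen before continuity", {
  ph <- generatePhantom(phShort(seed = 6))
  sem <- fillCytosol(removeExterior(semanticFromLabel(ph$label)))
  g <- voxelData(sem)
  cyt <- cytosolMask(sem)
  g0 <- voxelData(ph$label)
  for (k in c(5, 10, 15)) {
    ck <- cyt[, , k]
    lab <- vesselmorph3d:::.label(ck, conn = 8L)
    lumAdj <- vesselmorph3d:::.hasNeighbor2(g[, , k] == 2L, pad = FALSE)
    ecIds <- setdiff(unique(lab[ck & lumAdj]), 0L)
    lumRegions <- ck & (lab %in% ecIds)
    dim(lumRegions) <- dim(ck)
    ## no PC-side truth voxel sits in a region that touches the lumen
    expect_true(all(!(g0[, , k][lumRegions] %in% classGroup("PC_CYTO"))))
  }
})

test_that("junction and peg relabeling recovers planted counts and is
           conservative", {
  p <- phantomParams(peg_specs = rbind(
    pegSpec("PC-EC"), pegSpec("PC-EC"), pegSpec("PC-EC"),
    pegSpec("EC-PC"), pegSpec("EC-EC")), seed = 31)
  ph <- generatePhantom(p)
  res <- postprocessChain(semanticFromLabel(ph$label))
  tb <- pegTable(res$pegs)
  expect_equal(sum(tb$peg_type == "PC-EC"), 3)
  expect_equal(sum(tb$peg_type == "EC-PC"), 1)
  expect_equal(sum(tb$peg_type == "EC-EC"), 1)
  ## conservation: pure relabelings preserve the cytosol+junction+BM unions
  g0 <- voxelData(ph$label); g1 <- voxelData(res$vol)
  cytCls <- c(classGroup("EC_CYTO"), classGroup("PC_CYTO"), 25L)
  expect_identical(array(g0 %in% cytCls, dim(g0)),
                   array(g1 %in% cytCls, dim(g1)))
  bmCls <- c(1L, 17L, 18L)
  expect_identical(array(g0 %in% bmCls, dim(g0)),
                   array(g1 %in% bmCls, dim(g1)))
  ## relabeling its own output changes nothing
  res2 <- relabelJunctionsAndPegs(res$vol)
  expect_identical(voxelData(res2$vol), voxelData(res$vol))
})

test_that("seamless vessels yield zero EC-EC peg components", {
  ps <- seamlessMode(phShort(seed = 12))
  ph <- generatePhantom(ps)
  res <- postprocessChain(semanticFromLabel(ph$label))
  expect_equal(sum(pegTable(res$pegs)$peg_type == "EC-EC"), 0)
  expect_equal(sum(voxelData(res$vol) == 25L), 0)
})

test_that("organelles inside pegs join the peg's classes and volume", {
  p <- phBare(seed = 4, peg_specs = rbind(pegSpec("PC-EC", z = 10)))
  ph <- generatePhantom(p)
  g <- voxelData(ph$label)
  ## plant a small mitochondrion inside the peg shaft
  vox <- which(g == 20L, arr.ind = TRUE)
  core <- vox[vox[, 3] == 10, , drop = FALSE]
  cen <- round(colMeans(core))
  mito <- vox[abs(vox[, 1] - cen[1]) <= 1 & abs(vox[, 2] - cen[2]) <= 1 &
                abs(vox[, 3] - 10) <= 1, , drop = FALSE]
  g[mito] <- 12L
  ph2 <- LabelVolume(g, spacing = spacing(ph$label))
  res <- postprocessChain(semanticFromLabel(ph2))
  g1 <- voxelData(res$vol)
  expect_true(all(g1[mito] == 24L))
  tb <- pegTable(res$pegs)
  i <- which(tb$peg_type == "PC-EC")
  expect_length(i, 1)
  ## the mitochondrion's voxels count towards the peg volume
  pv <- pegVoxels(res$pegs, i)
  keys <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(keys(mito) %in% keys(pv)))
})

test_that("peg metrics follow their definitions", {
  sp <- voxelSpacing()
  ## single-voxel footprint spanning two slices
  v <- cbind(x = c(5L, 5L), y = c(5L, 5L), z = c(3L, 4L))
  m <- pegMetrics(v, sp)
  expect_equal(m$z_length_nm, 66)
  expect_equal(m$max_xy_diameter_nm, 8)
  expect_equal(m$aspect_ratio, 8.25)
  expect_equal(m$volume_nm3, 2 * 2112)

  ## planted cylinder: volume within 15% of pi r^2 h
  p <- phBare(seed = 6, peg_specs = rbind(
    pegSpec("PC-EC", z = 10, radius_nm = 40, z_extent = 5)))
  ph <- generatePhantom(p)
  res <- postprocessChain(semanticFromLabel(ph$label))
  tb <- pegTable(res$pegs)
  expect_equal(nrow(tb), 1)
  analytic <- pi * 40^2 * (5 * 33)
  expect_lt(abs(tb$volume_nm3 - analytic) / analytic, 0.15)

  ## Feret diameters match exhaustive pairwise brute force
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:25, 1)
    v <- cbind(x = sample(1:12, n, TRUE), y = sample(1:12, n, TRUE),
               z = rep(1L, n))
    m <- pegMetrics(v, sp)
    expect_equal(m$max_xy_diameter_nm, bruteFeret(v[, 1:2]) * 8 + 8)
  }
})
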