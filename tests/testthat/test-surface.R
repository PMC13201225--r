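test_that("the smoothed EC mask swaps pegs between cells", {
  p <- phBare(seed = 2, peg_specs = rbind(pegSpec("PC-EC", z = 10),
                                          pegSpec("EC-PC", z = 10)))
  ph <- generatePhantom(p)
  g <- voxelData(ph$label)
  m <- smoothedEcMask(ph$label)
  expect_true(all(m[g == 20L]))    # PC peg filled into the EC mask
  expect_true(all(!m[g == 19L]))   # EC peg removed
  ## junction-free, peg-free phantom: mask equals the EC classes exactly
  ph0 <- generatePhantom(phBare(seed = 2))
  g0 <- voxelData(ph0$label)
  expect_identical(smoothedEcMask(ph0$label),
                   array(g0 %in% classGroup("EC_CELL"), dim(g0)))
})

test_that("coverage is exact at the extremes and recovered at mid
           fractions", {
  full <- generatePhantom(phBare(seed = 3, pc_coverage = 1))
  cp <- pcCoverage(full$label)
  expect_true(all(cp$per_slice$percent > 98))
  none <- generatePhantom(phBare(seed = 3, pc_coverage = 0))
  expect_equal(pcCoverage(none$label)$mean_percent, 0)
  half <- generatePhantom(phBare(seed = 3, pc_coverage = 0.5))
  expect_lt(abs(pcCoverage(half$label)$mean_percent - 50), 2)
})

test_that("uniform BM shells are recovered within one in-plane pitch", {
  p <- phBare(seed = 7, pc_coverage = 1)
  p$bm_thickness_base <- p$bm_thickness_soma <- 100
  ph <- generatePhantom(p)
  bt <- bmThicknessSurface(ph$label)
  expect_lt(abs(bt$mean_nm - 100), 8)
  ## adjacency bound: a BM voxel touching the cell mask reads at most one
  ## voxel pitch
  g <- voxelData(ph$label)
  cells <- array(g %in% c(classGroup("EC_CELL"), classGroup("PC_CELL")),
                 dim(g))
  bm <- array(g %in% classGroup("BM"), dim(g))
  inner <- vesselmorph3d:::.touches6(bm, cells)
  dd <- anisotropicEDT(cells, spacing(ph$label))
  expect_lte(max(dd[inner]), 33)
  expect_error(bmThicknessSurface(LabelVolume(array(0L, c(4, 4, 2)))),
               "basement")
})

test_that("soma-thinned BM reads thinner than process and non-covered
           domains", {
  p <- phantomParams(bm_thickness_soma = 50, bm_thickness_base = 120,
                     elp_specs = NULL, seed = 15)
  ph <- generatePhantom(p)
  dom <- partitionSurface(ph$label, phantomSomaMask(ph$label, ph$truth))
  s <- dom$summary
  soma <- s$mean_thickness_nm[s$domain == "soma"]
  proc <- s$mean_thickness_nm[s$domain == "process"]
  ncov <- s$mean_thickness_nm[s$domain == "non_covered"]
  expect_lt(soma, proc)
  expect_lt(soma, ncov)
})

test_that("surface partition matches brute-force nearest-region search", {
  ph <- generatePhantom(phShort(seed = 10))
  soma <- phantomSomaMask(ph$label, ph$truth)
  dom <- partitionSurface(ph$label, soma)
  g <- voxelData(ph$label)
  d <- dim(g)
  pcAll <- array(g %in% classGroup("PC_CELL"), d)
  ecAll <- array(g %in% classGroup("EC_CELL"), d)
  masks <- list(soma = pcAll & soma, process = pcAll & !soma,
                non_covered = ecAll)
  set.seed(1)
  pick <- sample(nrow(dom$voxels), 120)
  oracle <- bruteNearestRegion(masks, dom$voxels[pick, , drop = FALSE])
  expect_identical(as.integer(dom$domain[pick]), as.integer(oracle))
  ## partition is total and rerun-identical
  expect_false(anyNA(dom$domain))
  dom2 <- partitionSurface(ph$label, soma)
  expect_identical(dom$domain, dom2$domain)
})

test_that("no-PC phantoms have an entirely non-covered surface", {
  ph <- generatePhantom(phBare(seed = 5, pc_coverage = 0))
  dom <- partitionSurface(ph$label, array(FALSE, dim(voxelData(ph$label))))
  expect_true(all(dom$domain == "non_covered"))
})

test_that("ELP volume per area assigns planted pockets to their domains", {
  ## no ELPs -> all zeros
  ph0 <- generatePhantom(phShort(seed = 3))
  soma0 <- phantomSomaMask(ph0$label, ph0$truth)
  dom0 <- partitionSurface(ph0$label, soma0)
  res0 <- elpVolumePerArea(ph0$label, dom0, soma0)
  expect_true(all(res0$elp_per_area_um == 0))

  ## one pocket over a process region: only that domain is non-zero and its
  ## value is the planted volume over the domain area
  p <- phantomParams(elp_specs = rbind(
    elpSpec("bm", theta = pi + 1.5, z = 20, r_nm = 60)), seed = 8)
  ph <- generatePhantom(p)
  expect_identical(ph$truth@elps$domain, "process")
  soma <- phantomSomaMask(ph$label, ph$truth)
  dom <- partitionSurface(ph$label, soma)
  res <- elpVolumePerArea(ph$label, dom, soma)
  pr <- res[res$domain == "process", ]
  expect_equal(pr$n_elps, 1L)
  expect_equal(pr$elp_volume_um3, ph$truth@elps$volume_nm3 / 1e9)
  expect_equal(pr$elp_per_area_um, pr$elp_volume_um3 / pr$area_um2)
  expect_true(all(res$elp_per_area_um[res$domain != "process"] == 0))
})

test_that("soma-free ELP placement reads below the non-covered domain", {
  ## pockets planted only over non-covered BM: soma value must be smaller
  p <- phantomParams(elp_specs = rbind(
    elpSpec("bm", theta = 0.3, z = 12, r_nm = 60),
    elpSpec("bm", theta = -0.5, z = 28, r_nm = 60)), seed = 9)
  ph <- generatePhantom(p)
  expect_true(all(ph$truth@elps$domain == "non_covered"))
  soma <- phantomSomaMask(ph$label, ph$truth)
  dom <- partitionSurface(ph$label, soma)
  res <- elpVolumePerArea(ph$label, dom, soma)
  expect_lt(res$elp_per_area_um[res$domain == "soma"],
            res$elp_per_area_um[res$domain == "non_covered"])
})

test_that("intensity-based ELP detection respects threshold and size", {
  ph <- generatePhantom(phantomParams(seed = 4))
  g <- voxelData(ph$label)
  stripped <- g
  stripped[stripped == 17L] <- 1L   # annotation without the ELP class
  det <- detectELPs(LabelVolume(stripped, spacing = spacing(ph$label)),
                    ph$intensity)
  ## all truly planted ELP voxels are bright by construction and recovered
  expect_true(all(voxelData(det)[g == 17L] == 17L))
  ## nothing outside the BM mask is ever relabeled
  expect_identical(which(voxelData(det) == 17L & stripped != 1L),
                   integer(0))
})
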