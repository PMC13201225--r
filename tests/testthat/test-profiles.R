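test_that("axial areas conserve group volumes exactly", {
  ph <- generatePhantom(phShort(seed = 4))
  pr <- axialClassAreas(ph$label)
  g <- voxelData(ph$label)
  sp <- spacing(ph$label)
  for (grp in list(
    list(col = "bm_um2", cls = c(1L, 17L, 18L)),
    list(col = "pc_um2", cls = setdiff(classGroup("PC_CELL"), 6L)),
    list(col = "ec_nucleus_um2", cls = 5L))) {
    vol_um3 <- sum(pr[[grp$col]]) * sp@sz / 1000
    mask <- array(g %in% grp$cls, dim(g))
    expect_equal(vol_um3, physicalVolumeNm3(mask, sp) / 1e9)
  }
})

test_that("the soma bulge elevates the PC area exactly over its extent", {
  p <- phShort(seed = 6)
  ph <- generatePhantom(p)
  pr <- axialClassAreas(ph$label)
  somaZ <- seq(p$soma$z_range[1], p$soma$z_range[2])
  expect_gt(min(pr$pc_um2[somaZ]), max(pr$pc_um2[-somaZ]))
})

test_that("a spherical nucleus profile peaks near pi R^2", {
  d <- c(60, 60, 31)
  g <- array(2L, d)
  R <- 200
  cx <- 30.5; cz <- 16
  for (k in seq_len(d[3])) {
    X <- matrix(1:60, 60, 60); Y <- t(X)
    rr <- ((X - cx) * 8)^2 + ((Y - cx) * 8)^2 + ((k - cz) * 33)^2
    g[, , k][rr <= R^2] <- 6L
  }
  np <- nucleusProfile(LabelVolume(g), 6L)
  expect_lt(abs(max(np$profile$area_um2) - pi * R^2 / 1e6) /
              (pi * R^2 / 1e6), 0.1)
  ## convex body: no two-lobe dip
  expect_true(is.na(np$dip_z_centered_um))
})

test_that("two-lobed nuclei show a dip between the lobe centres", {
  p <- presetParams("v2like", seed = 4)
  ph <- generatePhantom(p)
  np <- nucleusProfile(ph$label, 6L)
  zc <- round(mean(p$soma$z_range))
  off <- p$nuclei$pc$lobe_offset_slices
  ## dip position in slices relative to centroid, allow 2 slices slack
  dipSlice <- np$dip_z_centered_um / 0.033
  lob <- off + 2
  expect_true(dipSlice >= -lob && dipSlice <= lob)
  expect_equal(np$n_components, 1L)
})

test_that("Kruskal-Wallis H matches direct rank arithmetic", {
  res <- groupCompare(list(a = c(1, 2, 3), b = c(10, 11, 12),
                           c = c(20, 21, 22)))
  expect_equal(res$H, 7.2)           # 12/(9*10) * 3*(4+25+64) - 3*10
  expect_false(res$degenerate)
  expect_equal(nrow(res$pairwise), 3)
  ## identical groups: degenerate, H = 0, p = 1
  res0 <- groupCompare(list(a = c(5, 5), b = c(5, 5)))
  expect_true(res0$degenerate)
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)
  expect_error(groupCompare(list(a = 1:3)), "two groups")
  ## markers at the legend levels
  set.seed(1)
  res2 <- groupCompare(list(a = rnorm(30), b = rnorm(30, 10)))
  expect_true(res2$pairwise$signif[1] %in% c("****", "***", "**", "*"))
})

test_that("reports are deterministic and complete on phantoms", {
  ph <- generatePhantom(phShort(seed = 3))
  soma <- phantomSomaMask(ph$label, ph$truth)
  td <- withr::local_tempdir()
  r1 <- runReport(ph$label, img = ph$intensity, soma_mask = soma,
                  outdir = file.path(td, "a"))
  r2 <- runReport(ph$label, img = ph$intensity, soma_mask = soma,
                  outdir = file.path(td, "b"))
  expect_identical(r1$summary, r2$summary)
  expect_length(r1$failures, 0)
  for (f in list.files(file.path(td, "a")))
    expect_identical(readLines(file.path(td, "a", f)),
                     readLines(file.path(td, "b", f)))
  expect_true(all(c("coverage.csv", "pegs.csv", "report.json") %in%
                    list.files(file.path(td, "a"))))
})

test_that("seamless phantoms report zero EC-EC pegs", {
  ph <- generatePhantom(seamlessMode(phShort(seed = 11)))
  res <- postprocessChain(semanticFromLabel(ph$label))
  rep <- runReport(res$vol, pegs = res$pegs)
  expect_equal(unname(rep$summary["n_pegs_ec_ec"]), 0)
})

test_that("a v1-like preset recovers its coverage and peg ratio", {
  p <- presetParams("v1like", seed = 2)
  ph <- generatePhantom(p)
  res <- postprocessChain(semanticFromLabel(ph$label))
  rep <- runReport(res$vol, pegs = res$pegs,
                   soma_mask = phantomSomaMask(ph$label, ph$truth))
  expect_lt(abs(rep$summary[["mean_coverage_percent"]] - 64), 2.5)
  expect_equal(unname(rep$summary["n_pegs_ec_ec"]), 5)
  expect_equal(unname(rep$summary["n_pegs_ec_pc"]), 1)
})
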