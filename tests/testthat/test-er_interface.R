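test_that("PC surface categories partition the membrane", {
  ph <- generatePhantom(phShort(seed = 3))
  cats <- categorizePcSurface(ph$label)
  expect_false(anyNA(cats$category))
  expect_equal(length(cats$category), nrow(cats$voxels))
  ## rerun-identical
  cats2 <- categorizePcSurface(ph$label)
  expect_identical(cats$category, cats2$category)
})

test_that("sockets exist only around EC pegs and shell them", {
  ## no EC pegs -> zero socket voxels
  ph0 <- generatePhantom(phBare(seed = 2, peg_specs = rbind(
    pegSpec("PC-EC", z = 10))))
  cats0 <- categorizePcSurface(ph0$label)
  expect_equal(sum(cats0$category == "socket"), 0)
  ## one planted EC peg -> socket voxels wrap it
  ph1 <- generatePhantom(phBare(seed = 2, peg_specs = rbind(
    pegSpec("EC-PC", z = 10))))
  cats1 <- categorizePcSurface(ph1$label)
  sock <- cats1$voxels[cats1$category == "socket", , drop = FALSE]
  expect_gt(nrow(sock), 0)
  g <- voxelData(ph1$label)
  dPeg <- anisotropicEDT(array(g == 19L, dim(g)), spacing(ph1$label))
  expect_true(all(dPeg[sock] <= 2 * 8 + 1e-9))
})

test_that("lumen-facing vs abluminal matches a radial oracle", {
  ph <- generatePhantom(phBare(seed = 4, pc_coverage = 0.6))
  cats <- categorizePcSurface(ph$label)
  p <- ph$truth@params
  d <- dim(voxelData(ph$label))
  cx <- (d[1] + 1) / 2
  r <- sqrt((cats$voxels[, 1] - cx)^2 + (cats$voxels[, 2] - cx)^2) * 8
  R_in <- p$lumen_radius + p$ec_thickness + p$interface_thickness
  R_out <- R_in + p$pc_thickness
  mid <- (R_in + R_out) / 2
  ## compare on clearly inner/outer voxels away from the arc ends
  th <- atan2(cats$voxels[, 2] - cx, cats$voxels[, 1] - cx)
  insideArc <- abs(abs(th - pi)) > 0.15 & abs(th - pi) < 0.6 * pi - 0.15
  inner <- insideArc & r < mid - 12
  outer <- insideArc & r > mid + 12
  expect_true(all(cats$category[inner] == "lumen_facing"))
  expect_true(all(cats$category[outer] == "abluminal"))
})

test_that("ER contact statistics respond to planted geometry", {
  ## interior tubules only: zero contact on every surface
  ph <- generatePhantom(phShort(seed = 7))
  cats <- categorizePcSurface(ph$label)
  st <- erContactStats(ph$label, cats)
  expect_true(all(st$contact_percent == 0))
  expect_true(all(st$mean_distance_nm >= 0))
  ## socket-biased ER touches the socket shell
  p <- phantomParams(peg_specs = rbind(pegSpec("EC-PC"), pegSpec("EC-PC")),
                     er = list(n_tubules = 4, socket_bias = 100),
                     elp_specs = NULL, seed = 7)
  ph2 <- generatePhantom(p)
  cats2 <- categorizePcSurface(ph2$label)
  st2 <- erContactStats(ph2$label, cats2)
  expect_gt(st2$contact_percent[st2$category == "socket"], 0)
  ## empty ER errors
  ph3 <- generatePhantom(phBare(seed = 2))
  expect_error(erContactStats(ph3$label, categorizePcSurface(ph3$label)),
               "ER")
})

test_that("interface skeleton lies on the medial axis of thick bands", {
  ## synthetic 3-pixel band between an EC and a PC slab
  d <- c(40, 30, 1)
  g <- array(0L, d)
  g[, 1:10, 1] <- 2L
  g[, 11:13, 1] <- 1L
  g[, 14:24, 1] <- 3L
  g[, 25, 1] <- 1L          # outer BM so the PC has an abluminal side
  vol <- LabelVolume(g)
  sk <- skeletonizeInterface(vol, 1)
  expect_gt(nrow(sk), 0)
  expect_true(all(abs(sk$y - 12) <= 1))
  ## 1-pixel band: the skeleton is the band
  g2 <- array(0L, d)
  g2[, 1:10, 1] <- 2L
  g2[, 11, 1] <- 1L
  g2[, 12:24, 1] <- 3L
  sk2 <- skeletonizeInterface(LabelVolume(g2), 1)
  expect_true(all(sk2$y == 11))
  expect_gte(nrow(sk2), d[1] - 4)
})

test_that("an annular interface yields a closed chain", {
  ph <- generatePhantom(phBare(seed = 5, pc_coverage = 1))
  sk <- skeletonizeInterface(ph$label, 10)
  expect_gt(nrow(sk), 0)
  expect_true(any(attr(sk, "closed")))
})

test_that("intensities and domains attach to the centerline", {
  ph <- generatePhantom(phShort(seed = 5))
  sk <- skeletonizeInterface(ph$label, 10)
  flat <- IntensityVolume(array(100L, dim(voxelData(ph$label))),
                          spacing = spacing(ph$label))
  ski <- interfaceIntensity(sk, flat, ph$label)
  expect_true(all(ski$intensity == 100))
  bad <- IntensityVolume(array(100L, c(4, 4, 2)))
  expect_error(interfaceIntensity(sk, bad, ph$label), "different shapes")
})

test_that("planted interface ELP bands reappear as bright runs of the
           right extent", {
  hw <- 0.15
  p <- phantomParams(peg_specs = NULL, elp_specs = rbind(
    elpSpec("interface", theta = pi + 0.8, band = TRUE,
            theta_halfwidth = hw)), seed = 6)
  ph <- generatePhantom(p)
  sk <- interfaceIntensity(skeletonizeInterface(ph$label, 20),
                           ph$intensity, ph$label)
  bright <- sk$intensity > 180
  expect_gt(sum(bright), 0)
  ## arc extent of the bright stretch close to the band's planted extent
  span <- diff(range(sk$arc_nm[bright]))
  p0 <- ph$truth@params
  R_mid <- p0$lumen_radius + p0$ec_thickness + p0$interface_thickness / 2
  extent <- 2 * hw * R_mid
  expect_lt(abs(span - extent), 4 * 8)
})

test_that("the lucency threshold is strict and fractions span 0 to 100", {
  sk <- data.frame(slice = 1, chain = 1, idx = 1:4, x = 1:4, y = 1,
                   arc_nm = (0:3) * 8,
                   intensity = c(180L, 181L, 10L, 200L),
                   domain = factor(rep("non_peg", 4),
                                   levels = c("EC_peg", "PC_peg",
                                              "non_peg")))
  fr <- elpFractionByDomain(sk)
  expect_equal(fr$percent[fr$domain == "non_peg"], 50)   # 181 and 200 only
  expect_true(is.na(fr$percent[fr$domain == "EC_peg"]))
  sk$intensity <- rep(255L, 4)
  expect_equal(elpFractionByDomain(sk)$percent[3], 100)
})

test_that("no-ELP phantoms have no bright interface voxels", {
  p <- phantomParams(elp_specs = NULL, seed = 9)
  ph <- generatePhantom(p)
  sk <- interfaceIntensity(interfaceSkeleton(ph$label), ph$intensity,
                           ph$label)
  expect_equal(sum(sk$intensity > 180), 0)
})
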