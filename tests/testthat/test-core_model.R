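test_that("label schema is a bijection over 0..25 with consistent groups", {
  sch <- labelSchema()
  expect_identical(unname(sch), 0:25)
  expect_identical(anyDuplicated(names(sch)), 0L)
  for (g in classGroup())
    expect_true(all(classGroup(g) %in% sch))
  expect_length(intersect(classGroup("EC_CYTO"), classGroup("PC_CYTO")), 0)
  expect_true(all(classGroup("PEG_PC") %in% classGroup("PC_CYTO")))
  expect_true(all(classGroup("PEG_EC") %in% classGroup("EC_CYTO")))
  expect_error(classGroup("NOPE"), "unknown class group")
})

test_that("voxel spacing enforces in-plane isotropy and positivity", {
  expect_equal(as.numeric(voxelSpacing()), c(8, 8, 33))
  expect_error(voxelSpacing(8, 4, 33), "isotropy")
  expect_error(voxelSpacing(-8, -8, 33), "positive")
})

test_that("axial lengths of the three vessels match the printed values", {
  bb <- vesselBoundingBoxes()
  expect_equal(axialLengthUm(bb$V1), 30.36)
  expect_equal(axialLengthUm(bb$V2), 33.0)
  expect_equal(axialLengthUm(bb$V3), 33.99)
  expect_equal(axialLengthUm(boundingBox(0, 0, 0, 0, 0, 0)), 0.033)
  expect_error(boundingBox(5, 4, 0, 0, 0, 0), "lo <= hi")
})

test_that("physical volumes are voxel count times voxel volume", {
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
  expect_equal(physicalVolumeNm3(m), 8 * 8 * 33)
  expect_equal(physicalVolumeNm3(array(FALSE, c(2, 2, 2))), 0)
  m2 <- array(TRUE, c(2, 2, 2))
  expect_equal(physicalVolumeNm3(m2, voxelSpacing(4, 4, 33)), 8 * 528)
})

test_that("anisotropic EDT is exact against the all-pairs oracle", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  d <- anisotropicEDT(m)
  expect_equal(d[3, 3, 4], 33)
  expect_equal(d[4, 3, 3], 8)
  expect_equal(d[3, 3, 3], 0)
  expect_error(anisotropicEDT(array(FALSE, c(3, 3, 3))), "empty")

  set.seed(42)
  for (i in 1:8) {
    dd <- c(sample(4:11, 1), sample(4:11, 1), sample(3:9, 1))
    m <- array(runif(prod(dd)) < 0.12, dd)
    if (!any(m)) m[1, 1, 1] <- TRUE
    expect_lt(max(abs(anisotropicEDT(m) - bruteEDT(m))), 1e-6)
  }
})

test_that("distances are monotone under source-mask growth", {
  set.seed(7)
  for (i in 1:5) {
    d <- c(9, 9, 7)
    m1 <- array(runif(prod(d)) < 0.08, d)
    if (!any(m1)) m1[2, 2, 2] <- TRUE
    extra <- array(runif(prod(d)) < 0.08, d)
    m2 <- m1 | extra
    expect_true(all(anisotropicEDT(m2) <= anisotropicEDT(m1) + 1e-12))
  }
})

test_that("label volumes round-trip through multi-page TIFF exactly", {
  ph <- generatePhantom(phShort(seed = 21))
  td <- withr::local_tempdir()
  f <- file.path(td, "lab.tif")
  writeLabelVolume(ph$label, f)
  v2 <- readLabelVolume(f)
  expect_identical(voxelData(v2), voxelData(ph$label))
  expect_equal(as.numeric(spacing(v2)), as.numeric(spacing(ph$label)))
  fi <- file.path(td, "img.tif")
  writeIntensityVolume(ph$intensity, fi)
  expect_identical(voxelData(readIntensityVolume(fi)),
                   voxelData(ph$intensity))
})

test_that("codes outside the schema are rejected with the offending code", {
  td <- withr::local_tempdir()
  bad <- array(0L, c(6, 6, 2)); bad[1, 1, 1] <- 26L
  tiff::writeTIFF(lapply(1:2, function(k) bad[, , k] / 65535),
                  file.path(td, "bad.tif"), bits.per.sample = 16L)
  expect_error(readLabelVolume(file.path(td, "bad.tif")), "26")
  expect_error(readLabelVolume(file.path(td, "missing.tif")), "cannot read")
  expect_error(LabelVolume(array(27L, c(2, 2, 2))), "27")
})

test_that("an all-background volume is a valid LabelVolume", {
  v <- LabelVolume(array(0L, c(10, 10, 5)))
  expect_s4_class(v, "LabelVolume")
  expect_true(all(voxelData(v) == 0L))
})
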