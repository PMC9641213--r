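test_that("NIfTI round trip preserves data, spacing and mask encoding", {
  ph <- tinyPhantom()
  path <- tempfile(fileext = ".nii.gz")
  v <- MRIVolume(ph$volume@data, spacing = c(0.9, 1.0, 1.1), id = "rt")
  writeVolume(v, path)
  v2 <- readVolume(path)
  expect_equal(dim(v2), dim(v))
  # stored as float32: round trip exact at that precision
  expect_equal(v2@data, ph$volume@data, tolerance = 1e-6)
  expect_equal(v2@spacing, c(0.9, 1.0, 1.1), tolerance = 1e-5)

  mpath <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$mask, mpath)
  m2 <- readMask(mpath)
  expect_identical(maskData(m2), maskData(ph$mask))
})

test_that("readVolume rejects missing files and non-3D images", {
  expect_error(readVolume(tempfile()), "not found")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), p4)
  expect_error(readVolume(p4), "non-3D")
})

test_that("padToCube centers data, pads with exact zeros and conserves sums", {
  v <- MRIVolume(array(runif(30 * 32 * 32), dim = c(30, 32, 32)))
  p <- padToCube(v, 32)
  expect_identical(dim(p), c(32L, 32L, 32L))
  expect_equal(sum(p@data), sum(v@data))
  # odd deficit: one zero plane leading, one trailing on axis 1
  expect_true(all(p@data[1, , ] == 0))
  expect_true(all(p@data[32, , ] == 0))
  expect_equal(p@data[2:31, , ], v@data)

  # even deficit splits symmetrically, extra voxel trails when odd
  v2 <- MRIVolume(array(1, dim = c(5, 8, 8)))
  p2 <- padToCube(v2, 8)
  expect_true(all(p2@data[2:6, , ] == 1))
  expect_true(all(p2@data[c(1, 7, 8), , ] == 0))

  expect_identical(padToCube(p, 32)@data, p@data)  # identity when cubic
  expect_error(padToCube(p, 16), "exceeds target")
})

test_that("resizeVolume is cubic, exact on constants and identity targets", {
  ph <- tinyPhantom()
  v <- ph$volume
  r <- resizeVolume(v, c(16, 16, 16))
  expect_identical(dim(r), c(16L, 16L, 16L))
  expect_equal(r@spacing, v@spacing * 2)

  cst <- MRIVolume(array(0.7, dim = c(20, 20, 20)))
  expect_equal(resizeVolume(cst, c(33, 17, 41))@data,
               array(0.7, dim = c(33, 17, 41)), tolerance = 1e-12)

  expect_equal(resizeVolume(v, dim(v))@data, v@data, tolerance = 1e-12)
  expect_error(resizeVolume(v, c(0, 16, 16)), "positive")
})

test_that("computeTissueMask recovers phantom support and picks the largest blob", {
  ph <- tinyPhantom(seed = 21, shape = c(48L, 48L, 48L))
  m <- computeTissueMask(ph$volume)
  expect_gt(dice(maskData(m), maskData(ph$mask)), 0.99)

  # two disjoint blobs, one much larger: only the large one survives
  x <- array(0, dim = c(40, 40, 40))
  x[5:30, 5:30, 5:30] <- 1    # large cube
  x[35:38, 35:38, 35:38] <- 1 # small cube
  m2 <- maskData(computeTissueMask(MRIVolume(x)))
  expect_true(all(m2[8:27, 8:27, 8:27]))
  expect_false(any(m2[35:38, 35:38, 35:38]))

  expect_error(computeTissueMask(MRIVolume(array(1, dim = c(32, 32, 32)))),
               "constant")
})

test_that("homogenizeBackground zeroes background only and is idempotent", {
  ph <- tinyPhantom(seed = 3, noise = 0.02, texture = 2)
  v <- MRIVolume(ph$volume@data + 0.05)  # nonzero background
  h <- homogenizeBackground(v, ph$mask)
  mk <- maskData(ph$mask)
  expect_true(all(h@data[!mk] == 0))
  expect_identical(h@data[mk], v@data[mk])
  expect_identical(homogenizeBackground(h, ph$mask)@data, h@data)
  expect_equal(sum(h@data), sum(v@data[mk]))
  expect_error(homogenizeBackground(v, TissueMask(array(TRUE, dim = c(8, 8, 8)))),
               "mismatch")
})

test_that("minmaxNormalize maps own extrema to [0,1], clips, and is affine invariant", {
  set.seed(4)
  x <- array(runif(16^3, 100, 600), dim = c(16, 16, 16))
  v <- MRIVolume(x)
  n1 <- minmaxNormalize(v)
  expect_equal(min(n1@data), 0)
  expect_equal(max(n1@data), 1)

  # affine rescaling of the input leaves the self-normalized output unchanged
  n2 <- minmaxNormalize(MRIVolume(3.5 * x + 11))
  expect_equal(n2@data, n1@data, tolerance = 1e-12)

  # LR value below the HR reference minimum clips to 0, above max to 1
  pr <- NormalizationParams(200, 500)
  cl <- minmaxNormalize(v, pr)@data
  expect_true(all(cl >= 0 & cl <= 1))
  expect_equal(cl[x < 200], rep(0, sum(x < 200)))
  expect_equal(cl[x > 500], rep(1, sum(x > 500)))

  expect_error(NormalizationParams(5, 5), "strictly greater")
})
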