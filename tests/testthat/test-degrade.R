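test_that("smoothSubsample shapes, spacing and constants follow the model", {
  v <- MRIVolume(array(runif(64^3), dim = c(64, 64, 64)))
  lr <- smoothSubsample(v, DegradationSpec(2))
  expect_identical(dim(lr), c(32L, 32L, 32L))
  expect_equal(lr@spacing, v@spacing * 2)

  # non-divisible dimensions floor
  v2 <- MRIVolume(array(runif(21 * 22 * 23), dim = c(21, 22, 23)))
  expect_identical(dim(smoothSubsample(v2, DegradationSpec(3))),
                   c(7L, 7L, 7L))

  cst <- MRIVolume(array(0.4, dim = c(20, 20, 20)))
  expect_equal(smoothSubsample(cst, DegradationSpec(2))@data,
               array(0.4, dim = c(10, 10, 10)), tolerance = 1e-12)

  expect_error(smoothSubsample(MRIVolume(array(1:8 / 8, dim = c(2, 2, 2))),
                               DegradationSpec(1)), "smaller than")
})

test_that("unit impulse at a sampled location returns the central kernel weight", {
  x <- array(0, dim = c(21, 21, 21))
  x[10, 10, 10] <- 1  # 0-based index 9 = 3*3, an N=3 sampling location
  lr <- smoothSubsample(MRIVolume(x), DegradationSpec(3))
  off <- -2:2
  ker <- exp(-outer(outer(off^2, off^2, `+`), off^2, `+`) / 2)
  expect_equal(lr@data[4, 4, 4], ker[3, 3, 3] / sum(ker), tolerance = 1e-12)
})

test_that("smoothSubsample equals dense convolution + decimation and is affine equivariant", {
  for (s in 1:4) {
    x <- randomVolume(c(20, 20, 20), seed = 100 + s)
    N <- 1 + s %% 3
    got <- smoothSubsample(MRIVolume(x), DegradationSpec(N))@data
    expect_equal(got, oracleGaussSubsample(x, N), tolerance = 1e-12)
    # affine equivariance before normalization
    got2 <- smoothSubsample(MRIVolume(2.5 * x - 0.7), DegradationSpec(N))@data
    expect_equal(got2, 2.5 * got - 0.7, tolerance = 1e-10)
  }
})

test_that("upsampleBicubic is exact on constants, identities and linear ramps", {
  cst <- MRIVolume(array(0.3, dim = c(10, 10, 10)))
  up <- upsampleBicubic(cst, c(20, 20, 20))
  expect_equal(up@data, array(0.3, dim = c(20, 20, 20)), tolerance = 1e-12)

  v <- MRIVolume(randomVolume(c(12, 12, 12), 7))
  expect_equal(upsampleBicubic(v, dim(v))@data, v@data, tolerance = 1e-12)

  # cubic interpolation reproduces a linear ramp away from the borders
  ramp <- MRIVolume(array(rep(seq(0, 1, length.out = 24), 24 * 24),
                          dim = c(24, 24, 24)))
  up2 <- upsampleBicubic(ramp, c(48, 24, 24))
  src <- (seq_len(48) - 1) / 2               # 0-based, origin-anchored
  expected <- src / 23
  interior <- 5:44
  expect_equal(up2@data[interior, 12, 12], expected[interior],
               tolerance = 1e-6)

  expect_error(upsampleBicubic(v, c(6, 12, 12)), ">=")
})

test_that("simulatePair returns aligned normalized pairs with degrading fidelity in N", {
  ph <- generatePhantom(PhantomSpec(shape = c(48L, 48L, 48L),
                                    textureScale = 2, noiseSd = 0.01,
                                    seed = 9))
  hr <- homogenizeBackground(ph$volume, ph$mask)
  ps <- lapply(c(2L, 3L, 4L), function(N)
    simulatePair(hr, ph$mask, DegradationSpec(N)))
  for (p in ps) {
    expect_identical(dim(p@lrUp@data), dim(p@hr@data))
    expect_true(all(p@lrUp@data >= 0 & p@lrUp@data <= 1))
    expect_true(all(p@hr@data >= 0 & p@hr@data <= 1))
  }
  fid <- vapply(ps, function(p) psnr(p@lrUp, p@hr), numeric(1))
  expect_true(all(is.finite(fid)))
  expect_true(all(diff(fid) < 0))  # x2 > x3 > x4

  # factor 1 with a single-voxel kernel is the identity chain
  id <- simulatePair(hr, ph$mask, DegradationSpec(1, kernelSize = 1))
  expect_equal(id@lrUp@data, id@hr@data, tolerance = 1e-6)
})
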