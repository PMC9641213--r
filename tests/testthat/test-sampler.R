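test_that("makeGrid produces the expected origin lattices", {
  expect_identical(nrow(makeGrid(c(256, 256, 256), 32, 32)@origins), 512L)
  expect_identical(nrow(makeGrid(c(256, 256, 256), 32, 16)@origins),
                   3375L)  # ((256-32)/16 + 1)^3
  g1 <- makeGrid(c(32, 32, 32), 32, 7)
  expect_identical(g1@origins, matrix(0L, 1, 3))

  # clamping adds a final flush origin, duplicates removed
  g2 <- makeGrid(c(70, 32, 32), 32, 32)
  expect_identical(sort(unique(g2@origins[, 1])), c(0L, 32L, 38L))
  # origins sorted lexicographically
  o <- g2@origins
  expect_true(!is.unsorted(o[, 1]))
  expect_error(makeGrid(c(16, 32, 32), 32, 32), "smaller than patch")
})

test_that("extractPatches tiles exactly at stride = size and counts multiplicity at stride = size/2", {
  x <- randomVolume(c(32, 32, 32), 42)
  g <- makeGrid(dim(x), 16, 16)
  ps <- extractPatches(x, g)
  rebuilt <- array(0, dim = dim(x))
  for (i in seq_len(nrow(g@origins))) {
    o <- g@origins[i, ]
    rebuilt[o[1] + 1:16, o[2] + 1:16, o[3] + 1:16] <- ps@patches[[i]]
  }
  expect_identical(rebuilt, x)

  cst <- array(0.5, dim = c(32, 32, 32))
  expect_true(all(vapply(extractPatches(cst, g)@patches,
                         function(p) all(p == 0.5), logical(1))))

  # an interior voxel appears in ceil(size/stride)^3 = 8 patches at stride 16
  g2 <- makeGrid(c(64, 64, 64), 32, 16)
  x2 <- array(0, dim = c(64, 64, 64))
  x2[33, 33, 33] <- 1
  hits <- sum(vapply(extractPatches(x2, g2)@patches, sum, numeric(1)) > 0)
  expect_identical(hits, 8L)
})

test_that("extractSlices preserves order and restacks losslessly", {
  x <- randomVolume(c(6, 16, 16), 1)
  for (ax in 1:3) {
    sl <- extractSlices(x, ax)
    expect_length(sl, dim(x)[ax])
    expect_identical(stackSlices(sl, ax), x)
  }
  expect_identical(extractSlices(x, 1)[[3]], x[3, , ])
  expect_error(extractSlices(x, 2, inPlane = c(8, 8)), "wrong in-plane")
  x1 <- array(runif(16), dim = c(1, 4, 4))
  expect_length(extractSlices(x1, 1), 1L)
})

test_that("randomRotate is seeded, identity at zero angles, and support-preserving on spheres", {
  x <- randomVolume(c(32, 32, 32), 2)
  expect_identical(rotateVolume(x, c(0, 0, 0)), x)
  r1 <- randomRotate(x, seed = 77)
  r2 <- randomRotate(x, seed = 77)
  expect_identical(r1, r2)
  expect_false(identical(r1, randomRotate(x, seed = 78)))

  # a centered sphere is (near-)invariant under any rotation
  ctr <- (48 + 1) / 2
  g <- expand.grid(x = 1:48, y = 1:48, z = 1:48)
  sph <- array(as.numeric((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <=
                          18^2), dim = c(48, 48, 48))
  rs <- randomRotate(sph, seed = 5)
  expect_gt(dice(rs >= 0.5, sph >= 0.5), 0.98)
})

test_that("inner-cube stitching is the exact inverse of extraction", {
  x <- randomVolume(c(64, 64, 64), 3)
  ps <- extractPatches(x, makeGrid(dim(x), 32, 16))
  expect_identical(stitchPatches(ps), x)

  # all-ones outputs certify single coverage everywhere
  ones <- lapply(ps@patches, function(p) array(1, dim = dim(p)))
  expect_identical(stitchPatches(ps, ones), array(1, dim = dim(x)))

  expect_error(stitchPatches(ps, ones[-1]), "align 1:1")
  ps2 <- extractPatches(x, makeGrid(dim(x), 32, 32))
  expect_error(stitchPatches(ps2), "stride = patchSize/2")
})

test_that("stitching constant patches shows the hard inner-cube transition", {
  x <- array(0, dim = c(32, 16, 16))
  ps <- extractPatches(x, makeGrid(dim(x), 16, 8))
  consts <- seq_along(ps@patches)  # patch i filled with value i
  outs <- lapply(consts, function(v) array(v, dim = c(16, 16, 16)))
  st <- stitchPatches(ps, outs)
  # origins along axis 1: 0, 8, 16 -> regions [1:12], [13:20], [21:32]
  expect_true(all(st[1:12, , ] == st[1, 1, 1]))
  expect_true(all(st[13:20, , ] == st[13, 1, 1]))
  expect_true(all(st[21:32, , ] == st[21, 1, 1]))
  expect_identical(length(unique(as.vector(st))), 3L)
})
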