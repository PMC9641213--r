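test_that("clean phantoms are piecewise constant with one mode per shell", {
  ph <- tinyPhantom(seed = 2)
  vals <- sort(unique(as.vector(ph$volume@data)))
  expect_identical(vals, sort(c(0, PhantomSpec()@intensityLevels)))
  expect_identical(sort(unique(as.vector(ph$labels))), 0:3)
  # background exactly zero, mask = union of shells
  expect_identical(maskData(ph$mask), ph$labels > 0L)
  expect_true(all(ph$volume@data[!maskData(ph$mask)] == 0))
  expect_gt(sum(maskData(ph$mask)), 0)
})

test_that("phantom generation is deterministic in the seed", {
  s <- PhantomSpec(textureScale = 2, noiseSd = 0.02, seed = 123)
  p1 <- generatePhantom(s)
  p2 <- generatePhantom(s)
  expect_identical(p1$volume@data, p2$volume@data)
  expect_identical(p1$mask@data, p2$mask@data)
  p3 <- generatePhantom(PhantomSpec(textureScale = 2, noiseSd = 0.02,
                                    seed = 124))
  expect_false(identical(p1$volume@data, p3$volume@data))
})

test_that("computeTissueMask agrees with the generator's ground-truth support", {
  ph <- generatePhantom(PhantomSpec(shape = c(48L, 48L, 48L),
                                    textureScale = 2, noiseSd = 0.01,
                                    seed = 31))
  m <- computeTissueMask(ph$volume)
  expect_gt(dice(maskData(m), maskData(ph$mask)), 0.99)
})

test_that("cohorts are varied, reproducible, and usable end-to-end", {
  co <- generateCohort(5, PhantomSpec(shape = c(32L, 32L, 32L), seed = 1),
                       seed = 9)
  expect_length(co, 5L)
  ids <- vapply(co, function(p) p$volume@id, character(1))
  expect_identical(ids, sprintf("phantom-%03d", 1:5))
  for (i in 1:4)
    expect_gt(mae255(co[[i]]$volume@data, co[[i + 1]]$volume@data), 0)
  co2 <- generateCohort(5, PhantomSpec(shape = c(32L, 32L, 32L), seed = 1),
                        seed = 9)
  expect_identical(co[[3]]$volume@data, co2[[3]]$volume@data)
})

test_that("Gaussian degradation measurably removes phantom detail", {
  ph <- generatePhantom(PhantomSpec(seed = 8))
  hr <- homogenizeBackground(ph$volume, ph$mask)
  pair <- simulatePair(hr, ph$mask, DegradationSpec(2))
  expect_lt(psnr(pair@lrUp, pair@hr), 45)
})
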