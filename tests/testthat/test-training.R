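test_that("masked L1+gradient loss honors its closed forms and the brute-force oracle", {
  a <- randomVolume(c(5, 5, 5), 1)
  full <- array(1, dim = dim(a))
  expect_identical(maskedL1GradientLoss(a, a, full), 0)
  # constant offset: gradient term vanishes analytically
  expect_equal(maskedL1GradientLoss(a + 0.1, a, full), 0.1, tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:5) {
    p <- randomVolume(c(5, 5, 5), 10 + rep)
    t <- randomVolume(c(5, 5, 5), 20 + rep)
    m <- array(as.numeric(runif(125) < 0.5), dim = c(5, 5, 5))
    expect_equal(maskedL1GradientLoss(p, t, m), oracleMaskedLoss(p, t, m),
                 tolerance = 1e-12)
  }

  # zero iff equal on the mask; invariant to values outside it
  m <- array(0, dim = c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1
  p2 <- a; p2[1, 1, 1] <- 99
  expect_identical(maskedL1GradientLoss(p2, a, m), 0)
  expect_identical(maskedL1GradientLoss(a, a, array(0, dim = dim(a))), 0)
  expect_gt(maskedL1GradientLoss(a + m * 0.01, a, m), 0)
  expect_error(maskedL1GradientLoss(a, a[1:4, , ], full[1:4, , ]), "mismatch")

  # 2D grids are accepted
  expect_equal(maskedL1GradientLoss(a[, , 1] + 0.2, a[, , 1],
                                    matrix(1, 5, 5)), 0.2, tolerance = 1e-12)
})

test_that("cohort splits reproduce the reference cardinalities deterministically", {
  ids33 <- sprintf("a%02d", 1:33)
  p1 <- makeSplits(ids33, c(0.8, 0, 0.2), seed = 1)
  expect_length(p1@trainIds, 26L)
  expect_length(p1@valIds, 0L)
  expect_length(p1@testIds, 7L)

  ids90 <- sprintf("c%02d", 1:90)
  p2 <- makeSplits(ids90, c(0.6, 0.2, 0.2), seed = 2)
  expect_identical(vapply(list(p2@trainIds, p2@valIds, p2@testIds), length,
                          integer(1)), c(54L, 18L, 18L))
  expect_setequal(c(p2@trainIds, p2@valIds, p2@testIds), ids90)

  expect_identical(makeSplits(ids90, c(0.6, 0.2, 0.2), seed = 2)@trainIds,
                   p2@trainIds)
  expect_false(identical(makeSplits(ids90, c(0.6, 0.2, 0.2), 3)@trainIds,
                         p2@trainIds))
  expect_error(makeSplits(character(), c(1, 0, 0)), "empty")
  expect_error(makeSplits(ids33, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("reduce-on-plateau schedule divides by e^0.2 and floors at the minimum", {
  cfg <- TrainConfig(epochs = 10L, seed = 1L)
  hist_flat <- data.frame(epoch = 1:6, trainLoss = 1,
                          valLoss = c(1, 1, 1, 1, 1, 1), lr = 1e-4)
  expect_equal(lrScheduleStep(hist_flat, cfg), 1e-4 * exp(-0.2),
               tolerance = 1e-12)

  # strictly improving: untouched
  hist_imp <- data.frame(epoch = 1:6, trainLoss = 1,
                         valLoss = seq(1, 0.5, length.out = 6), lr = 1e-4)
  expect_identical(lrScheduleStep(hist_imp, cfg), 1e-4)

  # long plateau: decays but never below lr_min
  hist_long <- data.frame(epoch = 1:200, trainLoss = 1, valLoss = 1, lr = NA)
  expect_equal(lrScheduleStep(hist_long, cfg), 1e-5)

  # patience counter resets after a reduction (4 more flat epochs: no change)
  hist7 <- data.frame(epoch = 1:9, trainLoss = 1, valLoss = 1, lr = NA)
  expect_equal(lrScheduleStep(hist7, cfg), 1e-4 * exp(-0.2), tolerance = 1e-12)
  hist10 <- data.frame(epoch = 1:11, trainLoss = 1, valLoss = 1, lr = NA)
  expect_equal(lrScheduleStep(hist10, cfg), 1e-4 * exp(-0.4), tolerance = 1e-12)

  expect_error(lrScheduleStep(hist_flat[0, ], cfg), "at least one")
})

test_that("training reduces the validation loss and is seed-reproducible", {
  pairs <- tinyPairs(10, seed = 13)
  plan <- makeSplits(names(pairs), c(0.8, 0.2, 0), seed = 1)
  spec <- NetworkSpec(initialFilters = 4L)
  cfg <- TrainConfig(epochs = 8L, batchSize = 8L, seed = 3L, lr0 = 1e-3)
  fit <- trainNetwork(buildNetwork(spec, seed = 3), pairs, plan, cfg,
                      patchSize = 16L, augment = FALSE)
  h <- fit$history@history
  expect_identical(nrow(h), 8L)
  expect_lt(h$valLoss[fit$history@bestEpoch], h$valLoss[1])
  expect_identical(fit$history@bestEpoch, which.min(h$valLoss))
  expect_true(all(diff(h$lr) <= 0) && all(h$lr >= cfg@lrMin))

  fit2 <- trainNetwork(buildNetwork(spec, seed = 3), pairs, plan, cfg,
                       patchSize = 16L, augment = FALSE)
  expect_identical(fit2$history@history, h)
  expect_identical(fit2$net@weights, fit$net@weights)
})

test_that("transfer learning reuses base weights and reaches low loss sooner", {
  spec <- NetworkSpec(initialFilters = 4L)
  pairsA <- tinyPairs(8, seed = 41)
  pairsB <- tinyPairs(6, seed = 77)
  planA <- makeSplits(names(pairsA), c(1, 0, 0), seed = 1)
  planB <- makeSplits(names(pairsB), c(0.67, 0.33, 0), seed = 1)

  base <- trainNetwork(buildNetwork(spec, seed = 1), pairsA, planA,
                       TrainConfig(epochs = 12L, batchSize = 8L, seed = 1L,
                                   lr0 = 1e-3),
                       patchSize = 16L, augment = FALSE)$net

  # zero retraining epochs: returned network is the base, unchanged
  same <- transferLearn(base, pairsB, planB,
                        TrainConfig(epochs = 0L, batchSize = 8L, seed = 1L))
  expect_identical(same$net@weights, base@weights)

  # structurally incompatible base is rejected
  expect_error(
    transferLearn(buildNetwork(NetworkSpec(initialFilters = 2L), seed = 1),
                  pairsB, planB,
                  TrainConfig(epochs = 1L, batchSize = 8L, seed = 1L),
                  patchSize = 16L, augment = FALSE, spec = spec),
    "incompatible")

  cfg2 <- function(s) TrainConfig(epochs = 3L, batchSize = 8L, seed = s,
                                  lr0 = 1e-3)
  gain <- vapply(1:3, function(s) {
    vt <- transferLearn(base, pairsB, planB, cfg2(s), patchSize = 16L,
                        augment = FALSE)$history@history$valLoss
    vr <- trainNetwork(buildNetwork(spec, seed = s + 50), pairsB, planB,
                       cfg2(s), patchSize = 16L,
                       augment = FALSE)$history@history$valLoss
    min(vr) - min(vt)  # positive when transfer is ahead
  }, numeric(1))
  expect_gt(median(gain), 0)
})

test_that("superResolve reconstructs whole volumes with background homogenization", {
  pairs <- tinyPairs(1, seed = 19)
  pair <- pairs[[1]]
  net <- buildNetwork(NetworkSpec(initialFilters = 2L), seed = 2)
  sr <- superResolve(net, pair@lrUp, mask = pair@mask, patchSize = 16L)
  expect_identical(dim(sr), dim(pair@lrUp))
  expect_true(all(sr@data >= 0 & sr@data <= 1))
  expect_true(all(sr@data[!maskData(pair@mask)] == 0))

  # without a mask the raw network output is returned
  sr2 <- superResolve(net, pair@lrUp, patchSize = 16L)
  expect_false(all(sr2@data[!maskData(pair@mask)] == 0))

  net2d <- buildNetwork(NetworkSpec(dims = 2L, initialFilters = 2L), seed = 2)
  sr3 <- superResolve(net2d, pair@lrUp, mask = pair@mask)
  expect_identical(dim(sr3), dim(pair@lrUp))
})
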