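test_that("structural counts match the architecture arithmetic", {
  net <- buildNetwork(NetworkSpec(initialFilters = 2L), seed = 1)
  cc <- countLayers(net)
  expect_identical(cc$stages, 9L)
  expect_identical(cc$conv_blocks, 23L)
  expect_identical(cc$transposed_convs, 4L)
  expect_identical(cc$total_conv_layers, 28L)
  expect_identical(cc$shortcut_projections, 8L)

  # closed form: conv_blocks = sum(stageBlocks); total = blocks + 4 + 1
  net2 <- buildNetwork(NetworkSpec(initialFilters = 2L,
                                   stageBlocks = rep(2L, 9)), seed = 1)
  cc2 <- countLayers(net2)
  expect_identical(cc2$conv_blocks, 18L)
  expect_identical(cc2$total_conv_layers, 23L)

  # 2D and 3D variants share identical structure
  cc3 <- countLayers(buildNetwork(NetworkSpec(dims = 2L, initialFilters = 2L),
                                  seed = 1))
  expect_identical(cc3, cc)
})

test_that("invalid network specs are rejected", {
  expect_error(NetworkSpec(stageBlocks = c(2, 2, 3, 3, 3, 3, 3, 2, 3)),
               "symmetric")
  expect_error(NetworkSpec(stageBlocks = rep(2L, 8)), "length 9")
  expect_error(NetworkSpec(dims = 4L), "2 or 3")
  expect_error(NetworkSpec(pool = 1L), "pool")
})

test_that("forward preserves shape, bounds outputs and is deterministic", {
  net <- buildNetwork(NetworkSpec(initialFilters = 2L), seed = 3)
  x <- randomVolume(c(32, 32, 32), 5)
  y <- forwardPass(net, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))
  expect_identical(forwardPass(net, x), y)

  # batch of patches
  ys <- forwardPass(net, list(x[1:16, 1:16, 1:16], x[1:16, 1:16, 17:32]))
  expect_length(ys, 2L)
  expect_identical(dim(ys[[1]]), c(16L, 16L, 16L))

  net2 <- buildNetwork(NetworkSpec(dims = 2L, initialFilters = 2L), seed = 3)
  s <- forwardPass(net2, x[1, , ])
  expect_identical(dim(s), c(32L, 32L))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("indivisible spatial dimensions are rejected with the required divisor", {
  net <- buildNetwork(NetworkSpec(initialFilters = 2L), seed = 1)
  expect_error(forwardPass(net, randomVolume(c(24, 24, 24), 1)),
               "divisible by 16")
})

test_that("one optimization step moves every parameter tensor", {
  spec <- NetworkSpec(initialFilters = 2L)
  net <- buildNetwork(spec, seed = 7)
  pairs <- tinyPairs(2, seed = 31)
  plan <- methods::new("SplitPlan", trainIds = names(pairs),
                       valIds = character(), testIds = character(),
                       fractions = c(1, 0, 0))
  cfg <- TrainConfig(epochs = 1L, batchSize = 16L, seed = 7L, lr0 = 1e-3)
  fit <- trainNetwork(net, pairs, plan, cfg, patchSize = 16L,
                      augment = FALSE)
  w0 <- net@weights
  w1 <- fit$net@weights
  trainable <- grep("rmean|rvar", names(w0), invert = TRUE, value = TRUE)
  moved <- vapply(trainable,
                  function(nm) max(abs(w1[[nm]] - w0[[nm]])) > 0, logical(1))
  expect_true(all(moved))
})

test_that("checkpoints round-trip weights and write a structure manifest", {
  net <- buildNetwork(NetworkSpec(initialFilters = 2L), seed = 9)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(net, path)
  manifest <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_identical(manifest$conv_blocks, 23L)
  expect_identical(manifest$initialFilters, 2L)

  net2 <- loadCheckpoint(path)
  expect_identical(names(net2@weights), names(net@weights))
  x <- randomVolume(c(16, 16, 16), 2)
  expect_identical(forwardPass(net2, x), forwardPass(net, x))
})
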