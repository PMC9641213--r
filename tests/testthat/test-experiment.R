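test_that("run configurations validate keys, factors and fractions", {
  expect_error(validateRunConfig(list(bogus = 1)), "invalid config key: 'bogus'")
  expect_error(validateRunConfig(list(train = list(warmup = 3))),
               "train.warmup")
  expect_error(validateRunConfig(list(factors = 5L)), "\\{1, 2, 3, 4\\}")
  expect_error(validateRunConfig(list(fractions = c(0.5, 0.1, 0.1))),
               "sum to 1")
  cfg <- validateRunConfig(list(factors = c(1L, 2L)))
  expect_identical(cfg$factors, c(1L, 2L))
  expect_identical(cfg$train$epochs, defaultRunConfig()$train$epochs)
})

test_that("YAML configurations round-trip losslessly", {
  cfg <- defaultRunConfig()
  cfg$seed <- 42L
  cfg$factors <- c(2L, 3L)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  cfg2 <- readRunConfig(path)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$factors, c(2L, 3L))
  expect_equal(cfg2$cohort$shape, cfg$cohort$shape)
  expect_equal(cfg2$train$lr0, cfg$train$lr0)
})

test_that("dry runs report the plan without computing", {
  cfg <- defaultRunConfig()
  cfg$out_dir <- tempfile()
  out <- expect_output(runExperiment(cfg, dryRun = TRUE), "dry run")
  expect_false(dir.exists(cfg$out_dir))
})

test_that("a tiny experiment runs end-to-end, writes its tables, and reruns identically", {
  cfg <- defaultRunConfig()
  cfg$out_dir <- file.path(tempdir(), "voxsr-exp1")
  cfg$cohort$n <- 6L
  cfg$cohort$shape <- c(32L, 32L, 32L)
  cfg$fractions <- c(0.5, 0.17, 0.33)
  cfg$network$initial_filters <- 4L
  cfg$train$epochs <- 2L
  cfg$train$batch_size <- 8L
  cfg$train$patch_size <- 16L
  res <- runExperiment(cfg)
  expect_true(file.exists(file.path(res$outDir, "report.csv")))
  expect_true(file.exists(file.path(res$outDir, "summary.csv")))
  expect_true(file.exists(file.path(res$outDir, "history-x2.csv")))
  expect_true(file.exists(file.path(res$outDir, "checkpoint-x2.rds")))
  expect_true(file.exists(file.path(res$outDir, "config-resolved.yaml")))
  # 2 test volumes x 2 methods x 1 factor
  expect_identical(nrow(res$report), 4L)
  expect_setequal(unique(res$report$method), c("interp", "cnn3d"))

  cfg$out_dir <- file.path(tempdir(), "voxsr-exp2")
  res2 <- runExperiment(cfg)
  expect_identical(res2$report, res$report)
  unlink(c(file.path(tempdir(), "voxsr-exp1"),
           file.path(tempdir(), "voxsr-exp2")), recursive = TRUE)
})
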