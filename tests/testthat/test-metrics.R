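test_that("psnr matches closed forms, the brute-force oracle, and the identity sentinel", {
  a <- array(0.5, dim = c(4, 4, 4))
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a + 0.1, a), 20, tolerance = 1e-10)

  x <- randomVolume(c(8, 8, 8), 1)
  y <- randomVolume(c(8, 8, 8), 2)
  expect_equal(psnr(x, y), oraclePSNR(x, y), tolerance = 1e-10)
  expect_equal(psnr(x, y), psnr(y, x))
  expect_error(psnr(x, y[1:4, , ]), "mismatch")
})

test_that("mae255 matches closed forms and the brute-force oracle", {
  a <- array(0.5, dim = c(4, 4, 4))
  expect_identical(mae255(a, a), 0)
  expect_equal(mae255(a + 0.1, a), 25.5, tolerance = 1e-10)
  x <- randomVolume(c(4, 4, 4), 3)
  y <- randomVolume(c(4, 4, 4), 4)
  expect_equal(mae255(x, y), oracleMAE255(x, y), tolerance = 1e-10)
  expect_equal(mae255(x, y), mae255(y, x))
})

test_that("ssim is exactly 1 on identical inputs and follows the printed global form", {
  x <- randomVolume(c(12, 12, 12), 5)
  expect_equal(ssim(x, x), 1.0, tolerance = 1e-12)

  # single-window variant on constant inputs: closed form with the repeated
  # c1 in the variance factor, exactly as printed
  a <- 0.3; b <- 0.7
  c1 <- 1e-4; c2 <- 9e-4
  got <- ssim(array(a, dim = c(8, 8, 8)), array(b, dim = c(8, 8, 8)),
              global = TRUE)
  expect_equal(got, (2 * a * b + c1) * c2 / ((a^2 + b^2 + c1) * c1),
               tolerance = 1e-12)

  # anti-correlated structure about a common mean is negative
  ck <- array(0.5 + 0.4 * (-1)^(outer(outer(1:12, 1:12, `+`), 1:12, `+`)),
              dim = c(12, 12, 12))
  expect_lt(ssim(1 - ck, ck), 0)
})

test_that("global metrics are permutation invariant but windowed SSIM is not", {
  x <- randomVolume(c(10, 10, 10), 7)
  ph <- tinyPhantom(seed = 6)
  y <- ph$volume@data[1:10, 1:10, 1:10]
  set.seed(8)
  perm <- sample(length(x))
  xp <- array(x[perm], dim = dim(x))
  yp <- array(y[perm], dim = dim(y))
  expect_equal(psnr(xp, yp), psnr(x, y), tolerance = 1e-12)
  expect_equal(mae255(xp, yp), mae255(x, y), tolerance = 1e-12)
  expect_equal(ssim(xp, yp, global = TRUE), ssim(x, y, global = TRUE),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ssim(xp, yp), ssim(x, y), tolerance = 1e-6)))
})

test_that("evaluateCohort builds the report/summary tables and tracks degradation order", {
  ph <- generatePhantom(PhantomSpec(shape = c(48L, 48L, 48L),
                                    textureScale = 2, noiseSd = 0.01,
                                    seed = 15))
  hr <- homogenizeBackground(ph$volume, ph$mask)
  entries <- list()
  for (N in c(2L, 3L, 4L)) {
    pair <- simulatePair(hr, ph$mask, DegradationSpec(N))
    entries[[paste0("x", N)]] <- list(id = "ph1", factor = N, hr = pair@hr,
                                      sr = list(interp = pair@lrUp))
  }
  ev <- evaluateCohort(entries)
  expect_identical(nrow(ev$report), 3L)  # volumes x methods x factors
  expect_true(all(diff(ev$report$psnr_db[order(ev$report$factor)]) < 0))
  expect_true(all(diff(ev$report$ssim[order(ev$report$factor)]) < 0))

  ident <- evaluateCohort(list(list(id = "v", factor = 2L, hr = hr,
                                    sr = list(interp = hr))))
  expect_identical(ident$summary$psnr_mean, Inf)
  expect_identical(ident$summary$mae255_mean, 0)
  expect_equal(ident$summary$ssim_mean, 1.0, tolerance = 1e-12)

  bad <- list(list(id = "v", factor = 2L, hr = hr,
                   sr = list(interp = resizeVolume(hr, c(16, 16, 16)))))
  expect_error(evaluateCohort(bad), "pairing")
})

test_that("compareMethods runs RM-ANOVA and paired Wilcoxon with exact small-sample nulls", {
  set.seed(30)
  n <- 18
  base <- rnorm(n, 30, 1)
  report <- rbind(
    data.frame(id = sprintf("v%02d", 1:n), method = "interp", factor = 2L,
               psnr_db = base, mae255 = 6 + rnorm(n, 0, 0.2),
               ssim = 0.9 + rnorm(n, 0, 0.005)),
    data.frame(id = sprintf("v%02d", 1:n), method = "cnn3d", factor = 2L,
               psnr_db = base + 1, mae255 = 5 + rnorm(n, 0, 0.2),
               ssim = 0.93 + rnorm(n, 0, 0.005)))
  cmp <- compareMethods(report)
  w <- cmp$wilcoxon[cmp$wilcoxon$metric == "psnr_db", ]
  # a constant +1 dB shift over 18 volumes is detected at alpha 0.05
  expect_lt(w$p, 0.05)
  expect_true(w$significant)
  av <- cmp$anova[cmp$anova$metric == "psnr_db" & cmp$anova$effect == "method", ]
  expect_lt(av$p, 0.05)

  # identical method columns degenerate gracefully
  rep2 <- report
  rep2[rep2$method == "cnn3d", c("psnr_db", "mae255", "ssim")] <-
    rep2[rep2$method == "interp", c("psnr_db", "mae255", "ssim")]
  cmp2 <- compareMethods(rep2)
  expect_true(all(cmp2$wilcoxon$degenerate))
  expect_true(all(is.na(cmp2$wilcoxon$p)))

  expect_error(compareMethods(report[c(1:4, 19:22), ]), "insufficient")
})

test_that("Wilcoxon p-values agree with exhaustive sign-assignment enumeration", {
  fixtures <- list(c(0.5, -0.2, 0.8, 1.1, -0.6, 0.3, 0.9, -1.4),
                   c(-0.7, 1.2, 0.4, -0.1, 0.6, 2.0, -1.1, 0.25),
                   c(0.15, 0.35, -0.55, 0.75, 0.95, -1.15, 1.35, 1.55))
  set.seed(44)
  for (rep in 1:3) {
    d <- fixtures[[rep]]
    a <- rnorm(length(d), 30, 1)
    report <- rbind(
      data.frame(id = sprintf("v%d", seq_along(d)), method = "m1",
                 factor = 2L, psnr_db = a + d, mae255 = 1, ssim = 0.9),
      data.frame(id = sprintf("v%d", seq_along(d)), method = "m2",
                 factor = 2L, psnr_db = a, mae255 = 1, ssim = 0.9))
    cmp <- suppressWarnings(compareMethods(report))
    got <- cmp$wilcoxon[cmp$wilcoxon$metric == "psnr_db", ]
    oracle <- oracleWilcoxonP(d)
    expect_equal(got$statistic, oracle$V)
    expect_equal(got$p, oracle$p, tolerance = 1e-10)
  }
})
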