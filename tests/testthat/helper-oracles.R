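# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive re-implementations, kept free
# of any package internals.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

randomVolume <- function(shape, seed) {
  set.seed(seed)
  array(runif(prod(shape)), dim = shape)
}

# symmetric (half-sample) reflection of 0-based indices
reflect0 <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  while (any(i < 0 | i >= n)) {
    i <- ifelse(i < 0, -1L - i, i)
    i <- ifelse(i >= n, 2L * n - 1L - i, i)
  }
  i
}

# dense Gaussian convolution followed by strided decimation, direct sums
oracleGaussSubsample <- function(x, N, ksize = 5L, sigma = 1.0) {
  h <- (ksize - 1L) %/% 2L
  off <- -h:h
  ker <- exp(-outer(outer(off^2, off^2, `+`), off^2, `+`) / (2 * sigma^2))
  ker <- ker / sum(ker)
  d <- dim(x)
  od <- d %/% N
  out <- array(0, dim = od)
  for (k in seq_len(od[3])) {
    iz <- reflect0((k - 1L) * N + off, d[3]) + 1L
    for (j in seq_len(od[2])) {
      iy <- reflect0((j - 1L) * N + off, d[2]) + 1L
      for (i in seq_len(od[1])) {
        ix <- reflect0((i - 1L) * N + off, d[1]) + 1L
        out[i, j, k] <- sum(ker * x[ix, iy, iz])
      }
    }
  }
  out
}

# double-loop masked L1 + forward-difference gradient loss
oracleMaskedLoss <- function(pred, target, mask) {
  d <- dim(pred)
  s_mae <- 0; n_mae <- 0; s_g <- 0; n_g <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] == 0) next
    n_mae <- n_mae + 1
    s_mae <- s_mae + abs(pred[i, j, k] - target[i, j, k])
    if (i < d[1] && mask[i + 1, j, k] != 0) {
      n_g <- n_g + 1
      s_g <- s_g + abs((pred[i + 1, j, k] - pred[i, j, k]) -
                       (target[i + 1, j, k] - target[i, j, k]))
    }
    if (j < d[2] && mask[i, j + 1, k] != 0) {
      n_g <- n_g + 1
      s_g <- s_g + abs((pred[i, j + 1, k] - pred[i, j, k]) -
                       (target[i, j + 1, k] - target[i, j, k]))
    }
    if (k < d[3] && mask[i, j, k + 1] != 0) {
      n_g <- n_g + 1
      s_g <- s_g + abs((pred[i, j, k + 1] - pred[i, j, k]) -
                       (target[i, j, k + 1] - target[i, j, k]))
    }
  }
  (if (n_mae > 0) s_mae / n_mae else 0) + (if (n_g > 0) s_g / n_g else 0)
}

oraclePSNR <- function(est, ref) {
  s <- 0; n <- 0
  for (i in seq_along(est)) { s <- s + (est[i] - ref[i])^2; n <- n + 1 }
  20 * log10(1 / sqrt(s / n))
}

oracleMAE255 <- function(est, ref) {
  s <- 0
  for (i in seq_along(est)) s <- s + abs(est[i] - ref[i])
  255 * s / length(est)
}

# exact paired Wilcoxon signed-rank p-value (two-sided) by enumerating all
# sign assignments of the ranked absolute differences
oracleWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(Vs - mu) >= abs(V - mu) - 1e-12)
  list(V = V, p = p)
}

# a small clean phantom shared by several tests
tinyPhantom <- function(seed = 11, shape = c(32L, 32L, 32L), noise = 0,
                        texture = 0) {
  generatePhantom(PhantomSpec(shape = shape, textureScale = texture,
                              noiseSd = noise, seed = seed))
}

# simulate a cohort of paired samples for training tests
tinyPairs <- function(n, shape = c(32L, 32L, 32L), factor = 2L, seed = 5L) {
  cohort <- generateCohort(n, PhantomSpec(shape = shape, seed = seed),
                           seed = seed)
  pairs <- lapply(cohort, function(ph) {
    hr <- homogenizeBackground(ph$volume, ph$mask)
    simulatePair(hr, ph$mask, DegradationSpec(factor))
  })
  names(pairs) <- vapply(cohort, function(p) p$volume@id, character(1))
  pairs
}
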