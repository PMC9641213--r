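#' Generate a synthetic brain-like phantom
#'
#' Builds a volume of nested ellipsoid shells (outermost to innermost,
#' e.g. CSF/GM/WM-like) with per-shell base intensity, an optional
#' band-limited texture field (white noise smoothed to the requested
#' correlation length), and optional additive Gaussian noise, clipped to
#' [0, 1]. The background is exactly 0. The ground-truth tissue support
#' and a shell-label grid are returned alongside the volume, so masking,
#' degradation and training can all be validated against known structure.
#'
#' @param spec a [PhantomSpec-class].
#' @param semiAxes optional 3 x nShells matrix of ellipsoid semi-axes as
#'   fractions of the half-shape (columns outermost to innermost);
#'   defaults to nested fractions of 0.84, scaled by 0.74 per shell.
#' @param center optional center in voxel units; defaults to the volume
#'   center.
#' @return A list with elements \code{volume} ([MRIVolume-class]),
#'   \code{mask} ([TissueMask-class]) and \code{labels} (integer array,
#'   0 = background, s = shell s counting from the outermost).
#' @examples
#' ph <- generatePhantom(PhantomSpec(seed = 7))
#' ph$volume
#' @export
generatePhantom <- function(spec, semiAxes = NULL, center = NULL) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  d <- spec@shape
  n <- spec@nTissueShells
  if (is.null(semiAxes)) {
    semiAxes <- sapply(seq_len(n) - 1L, function(s) rep(0.84 * 0.74^s, 3))
    semiAxes <- matrix(semiAxes, nrow = 3)
  }
  stopifnot(nrow(semiAxes) == 3, ncol(semiAxes) == n)
  if (is.null(center)) center <- (d + 1) / 2
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)

  gx <- (seq_len(d[1]) - center[1]) / (d[1] / 2)
  gy <- (seq_len(d[2]) - center[2]) / (d[2] / 2)
  gz <- (seq_len(d[3]) - center[3]) / (d[3] / 2)
  labels <- array(0L, dim = d)
  # radial quadratic form per shell; voxel belongs to the innermost shell
  # whose ellipsoid contains it
  for (s in seq_len(n)) {
    a <- semiAxes[, s]
    r2 <- outer(outer((gx / a[1])^2, (gy / a[2])^2, `+`), (gz / a[3])^2, `+`)
    labels[r2 <= 1] <- s
  }
  vol <- array(0, dim = d)
  for (s in seq_len(n)) vol[labels == s] <- spec@intensityLevels[s]
  mask <- labels > 0L

  if (spec@textureScale > 0) {
    ks <- 2L * ceiling(2 * spec@textureScale) + 1L
    tex <- array(stats::rnorm(prod(d)), dim = d)
    tex <- array(.cpp_gauss_subsample(tex, 1L, ks, spec@textureScale),
                 dim = d)
    tex <- tex / stats::sd(tex) * 0.06  # fixed texture amplitude
    vol[mask] <- vol[mask] + tex[mask]
  }
  if (spec@noiseSd > 0) {
    nz <- stats::rnorm(sum(mask), sd = spec@noiseSd)
    vol[mask] <- vol[mask] + nz
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  vol[!mask] <- 0
  list(volume = MRIVolume(vol, id = sprintf("phantom-seed%d", spec@seed)),
       mask = TissueMask(mask),
       labels = labels)
}

#' Generate a cohort of varied phantoms
#'
#' Produces \code{n} phantoms whose ellipsoid semi-axes, centers and shell
#' intensities vary randomly within fixed ranges (semi-axes +/- 8%, center
#' +/- 2 voxels, intensity levels +/- 0.04 while preserving their order).
#' Per-phantom seeds are derived deterministically from \code{(seed, index)}.
#'
#' @param n number of phantoms (>= 1).
#' @param spec base [PhantomSpec-class].
#' @param seed cohort seed.
#' @return A list of length n; each element as in [generatePhantom()], with
#'   volume ids \code{"phantom-<index>"}.
#' @export
generateCohort <- function(n, spec = PhantomSpec(), seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    si <- as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483647)
    dspec <- spec
    dspec@seed <- si
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(si + 1L)
    nsh <- spec@nTissueShells
    base <- sapply(seq_len(nsh) - 1L, function(s) rep(0.84 * 0.74^s, 3))
    base <- matrix(base, nrow = 3)
    axes <- base * matrix(stats::runif(3 * nsh, 0.92, 1.08), nrow = 3)
    axes <- pmin(axes, 0.95)
    ctr <- (spec@shape + 1) / 2 + stats::runif(3, -2, 2)
    lv <- spec@intensityLevels + stats::runif(nsh, -0.04, 0.04)
    lv <- pmin(pmax(sort(lv), 0.05), 1)
    if (any(diff(lv) <= 0)) lv <- spec@intensityLevels
    dspec@intensityLevels <- lv
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    ph <- generatePhantom(dspec, semiAxes = axes, center = ctr)
    ph$volume@id <- sprintf("phantom-%03d", i)
    ph
  })
}
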