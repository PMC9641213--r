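# Image-quality metrics (PSNR, MAE on the [0,255] scale, SSIM) and the
# cohort evaluation / statistical comparison harness.

.asArray <- function(x) if (methods::is(x, "MRIVolume")) x@data else x

#' Peak signal-to-noise ratio
#'
#' \code{20 * log10(maxVal / sqrt(MSE))} in dB, computed over the whole
#' volume. Identical inputs have zero MSE and are reported as \code{Inf}
#' (a sentinel, never a division error).
#'
#' @param est,ref arrays or [MRIVolume-class] objects of equal shape.
#' @param maxVal peak intensity of the reference scale (default 1).
#' @return PSNR in dB; symmetric in its arguments.
#' @examples
#' a <- array(0.5, dim = c(4, 4, 4))
#' psnr(a + 0.1, a)  # 20 dB
#' @export
psnr <- function(est, ref, maxVal = 1) {
  est <- .asArray(est); ref <- .asArray(ref)
  if (!identical(dim(est), dim(ref))) stop("shape mismatch")
  mse <- mean((est - ref)^2)
  if (mse == 0) return(Inf)
  20 * log10(maxVal / sqrt(mse))
}

#' Mean absolute error on the [0, 255] scale
#'
#' Mean absolute voxel difference of [0, 1]-scaled inputs, reported in the
#' standard 8-bit intensity range (multiplied by 255).
#'
#' @param est,ref arrays or [MRIVolume-class] objects on the [0, 1] scale.
#' @return MAE in [0, 255]; symmetric in its arguments.
#' @export
mae255 <- function(est, ref) {
  est <- .asArray(est); ref <- .asArray(ref)
  if (!identical(dim(est), dim(ref))) stop("shape mismatch")
  mean(abs(est - ref)) * 255
}

#' Structural similarity index
#'
#' Windowed SSIM with a cubic uniform window (default side 7) and the
#' standard constants c1 = 0.01^2, c2 = 0.03^2 for unit dynamic range:
#' the mean over voxels of
#' \deqn{\frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'            {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}}
#' with local moments from the sliding window (symmetric reflection at
#' borders). \code{global = TRUE} evaluates the single-window variant on
#' whole-volume statistics with the constant \code{c1} repeated in the
#' second denominator factor — the formula exactly as printed in the
#' formulation this package follows; the windowed form is the headline
#' metric (see the methods vignette for the discrepancy discussion).
#'
#' @param est,ref arrays or [MRIVolume-class] objects, dynamic range 1.
#' @param window odd window side for the local form (default 7).
#' @param global use whole-volume statistics (single window).
#' @return SSIM in [-1, 1]; exactly 1 for identical inputs.
#' @export
ssim <- function(est, ref, window = 7L, global = FALSE) {
  est <- .asArray(est); ref <- .asArray(ref)
  if (!identical(dim(est), dim(ref))) stop("shape mismatch")
  c1 <- 0.01^2
  c2 <- 0.03^2
  if (global) {
    mx <- mean(est); my <- mean(ref)
    vx <- mean((est - mx)^2); vy <- mean((ref - my)^2)
    cxy <- mean((est - mx) * (ref - my))
    # printed single-window form: c1 repeated in the variance factor
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
           ((mx^2 + my^2 + c1) * (vx + vy + c1)))
  }
  if (is.matrix(est)) {
    est <- array(est, dim = c(dim(est), 1L))
    ref <- array(ref, dim = dim(est))
  }
  mx <- array(.cpp_box_mean(est, window), dim = dim(est))
  my <- array(.cpp_box_mean(ref, window), dim = dim(est))
  sxx <- array(.cpp_box_mean(est * est, window), dim = dim(est)) - mx^2
  syy <- array(.cpp_box_mean(ref * ref, window), dim = dim(est)) - my^2
  sxy <- array(.cpp_box_mean(est * ref, window), dim = dim(est)) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Evaluate a cohort of super-resolved volumes
#'
#' Computes PSNR, MAE and SSIM for every (volume, method, factor) cell and
#' summarizes mean and standard deviation per (method, factor) — the shape
#' of a per-cohort results table.
#'
#' @param cohort a list of entries, each a list with elements \code{id}
#'   (string), \code{factor} (integer), \code{hr} (reference
#'   [MRIVolume-class]) and \code{sr} (named list of estimated volumes,
#'   e.g. \code{list(interp = ..., cnn3d = ...)}).
#' @param masked if TRUE, metrics are restricted to the bounding box of a
#'   supplied \code{mask} entry; default FALSE (whole-volume metrics).
#' @param globalSSIM use the single-window SSIM variant.
#' @return A list with \code{report} (one row per volume/method/factor) and
#'   \code{summary} (mean and SD per method/factor).
#' @export
evaluateCohort <- function(cohort, masked = FALSE, globalSSIM = FALSE) {
  rows <- list()
  for (entry in cohort) {
    if (is.null(entry$hr) || is.null(entry$sr))
      stop("missing pairing: each entry needs hr and sr")
    hr <- .asArray(entry$hr)
    for (method in names(entry$sr)) {
      est <- .asArray(entry$sr[[method]])
      if (!identical(dim(est), dim(hr)))
        stop("missing pairing: '", method, "' not aligned to hr for ",
             entry$id)
      if (masked && !is.null(entry$mask)) {
        mk <- maskData(entry$mask)
        est <- est * mk
        hr_use <- hr * mk
      } else hr_use <- hr
      rows[[length(rows) + 1L]] <- data.frame(
        id = entry$id, method = method, factor = as.integer(entry$factor),
        psnr_db = psnr(est, hr_use), mae255 = mae255(est, hr_use),
        ssim = ssim(est, hr_use, global = globalSSIM),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  agg <- stats::aggregate(report[, c("psnr_db", "mae255", "ssim")],
                          by = list(method = report$method,
                                    factor = report$factor),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(method = agg$method, factor = agg$factor,
                        psnr_mean = agg$psnr_db[, "mean"],
                        psnr_sd = agg$psnr_db[, "sd"],
                        mae255_mean = agg$mae255[, "mean"],
                        mae255_sd = agg$mae255[, "sd"],
                        ssim_mean = agg$ssim[, "mean"],
                        ssim_sd = agg$ssim[, "sd"],
                        stringsAsFactors = FALSE)
  list(report = report, summary = summary[order(summary$method,
                                                summary$factor), ])
}

#' Compare super-resolution methods statistically
#'
#' For each metric: a repeated-measures ANOVA over method, scaling factor
#' and their interaction (volumes as the repeated unit), followed by
#' pairwise paired Wilcoxon signed-rank tests per metric and factor (exact
#' null distribution for n <= 25 without ties, normal approximation
#' otherwise). Significance is flagged at \code{alpha}.
#'
#' @param report the per-volume report from [evaluateCohort()].
#' @param alpha significance level (default 0.05).
#' @return A list with \code{anova} (one row per metric and effect) and
#'   \code{wilcoxon} (one row per metric, factor and method pair; pairs
#'   with no nonzero differences are reported as degenerate with p = NA).
#' @export
compareMethods <- function(report, alpha = 0.05) {
  methods_ <- unique(report$method)
  factors_ <- unique(report$factor)
  n_per_cell <- min(table(report$method, report$factor))
  if (n_per_cell < 6L)
    stop("insufficient pairs: need >= 6 paired observations per cell")
  metrics <- c("psnr_db", "mae255", "ssim")
  anova_rows <- list()
  for (m in metrics) {
    df <- data.frame(id = factor(report$id), method = factor(report$method),
                     fac = factor(report$factor), value = report[[m]])
    df <- df[is.finite(df$value), ]
    form <- if (length(factors_) > 1L && length(methods_) > 1L)
      value ~ method * fac + Error(id/(method * fac))
    else if (length(methods_) > 1L) value ~ method + Error(id/method)
    else value ~ fac + Error(id/fac)
    fit <- stats::aov(form, data = df)
    sm <- summary(fit)
    for (stratum in sm) {
      tab <- stratum[[1]]
      effs <- trimws(rownames(tab))
      for (i in seq_along(effs)) {
        if (effs[i] == "Residuals") next
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          metric = m, effect = effs[i], df = tab[i, "Df"],
          F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
          significant = isTRUE(tab[i, "Pr(>F)"] < alpha),
          stringsAsFactors = FALSE)
      }
    }
  }
  wil_rows <- list()
  pairsM <- if (length(methods_) > 1L) utils::combn(methods_, 2,
                                                    simplify = FALSE)
            else list()
  for (m in metrics) {
    for (f in factors_) {
      for (pr in pairsM) {
        a <- report[report$method == pr[1] & report$factor == f, ]
        b <- report[report$method == pr[2] & report$factor == f, ]
        a <- a[order(a$id), ]; b <- b[order(b$id), ]
        d <- a[[m]] - b[[m]]
        d <- d[is.finite(d)]
        if (length(d) == 0L || all(d == 0)) {
          wil_rows[[length(wil_rows) + 1L]] <- data.frame(
            metric = m, factor = f, method1 = pr[1], method2 = pr[2],
            n = length(d), statistic = NA_real_, p = NA_real_,
            significant = FALSE, degenerate = TRUE, stringsAsFactors = FALSE)
          next
        }
        wt <- suppressWarnings(
          stats::wilcox.test(a[[m]], b[[m]], paired = TRUE,
                             exact = length(d) <= 25))
        wil_rows[[length(wil_rows) + 1L]] <- data.frame(
          metric = m, factor = f, method1 = pr[1], method2 = pr[2],
          n = length(d), statistic = unname(wt$statistic), p = wt$p.value,
          significant = isTRUE(wt$p.value < alpha), degenerate = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(anova = if (length(anova_rows)) do.call(rbind, anova_rows)
       else data.frame(),
       wilcoxon = if (length(wil_rows)) do.call(rbind, wil_rows)
       else data.frame(),
       alpha = alpha)
}
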